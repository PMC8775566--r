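#' Mass-adjusted least-squares line means within one age x treatment stratum
#'
#' Fits, within the chosen stratum, the ANCOVA
#' `value = constant + beta * mass + line + block + error` with a single
#' mass slope shared by all lines, and returns each line's predicted value at
#' the stratum grand-mean mass, averaging block effects with equal weight
#' (the classic adjusted / least-squares mean). With `adjust = "raw"` the
#' plain per-line averages are returned instead, which is useful for
#' comparing the covariate-adjusted and unadjusted definitions of the
#' sensitivity index.
#'
#' @param records phenotype records (see [fit_full_ancova()] for columns).
#' @param age,treatment stratum selectors (single values).
#' @param adjust `"lsmeans"` (default) for the mass- and block-adjusted
#'   means, `"raw"` for unadjusted line averages.
#' @return data frame with one row per line: `line_id`, `age`, `treatment`,
#'   `lsmean`, `se`, `n`.
#' @details If mass is constant in the stratum the slope is dropped and
#'   (block-adjusted) plain means are returned. Lines present in `records`
#'   but absent from the stratum are omitted with a warning. LS-means are
#'   invariant to adding a constant to every mass.
#' @examples
#' d <- data.frame(line_id = rep(c("l1", "l2"), each = 2),
#'                 age = "young", treatment = "control", block = "b1",
#'                 mass_mg = c(1, 2, 2, 3), value = c(1, 2, 4, 5))
#' ls_line_means(d, "young", "control")   # adjusted means 2 and 4
#' @export
ls_line_means <- function(records, age, treatment,
                          adjust = c("lsmeans", "raw")) {
  check_records_minimal(records)
  adjust <- match.arg(adjust)
  sel <- records$age == age & records$treatment == treatment
  d <- records[sel, , drop = FALSE]
  if (nrow(d) == 0) stopf("no records in stratum (age %s, treatment %s)",
                          age, treatment)
  all_lines <- unique(records$line_id)
  absent <- setdiff(all_lines, unique(d$line_id))
  if (length(absent)) {
    warnf("omitting %d line(s) with no flies in stratum (age %s, treatment %s): %s",
          length(absent), age, treatment,
          paste(utils::head(absent, 5), collapse = ", "))
  }
  d$line_id <- factor(d$line_id)
  if (nlevels(d$line_id) < 2) stopf("need at least 2 lines in the stratum")
  n_per <- as.integer(table(d$line_id))

  if (adjust == "raw") {
    mu <- tapply(d$value, d$line_id, mean)
    sdv <- tapply(d$value, d$line_id, stats::sd)
    out <- data.frame(line_id = levels(d$line_id), age = age,
                      treatment = treatment, lsmean = as.numeric(mu),
                      se = as.numeric(sdv) / sqrt(n_per), n = n_per,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }

  has_mass <- "mass_mg" %in% names(d) && stats::var(d$mass_mg) > 0
  d$block <- factor(d$block)
  has_block <- nlevels(d$block) > 1
  rhs <- c(if (has_mass) "mass_mg", "line_id", if (has_block) "block")
  fit <- stats::lm(stats::reformulate(rhs, response = "value"), data = d)

  # equal-weight prediction grid: every line x every block at grand-mean mass
  grid <- expand.grid(line_id = levels(d$line_id), block = levels(d$block),
                      KEEP.OUT.ATTRS = FALSE)
  if (has_mass) grid$mass_mg <- mean(d$mass_mg)
  Xg <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  ok <- !is.na(stats::coef(fit))
  Xg <- Xg[, ok, drop = FALSE]
  # average grid rows over blocks within each line
  C <- rowsum(Xg, group = grid$line_id) / nlevels(d$block)
  C <- C[levels(d$line_id), , drop = FALSE]
  est <- as.numeric(C %*% stats::coef(fit)[ok])
  V <- suppressWarnings(stats::vcov(fit))  # zero-residual fits warn in summary.lm
  se <- sqrt(rowSums((C %*% V) * C))

  out <- data.frame(line_id = levels(d$line_id), age = age,
                    treatment = treatment, lsmean = est, se = as.numeric(se),
                    n = n_per, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Least-squares line means for every age x treatment stratum
#'
#' Convenience wrapper applying [ls_line_means()] to each stratum present in
#' the records and stacking the results.
#'
#' @inheritParams ls_line_means
#' @return data frame with columns `line_id`, `age`, `treatment`, `lsmean`,
#'   `se`, `n` covering all strata.
#' @export
line_means_all <- function(records, adjust = c("lsmeans", "raw")) {
  adjust <- match.arg(adjust)
  strata <- unique(records[, c("age", "treatment")])
  out <- lapply(seq_len(nrow(strata)), function(k) {
    ls_line_means(records, strata$age[k], strata$treatment[k], adjust)
  })
  do.call(rbind, out)
}

check_records_minimal <- function(records) {
  need <- c("line_id", "age", "treatment", "block", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stopf("phenotype records are missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  invisible(records)
}
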