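#' Among-line and residual variance components within one stratum
#'
#' Method-of-moments (one-way ANOVA) estimator of the among-line variance on
#' mass-adjusted phenotype values within an age x treatment stratum:
#'
#' * `sigma2_error = MS_within`
#' * `sigma2_line = (MS_between - MS_within) / n0`, with
#'   `n0 = (N - sum(n_i^2)/N) / (k - 1)` for unbalanced data (equal to the
#'   common per-line count when the design is balanced).
#'
#' Negative among-line estimates are truncated at zero for reporting (and for
#' genetic correlations), with the raw untruncated value retained.
#'
#' @param records phenotype records (see [fit_full_ancova()]).
#' @param age,treatment stratum selectors.
#' @param adjust_mass if `TRUE` (default) mass is regressed out with a
#'   stratum-common slope (estimated controlling for line) before the
#'   one-way ANOVA; ignored when mass is absent or constant.
#' @return list of class `variance_components`: `age`, `treatment`,
#'   `sigma2_line` (truncated at 0), `sigma2_line_raw`, `sigma2_error`,
#'   `n0`, `ms_between`, `ms_within`, `n_lines`, `n_total`.
#' @examples
#' d <- data.frame(line_id = rep(c("l1", "l2"), each = 2), age = "a",
#'                 treatment = "c", block = "b1", mass_mg = 1,
#'                 value = c(0, 2, 4, 6))
#' variance_components(d, "a", "c")$sigma2_line   # 7
#' @export
variance_components <- function(records, age, treatment, adjust_mass = TRUE) {
  check_records_minimal(records)
  sel <- records$age == age & records$treatment == treatment
  d <- records[sel, , drop = FALSE]
  if (nrow(d) == 0) stopf("no records in stratum (age %s, treatment %s)",
                          age, treatment)
  d$line_id <- factor(d$line_id)
  k <- nlevels(d$line_id)
  if (k < 2) stopf("need at least 2 lines in the stratum")
  n_i <- as.integer(table(d$line_id))
  N <- sum(n_i)
  if (all(n_i == 1)) {
    stopf("all lines are singletons: residual variance is inestimable")
  }

  y <- d$value
  if (adjust_mass && "mass_mg" %in% names(d) &&
      stats::var(d$mass_mg) > 0) {
    slope <- stats::coef(stats::lm(value ~ mass_mg + line_id, data = d))["mass_mg"]
    if (is.na(slope)) slope <- 0   # mass aliased with line
    y <- y - as.numeric(slope) * (d$mass_mg - mean(d$mass_mg))
  }

  mu_i <- tapply(y, d$line_id, mean)
  grand <- mean(y)
  ss_between <- sum(n_i * (mu_i - grand)^2)
  ss_within <- sum((y - mu_i[as.integer(d$line_id)])^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  raw <- (ms_between - ms_within) / n0

  structure(list(
    age = age, treatment = treatment,
    sigma2_line = max(0, raw), sigma2_line_raw = raw,
    sigma2_error = ms_within, n0 = n0,
    ms_between = ms_between, ms_within = ms_within,
    n_lines = k, n_total = N
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> age %s, treatment %s: sigma2_line = %.4g (raw %.4g), sigma2_error = %.4g, n0 = %.3g, %d lines / %d flies\n",
    x$age, x$treatment, x$sigma2_line, x$sigma2_line_raw, x$sigma2_error,
    x$n0, x$n_lines, x$n_total))
  invisible(x)
}

#' Genetic correlation between two strata from line means
#'
#' The genetic correlation between two age x treatment strata is the
#' covariance among line means across the strata divided by the product of
#' the square roots of the among-line variance components estimated in each
#' stratum: `r = cov12 / (sigmaL1 * sigmaL2)`. The covariance uses the
#' unbiased (n - 1) denominator over the lines shared by both strata. The
#' estimator is reported as-is: values outside [-1, 1] can occur and are
#' flagged, never truncated. When either truncated among-line component is
#' zero the correlation is undefined (`defined = FALSE`, `r = NA`).
#'
#' @param means_a,means_b line-mean tables from [ls_line_means()] for the
#'   two strata.
#' @param vc_a,vc_b matching [variance_components()] objects.
#' @param label correlation label, e.g. `"rGT1"` (control vs treated at
#'   age 1), `"rGAC"` (ages within control); free-form.
#' @return list of class `genetic_correlation`: `label`, `stratum_a`,
#'   `stratum_b`, `cov12`, `r`, `defined`, `exceeds_unit`, `n_lines`.
#' @export
genetic_correlation <- function(means_a, means_b, vc_a, vc_b,
                                label = "custom") {
  shared <- intersect(means_a$line_id, means_b$line_id)
  if (length(shared) < 3) {
    stopf("need at least 3 shared lines to estimate a genetic correlation (got %d)",
          length(shared))
  }
  xa <- means_a$lsmean[match(shared, means_a$line_id)]
  xb <- means_b$lsmean[match(shared, means_b$line_id)]
  cov12 <- stats::cov(xa, xb)
  s1 <- sqrt(vc_a$sigma2_line)
  s2 <- sqrt(vc_b$sigma2_line)
  defined <- s1 > 0 && s2 > 0
  r <- if (defined) cov12 / (s1 * s2) else NA_real_
  structure(list(
    label = label,
    stratum_a = paste(vc_a$age, vc_a$treatment, sep = ":"),
    stratum_b = paste(vc_b$age, vc_b$treatment, sep = ":"),
    cov12 = cov12, r = r, defined = defined,
    exceeds_unit = isTRUE(defined && abs(r) > 1),
    n_lines = length(shared)
  ), class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("<genetic_correlation> %s (%s vs %s): r = %s, cov12 = %.4g, %d lines%s\n",
              x$label, x$stratum_a, x$stratum_b,
              if (x$defined) sprintf("%.4f", x$r) else "undefined",
              x$cov12, x$n_lines,
              if (x$exceeds_unit) " [|r| > 1]" else ""))
  invisible(x)
}
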