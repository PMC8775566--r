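#' Full-design ANCOVA for panel phenotype records
#'
#' Fits the complete phenotype model over all records:
#'
#' value = constant + mass + line + treatment + age + line:treatment +
#'         line:age + treatment:age + line:treatment:age + block(age) + error
#'
#' with body mass as a covariate and block nested within age, and reports a
#' partial (Type III-style) F test for every term: each term's sum of squares
#' is the increase in residual sum of squares when that term's (sum-coded,
#' non-aliased) columns are removed from the full model, so the tests do not
#' depend on term order. On balanced designs they coincide with sequential
#' tests.
#'
#' @param records phenotype records: data frame with columns `line_id`,
#'   `age`, `treatment`, `block`, `mass_mg`, `value`.
#' @return data frame of class `ancova_table` with one row per term:
#'   `term`, `df`, `sum_sq`, `mean_sq`, `statistic` (F), `df_den`, `p_value`,
#'   plus a `Residuals` row.
#' @examples
#' cfg <- sim_config(n_lines = 8, n_flies_per_cell = 4, n_variants = 20,
#'                   n_causal_trait = 0, n_causal_sensitivity = 0)
#' ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
#' fit_full_ancova(ph$records)
#' @export
fit_full_ancova <- function(records) {
  check_records(records)
  d <- records
  for (f in c("line_id", "treatment", "age")) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2) {
      stopf("`%s` needs at least 2 levels for the full model", f)
    }
  }
  if (!all(is.finite(d$mass_mg)) || any(d$mass_mg <= 0)) {
    stopf("`mass_mg` must be finite and positive")
  }
  cell <- table(d$line_id, d$treatment, d$age)
  if (any(cell == 0)) {
    idx <- which(cell == 0, arr.ind = TRUE)[1, ]
    stopf("rank-deficient design: empty cell (line %s, treatment %s, age %s)",
          dimnames(cell)[[1]][idx[1]], dimnames(cell)[[2]][idx[2]],
          dimnames(cell)[[3]][idx[3]])
  }
  # renumber blocks within each age so age:block_f is the nested term
  # b(a): per-age block contrasts that never alias the age main effect
  d$block_f <- stats::ave(as.character(d$block), as.character(d$age),
                          FUN = function(b) match(b, sort(unique(b))))
  d$block_f <- factor(d$block_f)

  terms_rhs <- c("mass_mg", "line_id", "treatment", "age",
                 "line_id:treatment", "line_id:age", "treatment:age",
                 "line_id:treatment:age")
  facs <- c("line_id", "treatment", "age")
  if (nlevels(d$block_f) > 1) {
    terms_rhs <- c(terms_rhs, "age:block_f")
    facs <- c(facs, "block_f")
  }
  frm <- stats::as.formula(paste("value ~", paste(terms_rhs, collapse = " + ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(facs)), facs)
  mf <- stats::model.frame(frm, d)
  X <- stats::model.matrix(frm, mf, contrasts.arg = contr)
  y <- stats::model.response(mf)
  asg <- attr(X, "assign")  # 0 = intercept, then terms in formula order
  term_labels <- attr(stats::terms(frm), "term.labels")

  full <- stats::lm.fit(X, y)
  rank_full <- full$rank
  rss_full <- sum(full$residuals^2)
  df_res <- length(y) - rank_full
  if (df_res <= 0) stopf("no residual degrees of freedom in the full model")
  mse <- rss_full / df_res

  rows <- lapply(seq_along(term_labels), function(k) {
    keep <- asg != k
    red <- stats::lm.fit(X[, keep, drop = FALSE], y)
    df_k <- rank_full - red$rank
    ss_k <- sum(red$residuals^2) - rss_full
    if (df_k == 0) {
      return(data.frame(term = term_labels[k], df = 0, sum_sq = 0,
                        mean_sq = NA_real_, statistic = NA_real_,
                        df_den = df_res, p_value = NA_real_))
    }
    f_k <- (ss_k / df_k) / mse
    data.frame(term = term_labels[k], df = df_k, sum_sq = ss_k,
               mean_sq = ss_k / df_k, statistic = f_k, df_den = df_res,
               p_value = stats::pf(f_k, df_k, df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$term[out$term == "age:block_f"] <- "block(age)"
  out$term[out$term == "line_id"] <- "line"
  out$term <- sub("line_id:", "line:", out$term, fixed = TRUE)
  out <- rbind(out, data.frame(term = "Residuals", df = df_res,
                               sum_sq = rss_full, mean_sq = mse,
                               statistic = NA_real_, df_den = NA_real_,
                               p_value = NA_real_))
  rownames(out) <- NULL
  class(out) <- c("ancova_table", "data.frame")
  out
}

check_records <- function(records) {
  need <- c("line_id", "age", "treatment", "block", "mass_mg", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stopf("phenotype records are missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  invisible(records)
}
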