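#' Single-marker association test on line-level phenotypes
#'
#' Tests one biallelic variant against a line-level phenotype (line mean or
#' sensitivity index) with the single-marker linear model
#' `y = u + m * x + e`, where `x` is the homozygous genotype code (0/1) of
#' each inbred line. The allele effect is the difference between genotype
#' class means, and the two-sided p-value comes from the slope's t statistic
#' with n - 2 degrees of freedom (equivalent to the one-way F test with
#' (1, n - 2) df).
#'
#' Lines with missing genotype are dropped for that variant. A variant is
#' *skipped* (no p-value) when it is monomorphic among the used lines or its
#' minor genotype class has fewer than `min_class` lines.
#'
#' @param y numeric phenotype vector (one value per line).
#' @param x genotype vector (0/1, `NA` allowed), same length/order as `y`.
#' @param min_class minimum lines in the minor genotype class (default 4).
#' @param variant_id optional id copied into the result.
#' @return one-row data frame: `variant_id`, `n`, `effect`, `se`,
#'   `statistic`, `p_value`, `model`, `status` ("ok"/"skipped"), `reason`.
#' @examples
#' marker_test(c(1, 2, 3, 4), c(0, 0, 1, 1), min_class = 1)
#' @export
marker_test <- function(y, x, min_class = 4, variant_id = NA_character_) {
  stopifnot(length(y) == length(x))
  use <- is.finite(y) & !is.na(x)
  y <- y[use]; x <- x[use]
  n <- length(y)
  n1 <- sum(x == 1)
  n0 <- n - n1
  if (min(n1, n0) < max(1, min_class)) {
    reason <- if (min(n1, n0) == 0) "monomorphic" else "minor class below minimum"
    return(marker_row(variant_id, n, model = "trait",
                      status = "skipped", reason = reason))
  }
  m1 <- mean(y[x == 1]); m0 <- mean(y[x == 0])
  eff <- m1 - m0
  rss <- sum((y[x == 1] - m1)^2) + sum((y[x == 0] - m0)^2)
  df <- n - 2
  se <- sqrt(rss / df * (1 / n1 + 1 / n0))
  if (se == 0) {
    stat <- if (eff == 0) 0 else sign(eff) * Inf
  } else {
    stat <- eff / se
  }
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  marker_row(variant_id, n, effect = eff, se = se, statistic = stat,
             p_value = p, model = "trait")
}

#' Sensitivity association test with a trait-value cofactor
#'
#' Fits `sensitivity = intercept + gamma * z + m * x + e`, where `z` is the
#' line's trait value (the cofactor) and `x` the genotype, and reports the
#' partial test of the genotype term given the cofactor (t with n - 3 df).
#' Variants significant here are associated with treatment sensitivity after
#' accounting for each variant's effect on the trait itself, which separates
#' sensitivity loci from trait loci.
#'
#' @param y_sens numeric sensitivity vector (one value per line).
#' @param z numeric trait-value cofactor, same lines.
#' @param x genotype vector (0/1, `NA` allowed).
#' @inheritParams marker_test
#' @return one-row data frame as [marker_test()], plus `cofactor_coef`
#'   (gamma); `model` is `"sensitivity_cofactor"`. Exact collinearity of `x`
#'   with the cofactor yields a skipped result with reason "singular".
#' @export
marker_test_with_cofactor <- function(y_sens, z, x, min_class = 4,
                                      variant_id = NA_character_) {
  stopifnot(length(y_sens) == length(x), length(z) == length(x))
  use <- is.finite(y_sens) & is.finite(z) & !is.na(x)
  y <- y_sens[use]; z <- z[use]; x <- x[use]
  n <- length(y)
  n1 <- sum(x == 1)
  if (min(n1, n - n1) < max(1, min_class)) {
    reason <- if (min(n1, n - n1) == 0) "monomorphic" else "minor class below minimum"
    return(marker_row(variant_id, n, model = "sensitivity_cofactor",
                      status = "skipped", reason = reason))
  }
  X <- cbind(intercept = 1, z = z, x = x)
  q <- qr(X)
  if (q$rank < 3) {
    return(marker_row(variant_id, n, model = "sensitivity_cofactor",
                      status = "skipped", reason = "singular"))
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- n - 3
  XtX_inv <- solve(crossprod(X))
  sigma2 <- rss / df
  se_x <- sqrt(sigma2 * XtX_inv[3, 3])
  eff <- as.numeric(fit$coefficients["x"])
  # a numerically perfect cofactor fit leaves only rounding noise in the
  # genotype term: report a null statistic, not 0/0
  eps <- 1e-10 * (stats::sd(y) + abs(mean(y)))
  if (se_x <= eps) {
    stat <- if (abs(eff) <= eps) 0 else sign(eff) * Inf
  } else {
    stat <- eff / se_x
  }
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  out <- marker_row(variant_id, n, effect = as.numeric(eff),
                    se = se_x, statistic = as.numeric(stat), p_value = p,
                    model = "sensitivity_cofactor")
  out$cofactor_coef <- as.numeric(fit$coefficients["z"])
  out
}

marker_row <- function(variant_id, n, effect = NA_real_, se = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       model = "trait", status = "ok",
                       reason = NA_character_) {
  data.frame(variant_id = variant_id, n = n, effect = effect, se = se,
             statistic = statistic, p_value = p_value, model = model,
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Genome-wide single-marker scan over a genotype table
#'
#' Applies [marker_test()] (model `"trait"`) or
#' [marker_test_with_cofactor()] (model `"sensitivity_cofactor"`) to every
#' variant, fully vectorized across variants. Lines are matched by id
#' between the phenotype and the genotype table; results are deterministic
#' and invariant to consistent reordering of lines or variants.
#'
#' @param phenotype either a named numeric vector (names = line ids) or a
#'   data frame with `line_id` and one of `lsmean`/`S`/`value`.
#' @param genotypes a `genotype_table` (see [simulate_genotypes()] /
#'   [read_genotypes()]).
#' @param model `"trait"` or `"sensitivity_cofactor"`.
#' @param cofactor trait-value cofactor for the sensitivity model, same
#'   formats as `phenotype`.
#' @param min_class minimum minor-class line count (default 4).
#' @return data frame of class `marker_scan`: one row per variant with
#'   `variant_id`, `chrom`, `pos`, `type`, `n`, `effect`, `se`, `statistic`,
#'   `p_value`, `status`, `reason`, `model` (plus `cofactor_coef` for the
#'   cofactor model).
#' @export
run_scan <- function(phenotype, genotypes,
                     model = c("trait", "sensitivity_cofactor"),
                     cofactor = NULL, min_class = 4) {
  model <- match.arg(model)
  y <- as_line_vector(phenotype)
  geno <- genotypes$geno
  shared <- intersect(names(y), rownames(geno))
  if (length(shared) < 3) {
    stopf("phenotype and genotype tables share only %d line(s)", length(shared))
  }
  y <- y[shared]
  G <- geno[shared, , drop = FALSE]
  keep_y <- is.finite(y)
  y <- y[keep_y]; G <- G[keep_y, , drop = FALSE]

  if (model == "trait") {
    res <- scan_trait_vectorized(y, G, min_class)
  } else {
    if (is.null(cofactor)) {
      stopf("the sensitivity_cofactor model requires `cofactor`")
    }
    z <- as_line_vector(cofactor)
    if (!all(names(y) %in% names(z))) {
      stopf("cofactor is missing %d line(s) present in the phenotype",
            sum(!(names(y) %in% names(z))))
    }
    z <- z[names(y)]
    keep_z <- is.finite(z)
    res <- scan_cofactor(y[keep_z], z[keep_z], G[keep_z, , drop = FALSE],
                         min_class)
  }
  if (!any(res$status == "ok")) stopf("no usable variants in the scan")
  meta <- genotypes$variants
  if (!is.null(meta)) {
    j <- match(res$variant_id, meta$variant_id)
    res$chrom <- meta$chrom[j]
    res$pos <- meta$pos[j]
    res$type <- meta$type[j]
  } else {
    res$chrom <- NA_character_; res$pos <- NA_integer_; res$type <- NA_character_
  }
  first <- c("variant_id", "chrom", "pos", "type")
  res <- res[, c(first, setdiff(names(res), first))]
  class(res) <- c("marker_scan", "data.frame")
  res
}

# Closed-form two-class regression across all variants at once; handles
# per-variant missing genotypes through an observation mask.
scan_trait_vectorized <- function(y, G, min_class) {
  M <- !is.na(G)
  X <- G
  X[!M] <- 0L
  n_obs <- colSums(M)
  n1 <- colSums(X)
  n0 <- n_obs - n1
  sy <- as.numeric(crossprod(M, y))
  sy2 <- as.numeric(crossprod(M, y^2))
  s1 <- as.numeric(crossprod(X, y))        # sum of y in class 1
  m1 <- s1 / n1
  m0 <- (sy - s1) / n0
  eff <- m1 - m0
  ss_tot <- sy2 - sy^2 / n_obs
  ss_model <- eff^2 * n1 * n0 / n_obs
  df <- n_obs - 2
  sigma2 <- pmax(ss_tot - ss_model, 0) / df
  se <- sqrt(sigma2 * (1 / n1 + 1 / n0))
  stat <- ifelse(se > 0, eff / se,
                 ifelse(eff == 0, 0, sign(eff) * Inf))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  skip <- pmin(n1, n0) < max(1, min_class)
  reason <- ifelse(pmin(n1, n0) == 0, "monomorphic",
                   "minor class below minimum")
  data.frame(
    variant_id = colnames(G), n = n_obs,
    effect = ifelse(skip, NA_real_, eff),
    se = ifelse(skip, NA_real_, se),
    statistic = ifelse(skip, NA_real_, stat),
    p_value = ifelse(skip, NA_real_, p),
    model = "trait",
    status = ifelse(skip, "skipped", "ok"),
    reason = ifelse(skip, reason, NA_character_),
    stringsAsFactors = FALSE
  )
}

# Cofactor scan: fast residualization path when a variant has no missing
# genotypes, per-variant refit otherwise.
scan_cofactor <- function(y, z, G, min_class) {
  n_all <- length(y)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  ry <- y - mean(y) - if (szz > 0) zc * sum(zc * (y - mean(y))) / szz else 0
  rows <- lapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    if (!anyNA(x)) {
      res <- cofactor_closed_form(y, z, zc, szz, ry, x, n_all, min_class)
    } else {
      res <- NULL
    }
    if (is.null(res)) {
      res <- marker_test_with_cofactor(y, z, x, min_class)
    }
    res$variant_id <- colnames(G)[j]
    res
  })
  do.call(rbind, rows)
}

cofactor_closed_form <- function(y, z, zc, szz, ry, x, n, min_class) {
  n1 <- sum(x)
  if (min(n1, n - n1) < max(1, min_class)) {
    reason <- if (min(n1, n - n1) == 0) "monomorphic" else "minor class below minimum"
    out <- marker_row(NA_character_, n, model = "sensitivity_cofactor",
                      status = "skipped", reason = reason)
    out$cofactor_coef <- NA_real_
    return(out)
  }
  xc <- x - mean(x)
  rx <- xc - if (szz > 0) zc * sum(zc * xc) / szz else 0
  sxx <- sum(rx^2)
  if (sxx < 1e-12 * sum(xc^2) || sxx == 0) return(NULL)  # near-singular: refit
  eff <- sum(rx * ry) / sxx
  rss <- sum(ry^2) - eff^2 * sxx
  df <- n - 3
  sigma2 <- max(rss, 0) / df
  se <- sqrt(sigma2 / sxx)
  eps <- 1e-10 * (stats::sd(y) + abs(mean(y)))
  stat <- if (se > eps) eff / se else if (abs(eff) <= eps) 0 else sign(eff) * Inf
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  gamma <- if (szz > 0) {
    (sum(zc * (y - mean(y))) - eff * sum(zc * xc)) / szz
  } else NA_real_
  out <- marker_row(NA_character_, n, effect = eff, se = se, statistic = stat,
                    p_value = p, model = "sensitivity_cofactor")
  out$cofactor_coef <- gamma
  out
}

as_line_vector <- function(phenotype) {
  if (is.numeric(phenotype) && !is.null(names(phenotype))) {
    return(phenotype)
  }
  if (is.data.frame(phenotype)) {
    val_col <- intersect(c("lsmean", "S", "value"), names(phenotype))[1]
    if (!is.na(val_col) && "line_id" %in% names(phenotype)) {
      if (anyDuplicated(phenotype$line_id)) {
        stopf("phenotype table has duplicated line ids; pass one stratum at a time")
      }
      return(stats::setNames(phenotype[[val_col]], phenotype$line_id))
    }
  }
  stopf("phenotype must be a named numeric vector or a data frame with `line_id` and one of lsmean/S/value")
}
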