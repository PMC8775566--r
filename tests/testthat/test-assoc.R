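test_that("marker test matches the closed-form worked example and degenerate cases", {
  r <- marker_test(c(1, 2, 3, 4), c(0, 0, 1, 1), min_class = 1)
  expect_equal(r$effect, 2)
  expect_equal(r$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(r$statistic, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(2 * sqrt(2), 2, lower.tail = FALSE))
  expect_equal(r$status, "ok")

  # constant phenotype: zero effect, p = 1
  r0 <- marker_test(rep(5, 10), rep(c(0, 1), 5), min_class = 1)
  expect_equal(r0$effect, 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # monomorphic and undercount variants are skipped, never given a p
  expect_equal(marker_test(rnorm(8), rep(0, 8))$status, "skipped")
  expect_equal(marker_test(rnorm(8), rep(0, 8))$reason, "monomorphic")
  r_small <- marker_test(rnorm(8), c(1, rep(0, 7)), min_class = 4)
  expect_equal(r_small$status, "skipped")
  expect_true(is.na(r_small$p_value))
})

test_that("marker tests agree with brute-force least squares on random instances", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2) next
    y <- rnorm(n) + 0.5 * x
    z <- rnorm(n) + 0.3 * x
    # normal-equations oracle
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% beta)^2)
    se <- sqrt(rss / (n - 2) * solve(t(X) %*% X)[2, 2])
    r <- marker_test(y, x, min_class = 1)
    expect_equal(r$effect, beta[2], tolerance = 1e-10)
    expect_equal(r$se, se, tolerance = 1e-10)

    X2 <- cbind(1, z, x)
    if (qr(X2)$rank < 3) next
    b2 <- solve(t(X2) %*% X2, t(X2) %*% y)
    rss2 <- sum((y - X2 %*% b2)^2)
    se2 <- sqrt(rss2 / (n - 3) * solve(t(X2) %*% X2)[3, 3])
    r2 <- marker_test_with_cofactor(y, z, x, min_class = 1)
    expect_equal(r2$effect, b2[3], tolerance = 1e-10)
    expect_equal(r2$se, se2, tolerance = 1e-10)
    expect_equal(r2$cofactor_coef, b2[2], tolerance = 1e-10)
  }
})

test_that("the cofactor model nests the plain test and absorbs cofactor signal", {
  set.seed(11)
  n <- 40
  x <- rbinom(n, 1, 0.4)
  y <- rnorm(n)
  # gamma = 0 data: cofactor fit on an independent z matches plain test
  z <- rnorm(n)
  r_plain <- marker_test(y, x, min_class = 1)
  r_cof <- marker_test_with_cofactor(y, z, x, min_class = 1)
  # same effect estimate family; compare against explicit lm fits
  lm_cof <- lm(y ~ z + x)
  expect_equal(r_cof$p_value, summary(lm_cof)$coefficients["x", 4],
               tolerance = 1e-10)
  expect_equal(r_plain$p_value,
               summary(lm(y ~ x))$coefficients["x", 4], tolerance = 1e-10)

  # y an exact linear function of z: genotype term has nothing left
  y_lin <- 2 + 3 * z
  r_abs <- marker_test_with_cofactor(y_lin, z, x, min_class = 1)
  expect_lt(abs(r_abs$statistic), 1e-6)

  # x exactly collinear with z: singular fit is skipped with reason
  r_sing <- marker_test_with_cofactor(y, as.numeric(x), x, min_class = 1)
  expect_equal(r_sing$status, "skipped")
  expect_equal(r_sing$reason, "singular")
})

test_that("the cofactor scan suppresses trait-only variants but keeps sensitivity variants", {
  set.seed(12)
  n <- 126
  p_plain_traitvar <- numeric(40)
  p_cof_traitvar <- numeric(40)
  p_cof_sensvar <- numeric(40)
  for (i in 1:40) {
    x_trait <- rbinom(n, 1, 0.4)   # affects the trait only
    x_sens <- rbinom(n, 1, 0.4)    # affects sensitivity only
    z <- 0.8 * x_trait + rnorm(n, 0, 0.5)          # trait line means
    s <- 0.6 * z + 0.8 * x_sens + rnorm(n, 0, 0.5) # sensitivity, trait-correlated
    p_plain_traitvar[i] <- marker_test(s, x_trait, min_class = 1)$p_value
    p_cof_traitvar[i] <- marker_test_with_cofactor(s, z, x_trait,
                                                   min_class = 1)$p_value
    p_cof_sensvar[i] <- marker_test_with_cofactor(s, z, x_sens,
                                                  min_class = 1)$p_value
  }
  # trait-mediated signal is removed by the cofactor
  expect_gt(median(p_cof_traitvar), median(p_plain_traitvar))
  # genuine sensitivity signal survives the cofactor adjustment
  expect_lt(median(p_cof_sensvar), 1e-4)
})

test_that("scans align lines by id and are invariant to consistent reordering", {
  cfg <- tiny_config(maf_range = c(0.3, 0.5))
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, gt)
  lm_tab <- ls_line_means(ph$records, "young", "control")
  scan <- run_scan(lm_tab, gt, model = "trait", min_class = 2)
  expect_s3_class(scan, "marker_scan")
  expect_equal(nrow(scan), cfg$n_variants)
  expect_true(all(scan$p_value[scan$status == "ok"] > 0 &
                    scan$p_value[scan$status == "ok"] <= 1))

  # single-variant scan equals the single marker test
  gt1 <- gt
  gt1$geno <- gt1$geno[, 7, drop = FALSE]
  gt1$variants <- gt1$variants[7, ]
  s1 <- run_scan(lm_tab, gt1, model = "trait", min_class = 2)
  y <- setNames(lm_tab$lsmean, lm_tab$line_id)[rownames(gt$geno)]
  m1 <- marker_test(y, gt$geno[, 7], min_class = 2)
  expect_equal(s1$effect, m1$effect, tolerance = 1e-12)
  expect_equal(s1$p_value, m1$p_value, tolerance = 1e-12)

  # permute line order consistently: identical results
  perm <- sample(nrow(lm_tab))
  gt_perm <- gt
  gt_perm$geno <- gt$geno[sample(nrow(gt$geno)), ]
  scan_perm <- run_scan(lm_tab[perm, ], gt_perm, model = "trait",
                        min_class = 2)
  expect_equal(scan$effect, scan_perm$effect, tolerance = 1e-12)
  expect_equal(scan$p_value, scan_perm$p_value, tolerance = 1e-12)

  # missing genotypes drop lines per variant
  gt_na <- gt
  gt_na$geno[1:3, 5] <- NA
  scan_na <- run_scan(lm_tab, gt_na, model = "trait", min_class = 2)
  expect_equal(scan_na$n[5], cfg$n_lines - 3)
})

test_that("cofactor scan over a genotype table matches per-variant fits", {
  cfg <- tiny_config(maf_range = c(0.3, 0.5))
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, gt)
  lm_tab <- line_means_all(ph$records)
  sens <- sensitivity_index(lm_tab, "old", treatments = c("control", "treated"))
  cof <- lm_tab[lm_tab$age == "old" & lm_tab$treatment == "control", ]
  scan <- run_scan(sens, gt, model = "sensitivity_cofactor", cofactor = cof,
                   min_class = 2)
  y <- setNames(sens$S, sens$line_id)
  z <- setNames(cof$lsmean, cof$line_id)[names(y)]
  for (j in c(3, 11, 29)) {
    x <- gt$geno[names(y), j]
    ref <- marker_test_with_cofactor(y, z, x, min_class = 2)
    expect_equal(scan$p_value[j], ref$p_value, tolerance = 1e-10)
    expect_equal(scan$cofactor_coef[j], ref$cofactor_coef, tolerance = 1e-10)
  }
  # missing genotypes fall back to the per-variant path and still agree
  gt_na <- gt
  gt_na$geno[2, 3] <- NA
  scan_na <- run_scan(sens, gt_na, model = "sensitivity_cofactor",
                      cofactor = cof, min_class = 2)
  x <- gt_na$geno[names(y), 3]
  ref <- marker_test_with_cofactor(y, z, x, min_class = 2)
  expect_equal(scan_na$p_value[3], ref$p_value, tolerance = 1e-10)
})

test_that("candidate calling applies a strict threshold and tallies types", {
  scan <- data.frame(
    variant_id = c("a", "b", "c", "d"), chrom = "2L", pos = 1:4,
    type = c("snp", "indel", "snp", "snp"), n = 100,
    effect = 1, se = 1, statistic = 1,
    p_value = c(9.9e-6, 1e-5, 2e-7, NA),
    status = c("ok", "ok", "ok", "skipped"), reason = NA, model = "trait")
  cs <- call_candidates(scan, threshold = 1e-5, label = "demo")
  expect_setequal(cs$variants$variant_id, c("a", "c"))   # 1e-5 excluded
  expect_equal(cs$n_snps, 2)
  expect_equal(cs$n_indels, 0)
  all_in <- call_candidates(scan, threshold = 1)
  expect_equal(all_in$n_variants, 3)  # skipped rows never qualify
})

test_that("gene-window annotation honours the strict 5 kb rule", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "2L",
                      start = c(10000, 16500), end = c(12000, 17000))
  scan <- data.frame(
    variant_id = c("inside", "near", "edge", "between", "far", "nochrom"),
    chrom = c("2L", "2L", "2L", "2L", "2L", "4"),
    pos = c(10500, 5001, 5000, 13000, 30000, 100),
    type = "snp", n = 10, effect = 1, se = 1, statistic = 5,
    p_value = 1e-8, status = "ok", reason = NA, model = "trait")
  cs <- call_candidates(scan, 1e-5)
  expect_warning(cs <- annotate_variants(cs, genes, window = 5000),
                 "chromosome")
  vg <- cs$variant_genes
  expect_true("inside" %in% vg$variant_id)
  expect_true("near" %in% vg$variant_id)       # gap 4999 < 5000
  expect_false("edge" %in% vg$variant_id)      # gap 5000, strict
  expect_false("far" %in% vg$variant_id)
  expect_false("nochrom" %in% vg$variant_id)
  # a variant between two genes within the window maps to both
  expect_setequal(vg$gene_id[vg$variant_id == "between"], c("g1", "g2"))
  expect_setequal(cs$genes, c("g1", "g2"))
})

test_that("overlap summaries cover identical, disjoint, and partial sets", {
  ident <- overlap_summary(c("a", "b"), c("a", "b"))
  expect_equal(ident$intersection, ident$union)
  disj <- overlap_summary(c("a", "b", "c"), c("d", "e", "f", "g"))
  expect_equal(disj$n_union, 7)
  expect_equal(disj$n_intersection, 0)
  part <- overlap_summary(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(part$intersection, c("b", "c"))
  expect_equal(part$n_union, 4)
  expect_setequal(part$only_a, "a")
})
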