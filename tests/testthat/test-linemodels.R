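test_that("full ANCOVA recovers planted fixed effects and calibrates under the null", {
  cfg <- tiny_config(var_line = 0, var_line_by_age = 0,
                     var_line_by_treatment = 0,
                     var_line_by_age_by_treatment = 0, var_block = 0,
                     var_error = 1, treatment_effect = 2, age_effect = 0,
                     mass_slope = 0, n_causal_trait = 0,
                     n_causal_sensitivity = 0)
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  tab <- fit_full_ancova(ph$records)
  expect_setequal(tab$term,
                  c("mass_mg", "line", "treatment", "age", "line:treatment",
                    "line:age", "treatment:age", "line:treatment:age",
                    "block(age)", "Residuals"))
  p <- function(term) tab$p_value[tab$term == term]
  expect_lt(p("treatment"), 0.01)
  expect_gt(p("line:treatment"), 0.001)  # no planted interaction
  # design df: line 11, treatment 1, interactions multiply
  expect_equal(tab$df[tab$term == "line"], cfg$n_lines - 1)
  expect_equal(tab$df[tab$term == "line:treatment:age"], cfg$n_lines - 1)
  expect_equal(tab$df[tab$term == "block(age)"],
               length(cfg$ages) * (cfg$n_blocks_per_age - 1))
})

test_that("partial ANCOVA tests agree with sequential tests on balanced data", {
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  # constant mass isolates the balanced factorial part, where sequential
  # and partial sums of squares coincide
  d <- ph$records
  d$mass_mg <- 1
  tab <- fit_full_ancova(d)
  d$block_f <- ave(as.character(d$block), d$age,
                   FUN = function(b) match(b, sort(unique(b))))
  seq_fit <- stats::aov(value ~ line_id * treatment * age + age:block_f,
                        data = d)
  seq_tab <- summary(seq_fit)[[1]]
  f_seq <- seq_tab[["F value"]]
  names(f_seq) <- trimws(rownames(seq_tab))
  for (pair in list(c("line", "line_id"), c("treatment", "treatment"),
                    c("line:treatment", "line_id:treatment"),
                    c("line:treatment:age", "line_id:treatment:age"))) {
    expect_equal(tab$statistic[tab$term == pair[1]],
                 unname(f_seq[pair[2]]), tolerance = 1e-6)
  }
})

test_that("ANCOVA matches the type-III oracle on a small crossed design", {
  skip_if_not_installed("car")
  cfg <- sim_config(n_lines = 6, n_flies_per_cell = 3, n_variants = 10,
                    n_blocks_per_age = 1, n_causal_trait = 0,
                    n_causal_sensitivity = 0, seed = 9L)
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  # drop one record so the design is unbalanced and partial != sequential
  d <- ph$records[-1, ]
  tab <- fit_full_ancova(d)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(value ~ mass_mg + line_id * treatment * age, data = d)
  oracle <- car::Anova(fit, type = 3)
  get_f <- function(term) oracle[term, "F value"]
  expect_equal(tab$statistic[tab$term == "line"], get_f("line_id"),
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "mass_mg"], get_f("mass_mg"),
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "line:treatment:age"],
               get_f("line_id:treatment:age"), tolerance = 1e-8)
})

test_that("empty design cells produce a named error", {
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  d <- ph$records
  drop <- d$line_id == "line_003" & d$treatment == "treated" & d$age == "old"
  expect_error(fit_full_ancova(d[!drop, ]),
               "empty cell \\(line line_003, treatment treated, age old\\)")
})

test_that("LS-means match the hand-worked unbalanced-mass example", {
  d <- data.frame(line_id = rep(c("l1", "l2"), each = 2), age = "young",
                  treatment = "control", block = "b1",
                  mass_mg = c(1, 2, 2, 3), value = c(1, 2, 4, 5))
  lsm <- ls_line_means(d, "young", "control")
  expect_equal(lsm$lsmean, c(2, 4))
  expect_equal(lsm$n, c(2L, 2L))
})

test_that("LS-means reduce to raw means when the covariate is flat and are translation invariant", {
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  d <- ph$records
  d$mass_mg <- 1  # constant mass: slope dropped
  d1 <- d[d$age == "young" & d$treatment == "control" & d$block == "young_b1", ]
  lsm <- ls_line_means(d1, "young", "control")
  raw <- tapply(d1$value, d1$line_id, mean)
  expect_equal(lsm$lsmean, as.numeric(raw[lsm$line_id]))

  # translation invariance in mass
  d2 <- ph$records
  lsm_a <- ls_line_means(d2, "young", "control")
  d2$mass_mg <- d2$mass_mg + 5
  lsm_b <- ls_line_means(d2, "young", "control")
  expect_equal(lsm_a$lsmean, lsm_b$lsmean, tolerance = 1e-9)
  expect_equal(lsm_a$se, lsm_b$se, tolerance = 1e-9)

  # block relabeling invariance
  d3 <- ph$records
  d3$block <- paste0("relabel_", d3$block)
  lsm_c <- ls_line_means(d3, "young", "control")
  expect_equal(lsm_a$lsmean, lsm_c$lsmean, tolerance = 1e-12)
})

test_that("LS-means agree with the emmeans oracle", {
  skip_if_not_installed("emmeans")
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  d <- ph$records[ph$records$age == "old" & ph$records$treatment == "treated", ]
  d$line_id <- factor(d$line_id)
  d$block <- factor(d$block)
  lsm <- ls_line_means(ph$records, "old", "treated")
  fit <- lm(value ~ mass_mg + line_id + block, data = d)
  em <- as.data.frame(emmeans::emmeans(fit, "line_id"))
  expect_equal(lsm$lsmean, em$emmean[match(lsm$line_id, em$line_id)],
               tolerance = 1e-10)
  expect_equal(lsm$se, em$SE[match(lsm$line_id, em$line_id)],
               tolerance = 1e-8)
})

test_that("lines absent from a stratum are omitted with a warning", {
  cfg <- tiny_config()
  ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
  d <- ph$records
  d <- d[!(d$line_id == "line_001" & d$age == "young" &
             d$treatment == "control"), ]
  expect_warning(lsm <- ls_line_means(d, "young", "control"),
                 "line_001")
  expect_false("line_001" %in% lsm$line_id)
})

test_that("variance components reproduce the hand ANOVA and truncate at zero", {
  d <- data.frame(line_id = rep(c("l1", "l2"), each = 2), age = "a",
                  treatment = "c", block = "b1", mass_mg = 1,
                  value = c(0, 2, 4, 6))
  v <- variance_components(d, "a", "c")
  expect_equal(v$ms_within, 2)
  expect_equal(v$ms_between, 16)
  expect_equal(v$n0, 2)
  expect_equal(v$sigma2_line, 7)
  expect_equal(v$sigma2_error, 2)

  d$value <- 1
  v0 <- variance_components(d, "a", "c")
  expect_equal(v0$sigma2_line, 0)
  expect_equal(v0$sigma2_error, 0)

  # raw value below zero is retained; reported one truncated
  d2 <- data.frame(line_id = rep(c("l1", "l2", "l3"), each = 3), age = "a",
                   treatment = "c", block = "b1", mass_mg = 1,
                   value = c(0, 10, -10, 1, 11, -9, 2, 12, -8))
  v2 <- variance_components(d2, "a", "c")
  expect_lt(v2$sigma2_line_raw, 0)
  expect_equal(v2$sigma2_line, 0)

  d3 <- data.frame(line_id = c("l1", "l2"), age = "a", treatment = "c",
                   block = "b1", mass_mg = 1, value = c(1, 2))
  expect_error(variance_components(d3, "a", "c"), "singleton")
})

test_that("unbalanced n0 matches its closed form and balanced case equals common n", {
  d <- data.frame(line_id = rep(c("l1", "l2", "l3"), times = c(2, 3, 5)),
                  age = "a", treatment = "c", block = "b1", mass_mg = 1,
                  value = rnorm(10))
  v <- variance_components(d, "a", "c")
  n_i <- c(2, 3, 5); N <- 10; k <- 3
  expect_equal(v$n0, (N - sum(n_i^2) / N) / (k - 1))
})

test_that("variance components recover a simulated among-line variance", {
  # moderate replication: the estimator is unbiased, so the mean over
  # replicates closes on the truth
  ests <- vapply(1:30, function(i) {
    cfg <- sim_config(n_lines = 60, n_flies_per_cell = 10, n_variants = 5,
                      var_line = 1, var_line_by_age = 0,
                      var_line_by_treatment = 0,
                      var_line_by_age_by_treatment = 0, var_block = 0,
                      var_error = 1, n_causal_trait = 0,
                      n_causal_sensitivity = 0, seed = 500L + i)
    ph <- simulate_phenotypes(cfg, simulate_genotypes(cfg))
    variance_components(ph$records, "young", "control")$sigma2_line_raw
  }, numeric(1))
  expect_equal(mean(ests), 1, tolerance = 0.15)
})

test_that("genetic correlation follows its definition and edge cases", {
  means_a <- data.frame(line_id = paste0("l", 1:6), age = "a",
                        treatment = "c", lsmean = c(1, 2, 3, 4, 5, 6))
  means_b <- means_a
  means_b$lsmean <- 2 * means_a$lsmean
  vc_a <- list(age = "a", treatment = "c",
               sigma2_line = var(means_a$lsmean))
  vc_b <- list(age = "a", treatment = "t",
               sigma2_line = var(means_b$lsmean))
  g <- genetic_correlation(means_a, means_b, vc_a, vc_b, label = "rGT1")
  expect_equal(g$r, 1.0)
  expect_equal(g$cov12, cov(means_a$lsmean, means_b$lsmean))
  expect_true(g$defined)

  # zero among-line variance: undefined, not infinite
  vc0 <- list(age = "a", treatment = "c", sigma2_line = 0)
  g0 <- genetic_correlation(means_a, means_b, vc0, vc_b)
  expect_false(g0$defined)
  expect_true(is.na(g0$r))

  # |r| > 1 excursions flagged, not clamped
  vc_small <- list(age = "a", treatment = "c",
                   sigma2_line = var(means_a$lsmean) / 4)
  gx <- genetic_correlation(means_a, means_b, vc_small, vc_b)
  expect_gt(gx$r, 1)
  expect_true(gx$exceeds_unit)

  expect_error(genetic_correlation(means_a[1:2, ], means_b[1:2, ],
                                   vc_a, vc_b), "3 shared lines")
})

test_that("independently shuffled line means decorrelate", {
  set.seed(99)
  rs <- replicate(200, {
    means_a <- data.frame(line_id = paste0("l", 1:20), age = "a",
                          treatment = "c", lsmean = rnorm(20))
    means_b <- means_a
    means_b$lsmean <- sample(means_b$lsmean)
    vc <- list(age = "a", treatment = "c", sigma2_line = 1)
    genetic_correlation(means_a, means_b, vc, vc)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})
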