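#' Simulate individual-fly phenotype records with known genetic architecture
#'
#' Generates one record per fly under the full factorial design
#' (line x age x treatment, `n_flies_per_cell` flies each) following the
#' additive model used for the phenotype analysis:
#'
#' value = constant + age effect + treatment effect + line deviation
#'         + block(age) effect + mass_slope * (mass - mass_mean) + residual
#'
#' The line deviation for a (line, age, treatment) cell is the sum of
#' independent draws for the line main effect and its interactions with age
#' and treatment, at the configured variance components. Planted causal
#' variants contribute additively: trait variants add
#' `causal_effect_size` per alternative allele to the line main effect,
#' sensitivity variants add it to the line x treatment deviation of the
#' treated condition only, so sensitivity loci carry no signal in the control
#' condition. Causal variants are drawn preferentially among variants whose
#' minor genotype class has at least four lines, so planted signal is
#' testable by the association scan.
#'
#' @param config a [sim_config()].
#' @param genotypes a `genotype_table` from [simulate_genotypes()].
#' @param intercept grand constant (trait units, default 10).
#' @param trait trait label stored in the records (default `"trait1"`).
#' @return list with elements
#'   \describe{
#'     \item{records}{data frame of phenotype records: `line_id`, `age`,
#'       `treatment`, `block`, `mass_mg`, `trait`, `value`.}
#'     \item{truth}{ground truth: causal variant ids, per-cell true line
#'       effects, true genetic correlations between strata, and the block
#'       effects used.}
#'   }
#' @export
simulate_phenotypes <- function(config, genotypes, intercept = 10,
                                trait = "trait1") {
  validate_sim_config(config)
  if (missing(genotypes) || !inherits(genotypes, "genotype_table")) {
    stopf("configuration error: `genotypes` must be a genotype_table")
  }
  with_seed(derive_seed(config$seed, "phenotypes"), {
    n_l <- config$n_lines
    lines <- genotypes$lines
    if (length(lines) != n_l) {
      stopf("configuration error: genotype table has %d lines, config expects %d",
            length(lines), n_l)
    }
    ages <- config$ages
    trts <- config$treatments
    treated <- trts[2]

    causal <- pick_causal_variants(config, genotypes)

    # independent deviations per design stratum
    g  <- stats::rnorm(n_l, 0, sqrt(config$var_line))
    if (length(causal$trait)) {
      xs <- genotypes$geno[, causal$trait, drop = FALSE]
      xs[is.na(xs)] <- 0L
      g <- g + as.numeric(xs %*% rep(config$causal_effect_size,
                                     length(causal$trait)))
    }
    ga <- matrix(stats::rnorm(n_l * length(ages), 0,
                              sqrt(config$var_line_by_age)),
                 n_l, length(ages), dimnames = list(lines, ages))
    gt <- matrix(stats::rnorm(n_l * length(trts), 0,
                              sqrt(config$var_line_by_treatment)),
                 n_l, length(trts), dimnames = list(lines, trts))
    if (length(causal$sensitivity)) {
      xs <- genotypes$geno[, causal$sensitivity, drop = FALSE]
      xs[is.na(xs)] <- 0L
      gt[, treated] <- gt[, treated] +
        as.numeric(xs %*% rep(config$causal_effect_size,
                              length(causal$sensitivity)))
    }
    gat <- array(stats::rnorm(n_l * length(ages) * length(trts), 0,
                              sqrt(config$var_line_by_age_by_treatment)),
                 dim = c(n_l, length(ages), length(trts)),
                 dimnames = list(lines, ages, trts))

    # block effects drawn fresh within each age
    nb <- config$n_blocks_per_age
    block_ids <- as.vector(outer(seq_len(nb), ages,
                                 function(b, a) paste0(a, "_b", b)))
    block_eff <- stats::setNames(
      stats::rnorm(length(block_ids), 0, sqrt(config$var_block)), block_ids)

    mass_line <- stats::rnorm(n_l, 0, config$mass_line_sd)

    cells <- expand.grid(line_id = lines, age = ages, treatment = trts,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    li <- match(cells$line_id, lines)
    ai <- match(cells$age, ages)
    ti <- match(cells$treatment, trts)
    cell_gen <- g[li] + ga[cbind(li, ai)] + gt[cbind(li, ti)] +
      gat[cbind(li, ai, ti)]
    age_shift <- c(0, rep_len(config$age_effect, length(ages) - 1))
    cell_fixed <- intercept + age_shift[ai] +
      ifelse(ti == 2, config$treatment_effect, 0)

    nf <- config$n_flies_per_cell
    n_rec <- nrow(cells) * nf
    rec_cell <- rep(seq_len(nrow(cells)), each = nf)
    fly_in_cell <- rep(seq_len(nf), times = nrow(cells))
    block <- paste0(cells$age[rec_cell], "_b", ((fly_in_cell - 1) %% nb) + 1)

    mass <- config$mass_mean + mass_line[li[rec_cell]] +
      stats::rnorm(n_rec, 0, config$mass_sd)
    mass <- pmax(mass, 0.05)

    value <- cell_fixed[rec_cell] + cell_gen[rec_cell] + block_eff[block] +
      config$mass_slope * (mass - config$mass_mean) +
      stats::rnorm(n_rec, 0, sqrt(config$var_error))

    records <- data.frame(
      line_id = cells$line_id[rec_cell],
      age = cells$age[rec_cell],
      treatment = cells$treatment[rec_cell],
      block = block,
      mass_mg = mass,
      trait = trait,
      value = as.numeric(value),
      stringsAsFactors = FALSE
    )

    truth <- list(
      causal_trait_variants = causal$trait,
      causal_sensitivity_variants = causal$sensitivity,
      true_line_effects = data.frame(cells, effect = cell_gen,
                                     stringsAsFactors = FALSE),
      true_genetic_correlations = true_stratum_correlations(cells, cell_gen),
      block_effects = block_eff,
      intercept = intercept
    )
    list(records = records, truth = truth)
  })
}

# Sample causal variant ids, preferring variants whose minor class has >= 4
# lines; trait and sensitivity sets are disjoint.
pick_causal_variants <- function(config, genotypes) {
  need <- config$n_causal_trait + config$n_causal_sensitivity
  if (need == 0) return(list(trait = character(), sensitivity = character()))
  n1 <- colSums(genotypes$geno == 1L, na.rm = TRUE)
  n0 <- colSums(genotypes$geno == 0L, na.rm = TRUE)
  ok <- pmin(n1, n0) >= 4
  pool <- colnames(genotypes$geno)[ok]
  if (length(pool) < need) pool <- colnames(genotypes$geno)
  if (length(pool) < need) {
    stopf("configuration error: %d causal variants requested but only %d variants available",
          need, length(pool))
  }
  ids <- sample(pool, need)
  list(trait = ids[seq_len(config$n_causal_trait)],
       sensitivity = ids[config$n_causal_trait + seq_len(config$n_causal_sensitivity)])
}

# Pearson correlations of true line effects between every pair of
# age x treatment strata.
true_stratum_correlations <- function(cells, cell_gen) {
  strata <- unique(cells[, c("age", "treatment")])
  key <- paste(strata$age, strata$treatment, sep = ":")
  eff <- sapply(seq_len(nrow(strata)), function(k) {
    sel <- cells$age == strata$age[k] & cells$treatment == strata$treatment[k]
    cell_gen[sel]
  })
  colnames(eff) <- key
  pairs <- utils::combn(key, 2)
  data.frame(
    stratum_a = pairs[1, ], stratum_b = pairs[2, ],
    r = apply(pairs, 2, function(p) {
      a <- eff[, p[1]]; b <- eff[, p[2]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
      else stats::cor(a, b)
    }),
    stringsAsFactors = FALSE
  )
}
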