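#' Configuration for the synthetic inbred-panel generator
#'
#' Builds and validates the configuration driving all three synthetic-data
#' generators ([simulate_genotypes()], [simulate_phenotypes()],
#' [simulate_gene_models_and_network()]). Defaults emulate a
#' DGRP-style physical-performance study: 126 fully inbred lines, 30 flies per
#' line x age x treatment cell, two ages, two treatments, rearing blocks
#' nested within age, body mass as a nuisance covariate, and genetic effects
#' on both the trait itself and its sensitivity to treatment.
#'
#' @param n_lines number of inbred lines (default 126).
#' @param n_flies_per_cell flies measured per line x age x treatment cell
#'   (default 30).
#' @param n_variants number of biallelic variants to simulate.
#' @param maf_range length-2 numeric, range of minor-line allele frequencies;
#'   both endpoints in (0, 0.5].
#' @param ages character vector of age labels, in design order.
#' @param treatments character vector of treatment labels; the first is the
#'   control, the second the treated condition.
#' @param n_blocks_per_age rearing/assay blocks within each age.
#' @param var_line,var_line_by_age,var_line_by_treatment,var_line_by_age_by_treatment
#'   variance components (trait units squared) of the line main effect and its
#'   interactions with age and treatment.
#' @param var_block variance of block effects nested within age.
#' @param var_error residual variance among individual flies.
#' @param mass_mean,mass_sd body mass distribution (mg).
#' @param mass_line_sd line-level standard deviation of mean mass (mg); 0
#'   makes mass independent of genotype.
#' @param mass_slope trait units per mg of body mass.
#' @param age_effect additive shift for each age after the first (trait
#'   units); recycled across the non-reference ages.
#' @param treatment_effect additive shift for the treated condition (trait
#'   units); this is the panel-average treatment response.
#' @param n_causal_trait,n_causal_sensitivity numbers of causal variants
#'   planted on the trait (line main effect) and on treatment sensitivity
#'   (line x treatment effect).
#' @param causal_effect_size additive effect per alternative allele (trait
#'   units).
#' @param network_n_genes number of genes in the synthetic interaction graph.
#' @param network_attach_m preferential-attachment parameter (edges added per
#'   new node).
#' @param planted_module_size size of the connected module planted in the
#'   graph; its genes preferentially receive the causal variants.
#' @param seed integer seed making every generator call reproducible.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_lines = 20, n_variants = 100, n_flies_per_cell = 5)
#' cfg$n_lines
#' @export
sim_config <- function(n_lines = 126,
                       n_flies_per_cell = 30,
                       n_variants = 1000,
                       maf_range = c(0.05, 0.5),
                       ages = c("young", "old"),
                       treatments = c("control", "treated"),
                       n_blocks_per_age = 2,
                       var_line = 1,
                       var_line_by_age = 0.3,
                       var_line_by_treatment = 0.3,
                       var_line_by_age_by_treatment = 0.15,
                       var_block = 0.2,
                       var_error = 4,
                       mass_mean = 0.8,
                       mass_sd = 0.08,
                       mass_line_sd = 0,
                       mass_slope = 2,
                       age_effect = -1,
                       treatment_effect = 0.5,
                       n_causal_trait = 5,
                       n_causal_sensitivity = 5,
                       causal_effect_size = 0.5,
                       network_n_genes = 500,
                       network_attach_m = 2,
                       planted_module_size = 15,
                       seed = 1L) {
  cfg <- list(
    n_lines = n_lines, n_flies_per_cell = n_flies_per_cell,
    n_variants = n_variants, maf_range = as.numeric(maf_range),
    ages = as.character(ages), treatments = as.character(treatments),
    n_blocks_per_age = n_blocks_per_age,
    var_line = var_line, var_line_by_age = var_line_by_age,
    var_line_by_treatment = var_line_by_treatment,
    var_line_by_age_by_treatment = var_line_by_age_by_treatment,
    var_block = var_block, var_error = var_error,
    mass_mean = mass_mean, mass_sd = mass_sd, mass_line_sd = mass_line_sd,
    mass_slope = mass_slope,
    age_effect = age_effect, treatment_effect = treatment_effect,
    n_causal_trait = n_causal_trait,
    n_causal_sensitivity = n_causal_sensitivity,
    causal_effect_size = causal_effect_size,
    network_n_genes = network_n_genes,
    network_attach_m = network_attach_m,
    planted_module_size = planted_module_size,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_lines", "n_flies_per_cell", "n_variants", "n_blocks_per_age",
              "network_n_genes", "network_attach_m")) {
    if (!is_count(cfg[[f]])) {
      stopf("configuration error: `%s` must be a positive integer (got %s)",
            f, deparse(cfg[[f]]))
    }
  }
  vars <- c("var_line", "var_line_by_age", "var_line_by_treatment",
            "var_line_by_age_by_treatment", "var_block", "var_error")
  for (f in vars) {
    v <- cfg[[f]]
    if (is.null(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stopf("configuration error: variance component `%s` must be a single finite value >= 0", f)
    }
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || any(!is.finite(mr)) || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5) {
    stopf("configuration error: `maf_range` must lie within (0, 0.5]")
  }
  if (length(cfg$ages) < 1 || anyDuplicated(cfg$ages)) {
    stopf("configuration error: `ages` must be distinct labels")
  }
  if (length(cfg$treatments) != 2 || anyDuplicated(cfg$treatments)) {
    stopf("configuration error: `treatments` must be two distinct labels (control, treated)")
  }
  if (cfg$n_causal_trait + cfg$n_causal_sensitivity > cfg$n_variants) {
    stopf("configuration error: causal variant counts exceed `n_variants`")
  }
  if (cfg$planted_module_size > cfg$network_n_genes) {
    stopf("configuration error: `planted_module_size` exceeds `network_n_genes`")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d lines x %d flies/cell; %d variants (MAF %.2f-%.2f)\n",
              x$n_lines, x$n_flies_per_cell, x$n_variants,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  ages: %s | treatments: %s | %d blocks/age\n",
              paste(x$ages, collapse = ", "),
              paste(x$treatments, collapse = ", "), x$n_blocks_per_age))
  cat(sprintf("  var components (L, LxA, LxT, LxAxT, block, error): %s\n",
              paste(c(x$var_line, x$var_line_by_age, x$var_line_by_treatment,
                      x$var_line_by_age_by_treatment, x$var_block, x$var_error),
                    collapse = ", ")))
  cat(sprintf("  causal: %d trait + %d sensitivity variants, effect %.3g\n",
              x$n_causal_trait, x$n_causal_sensitivity, x$causal_effect_size))
  cat(sprintf("  network: %d genes, m = %d, planted module %d | seed %d\n",
              x$network_n_genes, x$network_attach_m, x$planted_module_size,
              x$seed))
  invisible(x)
}
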