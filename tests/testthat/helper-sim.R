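# Small simulation configurations shared across test files.

tiny_config <- function(...) {
  args <- list(n_lines = 12, n_flies_per_cell = 4, n_variants = 40,
               n_blocks_per_age = 2, n_causal_trait = 2,
               n_causal_sensitivity = 2, network_n_genes = 60,
               planted_module_size = 6, seed = 42L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

# records with every effect switched off: value is purely fixed effects
null_config <- function(...) {
  sim_config(n_lines = 10, n_flies_per_cell = 3, n_variants = 20,
             var_line = 0, var_line_by_age = 0, var_line_by_treatment = 0,
             var_line_by_age_by_treatment = 0, var_block = 0, var_error = 0,
             mass_slope = 0, n_causal_trait = 0, n_causal_sensitivity = 0,
             network_n_genes = 30, planted_module_size = 4, seed = 7L, ...)
}

# two-line, one-block records for hand-checked line-mean examples
toy_records <- function(values, masses = rep(1, length(values)),
                        lines = rep(c("l1", "l2"), each = length(values) / 2)) {
  data.frame(line_id = lines, age = "young", treatment = "control",
             block = "b1", mass_mg = masses, value = values,
             stringsAsFactors = FALSE)
}

# 5-node path graph used by the netperm hand examples
path5 <- function() {
  build_graph(data.frame(from = c("1", "2", "3", "4"),
                         to = c("2", "3", "4", "5")))
}
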