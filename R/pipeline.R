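#' Configuration for an end-to-end analysis run
#'
#' Bundles the thresholds and knobs of the whole pipeline. Inputs either
#' come from a simulation (`sim` is a [sim_config()]) or from files
#' (`paths` is a named list with `genotypes`, `phenotypes`, and optionally
#' `genes` and `network`).
#'
#' @param sim a [sim_config()] used when `paths` is `NULL`.
#' @param paths named list of input files (alternative to simulation).
#' @param candidate_threshold nominal candidate p-value cutoff
#'   (default 1e-5).
#' @param network_threshold stricter cutoff used to pick the genes entering
#'   network analysis (default 1e-6).
#' @param window gene-annotation window in bp, strict (default 5000).
#' @param n_perm network permutations (default 1000).
#' @param min_class minimum minor-class line count per variant (default 4).
#' @param adjust line-mean definition, `"lsmeans"` or `"raw"`.
#' @param run_sensitivity run the sensitivity stages (default `TRUE`).
#' @param seed master seed; per-stage seeds are derived from it by hashing
#'   the stage name.
#' @param outdir output directory.
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(), paths = NULL,
                            candidate_threshold = 1e-5,
                            network_threshold = 1e-6,
                            window = 5000, n_perm = 1000, min_class = 4,
                            adjust = c("lsmeans", "raw"),
                            run_sensitivity = TRUE,
                            seed = 1L, outdir = tempfile("sensigwas_run_")) {
  adjust <- match.arg(adjust)
  for (thr in list(candidate_threshold, network_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      stopf("configuration error: thresholds must lie in (0, 1)")
    }
  }
  if (!is.numeric(window) || window < 0) {
    stopf("configuration error: `window` must be >= 0")
  }
  if (!is_count(n_perm)) stopf("configuration error: `n_perm` must be a positive count")
  if (is.null(paths) && !inherits(sim, "sim_config")) {
    stopf("configuration error: either `sim` or `paths` must be supplied")
  }
  structure(list(
    sim = sim, paths = paths,
    candidate_threshold = candidate_threshold,
    network_threshold = network_threshold,
    window = window, n_perm = n_perm, min_class = min_class,
    adjust = adjust, run_sensitivity = isTRUE(run_sensitivity),
    seed = as.integer(seed), outdir = outdir
  ), class = "analysis_config")
}

#' Run the full drug-response mapping pipeline
#'
#' Executes, in order: data acquisition (simulation or file input),
#' full-design ANCOVA, per-stratum least-squares line means, variance
#' components and genetic correlations, the Falconer sensitivity index per
#' age, single-marker scans (trait per age x treatment; sensitivity with the
#' control trait means as cofactor, per age), candidate calling and
#' gene-window annotation, and — per age — bridged-subnetwork extraction
#' plus the permutation test on the combined control + treated candidate
#' genes (at the stricter network threshold) and on the sensitivity
#' candidates. All outputs are written under `config$outdir` and listed,
#' with checksums and wall-clock per stage, in `manifest.json`.
#'
#' @param config an [analysis_config()].
#' @return list of class `run_manifest`: `config`, per-`stage` seconds,
#'   `outputs` (file -> md5), `results` (in-memory stage results), and the
#'   package `version`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stopf("`config` must come from analysis_config()")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  timings <- c()
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    value
  }

  # --- input data -----------------------------------------------------
  dat <- stage("data", acquire_data(config, out))
  genotypes <- dat$genotypes
  records <- dat$records
  ages <- unique(records$age)
  treatments <- sort_treatments(records$treatment)

  results$ancova <- stage("ancova", {
    tab <- fit_full_ancova(records)
    utils::write.csv(tab, out("ancova.csv"), row.names = FALSE)
    tab
  })

  results$line_means <- stage("line_means", {
    lm_tab <- line_means_all(records, adjust = config$adjust)
    utils::write.csv(lm_tab, out("line_means.csv"), row.names = FALSE)
    lm_tab
  })
  lm_tab <- results$line_means

  results$varcomp <- stage("varcomp", {
    vcs <- list()
    for (a in ages) for (tr in treatments) {
      vcs[[paste(a, tr, sep = ":")]] <- variance_components(records, a, tr)
    }
    vc_df <- do.call(rbind, lapply(vcs, function(v) {
      data.frame(age = v$age, treatment = v$treatment,
                 sigma2_line = v$sigma2_line,
                 sigma2_line_raw = v$sigma2_line_raw,
                 sigma2_error = v$sigma2_error, n0 = v$n0)
    }))
    utils::write.csv(vc_df, out("variance_components.csv"), row.names = FALSE)
    vcs
  })

  results$genetic_correlations <- stage("genetic_correlations", {
    gc <- stratum_correlations(lm_tab, results$varcomp, ages, treatments)
    jsonlite::write_json(
      lapply(gc, function(g) g[c("cov12", "r", "defined", "n_lines",
                                 "stratum_a", "stratum_b")]),
      out("genetic_correlations.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    gc
  })

  sens <- NULL
  if (config$run_sensitivity) {
    sens <- stage("sensitivity", {
      st <- lapply(ages, function(a) {
        sensitivity_index(lm_tab, a, treatments = treatments)
      })
      names(st) <- ages
      all <- do.call(rbind, st)
      utils::write.csv(all, out("sensitivity.csv"), row.names = FALSE)
      st
    })
    results$sensitivity <- sens
  }

  results$scans <- stage("scans", {
    scans <- list()
    for (a in ages) {
      for (tr in treatments) {
        key <- paste("trait", a, tr, sep = ":")
        ph <- lm_tab[lm_tab$age == a & lm_tab$treatment == tr, ]
        scans[[key]] <- run_scan(ph, genotypes, model = "trait",
                                 min_class = config$min_class)
      }
      if (config$run_sensitivity) {
        key <- paste("sensitivity", a, sep = ":")
        cof <- lm_tab[lm_tab$age == a & lm_tab$treatment == treatments[1], ]
        scans[[key]] <- run_scan(sens[[a]], genotypes,
                                 model = "sensitivity_cofactor",
                                 cofactor = cof, min_class = config$min_class)
      }
    }
    for (key in names(scans)) {
      utils::write.table(scans[[key]], out(scan_file(key)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    scans
  })

  results$candidates <- stage("candidates", {
    cands <- lapply(names(results$scans), function(key) {
      cs <- call_candidates(results$scans[[key]],
                            threshold = config$candidate_threshold,
                            label = key)
      if (!is.null(dat$genes)) {
        cs <- annotate_variants(cs, dat$genes, window = config$window)
      }
      utils::write.table(cs$variants, out(paste0("candidates_", scan_file(key))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cs
    })
    names(cands) <- names(results$scans)
    cands
  })

  if (!is.null(dat$genes)) {
    results$overlaps <- stage("overlaps", {
      ov <- lapply(ages, function(a) {
        overlap_summary(results$candidates[[paste("trait", a, treatments[1], sep = ":")]],
                        results$candidates[[paste("trait", a, treatments[2], sep = ":")]])
      })
      names(ov) <- ages
      jsonlite::write_json(ov, out("overlaps.json"), auto_unbox = TRUE,
                           digits = NA)
      ov
    })
  }

  if (!is.null(dat$graph) && !is.null(dat$genes)) {
    results$networks <- stage("networks", {
      run_network_stage(config, dat, results$scans, ages, treatments, out)
    })
  }

  outputs <- list.files(config$outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- structure(list(
    config = config,
    stage_seconds = as.list(timings),
    outputs = as.list(tools::md5sum(outputs)),
    results = results,
    version = as.character(utils::packageVersion("sensigwas"))
  ), class = "run_manifest")
  jsonlite::write_json(list(
    candidate_threshold = config$candidate_threshold,
    network_threshold = config$network_threshold,
    window = config$window, n_perm = config$n_perm,
    min_class = config$min_class, adjust = config$adjust, seed = config$seed,
    stage_seconds = as.list(timings),
    outputs = as.list(tools::md5sum(outputs)),
    version = as.character(utils::packageVersion("sensigwas"))
  ), out("manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

acquire_data <- function(config, out) {
  if (!is.null(config$paths)) {
    p <- config$paths
    genotypes <- read_genotypes(p$genotypes)
    records <- read_phenotypes(p$phenotypes)
    genes <- if (!is.null(p$genes)) read_gene_models(p$genes)
    graph <- if (!is.null(p$network)) build_graph(read_edge_list(p$network))
    return(list(genotypes = genotypes, records = records, genes = genes,
                graph = graph, truth = NULL))
  }
  sim <- config$sim
  genotypes <- simulate_genotypes(sim)
  ph <- simulate_phenotypes(sim, genotypes)
  gn <- simulate_gene_models_and_network(sim, genotypes, ph$truth)
  write_genotypes_tsv(genotypes, out("genotypes.tsv"))
  write_genotypes_vcf(genotypes, out("genotypes.vcf"))
  write_phenotypes(ph$records, out("phenotypes.csv"))
  write_gene_models(gn$genes, out("genes.bed"))
  write_edge_list(gn$graph, out("network.tsv"))
  truth <- c(ph$truth[c("causal_trait_variants", "causal_sensitivity_variants")],
             list(planted_module_genes = gn$truth$planted_module_genes))
  jsonlite::write_json(truth, out("ground_truth.json"), auto_unbox = FALSE)
  list(genotypes = genotypes, records = ph$records, genes = gn$genes,
       graph = gn$graph, truth = c(ph$truth, gn$truth))
}

# per-age networks: combined control+treated trait candidates, and
# sensitivity candidates, both at the stricter network threshold
run_network_stage <- function(config, dat, scans, ages, treatments, out) {
  nets <- list()
  for (a in ages) {
    combos <- list(
      trait = paste("trait", a, treatments, sep = ":"),
      sensitivity = if (config$run_sensitivity) paste("sensitivity", a, sep = ":")
    )
    for (what in names(combos)) {
      keys <- combos[[what]]
      if (is.null(keys)) next
      genes <- unique(unlist(lapply(keys, function(key) {
        cs <- call_candidates(scans[[key]],
                              threshold = config$network_threshold,
                              label = key)
        cs <- annotate_variants(cs, dat$genes, window = config$window)
        cs$genes
      })))
      label <- paste("network", what, a, sep = ":")
      mapped <- intersect(genes, igraph::V(dat$graph)$name)
      if (length(mapped) == 0) {
        nets[[label]] <- list(skipped = "no candidate genes map to the graph")
        next
      }
      sub <- bridged_subnetworks(dat$graph, mapped)
      pt <- permutation_test(dat$graph, n = sub$n_candidates_mapped,
                             observed_size = sub$largest_size,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, label))
      nets[[label]] <- list(subnetworks = sub, perm = pt,
                            candidate_genes = mapped)
      nodes <- do.call(rbind, lapply(sub$components, function(cc) {
        hubs <- classify_hubs(cc)
        data.frame(gene_id = cc$nodes,
                   role = ifelse(cc$candidate, "candidate", "bridge"),
                   degree = hubs$degree[match(cc$nodes, hubs$gene_id)],
                   hub = hubs$hub[match(cc$nodes, hubs$gene_id)])
      }))
      stem <- gsub(":", "_", label)
      utils::write.table(nodes, out(paste0(stem, "_nodes.tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      edges <- do.call(rbind, lapply(sub$components, `[[`, "edges"))
      utils::write.table(edges, out(paste0(stem, "_edges.tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(list(n = pt$n, observed_size = pt$observed_size,
                                n_perm = pt$n_perm, A = pt$A,
                                p_value = pt$p_value, seed = pt$seed),
                           out(paste0(stem, "_summary.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  nets
}

# canonical genetic-correlation labels for the 2-age, 2-treatment design:
# rGT<age> across treatments within an age, rGA<treatment initial> across
# ages within a treatment
stratum_correlations <- function(lm_tab, vcs, ages, treatments) {
  gc <- list()
  slice <- function(a, tr) lm_tab[lm_tab$age == a & lm_tab$treatment == tr, ]
  two_by_two <- length(ages) == 2 && length(treatments) == 2
  for (i in seq_along(ages)) {
    a <- ages[i]
    label <- if (two_by_two) c("rGT1", "rGT5")[i] else paste0("rGT_", a)
    gc[[label]] <- genetic_correlation(
      slice(a, treatments[1]), slice(a, treatments[2]),
      vcs[[paste(a, treatments[1], sep = ":")]],
      vcs[[paste(a, treatments[2], sep = ":")]], label = label)
  }
  if (length(ages) >= 2) {
    for (j in seq_along(treatments)) {
      tr <- treatments[j]
      label <- if (two_by_two) c("rGAC", "rGAL")[j] else paste0("rGA_", tr)
      gc[[label]] <- genetic_correlation(
        slice(ages[1], tr), slice(ages[2], tr),
        vcs[[paste(ages[1], tr, sep = ":")]],
        vcs[[paste(ages[2], tr, sep = ":")]], label = label)
    }
  }
  gc
}

scan_file <- function(key) paste0("scan_", gsub(":", "_", key), ".tsv")

sort_treatments <- function(x) {
  u <- unique(x)
  if (length(u) != 2) stopf("pipeline expects exactly two treatments (got: %s)",
                            paste(u, collapse = ", "))
  # put a label that looks like a control first
  ctrl <- grepl("control|ctrl|untreated", u, ignore.case = TRUE)
  if (any(ctrl)) c(u[ctrl][1], u[!ctrl][1]) else sort(u)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  outdir: %s\n", x$config$outdir))
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s (%.2fs)", names(x$stage_seconds),
                            unlist(x$stage_seconds)), collapse = ", ")))
  cat(sprintf("  outputs: %d files\n", length(x$outputs)))
  invisible(x)
}
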