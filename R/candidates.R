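#' Call candidate variants from a marker scan
#'
#' Selects variants with `p_value` strictly below the nominal threshold
#' (default `1e-5`). Skipped variants never qualify. SNP and indel counts
#' are tallied from the scan's variant metadata.
#'
#' @param scan a `marker_scan` from [run_scan()].
#' @param threshold nominal p-value cutoff; strict inequality (default 1e-5).
#' @param label condition label carried through reports (e.g.
#'   `"old:treated"` or `"sensitivity:old"`).
#' @return object of class `candidate_set`: list with `label`, `threshold`,
#'   `variants` (scan rows passing), `n_variants`, `n_snps`, `n_indels`,
#'   `genes` (filled by [annotate_variants()]), `n_genes`, `variant_genes`.
#' @export
call_candidates <- function(scan, threshold = 1e-5, label = "condition") {
  if (!is.data.frame(scan) || !"p_value" %in% names(scan)) {
    stopf("`scan` must be a marker_scan data frame")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stopf("`threshold` must be in (0, 1]")
  }
  hit <- scan$status == "ok" & !is.na(scan$p_value) & scan$p_value < threshold
  vars <- scan[hit, , drop = FALSE]
  rownames(vars) <- NULL
  structure(list(
    label = label, threshold = threshold,
    variants = vars,
    n_variants = nrow(vars),
    n_snps = sum(vars$type == "snp", na.rm = TRUE),
    n_indels = sum(vars$type == "indel", na.rm = TRUE),
    genes = NULL, n_genes = NA_integer_, variant_genes = NULL,
    window = NA_real_
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %s: %d variants (%d SNPs, %d indels) at p < %g",
              x$label, x$n_variants, x$n_snps, x$n_indels, x$threshold))
  if (!is.null(x$genes)) {
    cat(sprintf("; %d genes within %g bp", x$n_genes, x$window))
  }
  cat("\n")
  invisible(x)
}

#' Annotate candidate variants with nearby genes
#'
#' Maps each candidate variant to every gene it falls inside
#' (`pos` in `[start, end]`, 1-based inclusive) or lies near: the distance
#' from the variant to the closer gene boundary must be strictly less than
#' `window` base pairs (default 5000). A variant may map to several genes
#' and all mappings are kept; the gene list is deduplicated. Variants on
#' chromosomes absent from the gene models are left unannotated with a
#' warning.
#'
#' @param candidates a `candidate_set` from [call_candidates()].
#' @param genes gene models: data frame with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive; see [read_gene_models()] for BED input).
#' @param window strict distance window in bp (default 5000).
#' @return the `candidate_set` with `genes`, `n_genes`, `variant_genes`
#'   (variant -> gene map) and `window` filled in.
#' @examples
#' genes <- data.frame(gene_id = "g1", chrom = "2L",
#'                     start = 10000, end = 12000)
#' sc <- data.frame(variant_id = c("a", "b"), chrom = "2L",
#'                  pos = c(5001, 5000), type = "snp", status = "ok",
#'                  p_value = c(1e-7, 1e-7))
#' cs <- annotate_variants(call_candidates(sc, 1e-5), genes)
#' cs$variant_genes   # variant "a" maps (gap 4999), "b" does not (gap 5000)
#' @export
annotate_variants <- function(candidates, genes, window = 5000) {
  if (!inherits(candidates, "candidate_set")) {
    stopf("`candidates` must be a candidate_set")
  }
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stopf("gene models need columns: %s", paste(need, collapse = ", "))
  }
  if (!is.numeric(window) || window < 0) stopf("`window` must be >= 0")
  vmeta <- candidates$variants
  map <- map_variants_to_genes(vmeta, genes, window)
  unknown <- unique(vmeta$chrom[!(vmeta$chrom %in% genes$chrom)])
  if (length(unknown)) {
    warnf("chromosome(s) absent from gene models, variants left unannotated: %s",
          paste(unknown, collapse = ", "))
  }
  mapped <- map[!is.na(map$gene_id), , drop = FALSE]
  candidates$variant_genes <- mapped
  candidates$genes <- unique(mapped$gene_id)
  candidates$n_genes <- length(candidates$genes)
  candidates$window <- window
  candidates
}

# One row per (variant, gene) hit; variants with no hit get gene_id NA.
# Mapping rule: inside the gene, or boundary gap strictly below `window`.
map_variants_to_genes <- function(vmeta, genes, window) {
  if (nrow(vmeta) == 0) {
    return(data.frame(variant_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(vmeta))
  for (i in seq_len(nrow(vmeta))) {
    g <- genes[genes$chrom == vmeta$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      out[[i]] <- data.frame(variant_id = vmeta$variant_id[i],
                             gene_id = NA_character_, distance = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    pos <- vmeta$pos[i]
    gap <- pmax(g$start - pos, pos - g$end, 0)
    hit <- gap == 0 | gap < window
    if (!any(hit)) {
      out[[i]] <- data.frame(variant_id = vmeta$variant_id[i],
                             gene_id = NA_character_, distance = NA_real_,
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(variant_id = vmeta$variant_id[i],
                             gene_id = g$gene_id[hit],
                             distance = gap[hit], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Overlap report between two candidate gene sets
#'
#' @param set_a,set_b `candidate_set` objects (annotated) or character
#'   vectors of gene ids.
#' @return list with `intersection`, `union`, `only_a`, `only_b` (gene id
#'   vectors) and the corresponding counts `n_intersection`, `n_union`,
#'   `n_only_a`, `n_only_b`.
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- candidate_genes(set_a)
  b <- candidate_genes(set_b)
  list(
    intersection = sort(intersect(a, b)),
    union = sort(union(a, b)),
    only_a = sort(setdiff(a, b)),
    only_b = sort(setdiff(b, a)),
    n_intersection = length(intersect(a, b)),
    n_union = length(union(a, b)),
    n_only_a = length(setdiff(a, b)),
    n_only_b = length(setdiff(b, a))
  )
}

candidate_genes <- function(x) {
  if (inherits(x, "candidate_set")) {
    if (is.null(x$genes)) stopf("candidate set '%s' has not been annotated", x$label)
    unique(x$genes)
  } else {
    unique(as.character(x))
  }
}
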