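#' Simulate gene models and a gene-interaction network with a planted module
#'
#' Genes are tiled along the same synthetic chromosome arms used by
#' [simulate_genotypes()], with variable lengths and intergenic gaps so that
#' window-based variant annotation is exercised (variants fall inside genes,
#' near genes, and in gene deserts). The interaction graph is an undirected
#' scale-free network grown by preferential attachment
#' ([igraph::sample_pa()]), on top of which a connected module of
#' `planted_module_size` genes is planted by adding a random spanning tree
#' plus extra within-module edges (mean intra-module degree about 5,
#' mimicking the dense wiring of a biological pathway). When `genotypes` and
#' `truth` are supplied, gene identities are permuted so genes harbouring the
#' planted causal variants are preferentially placed inside the module.
#'
#' @param config a [sim_config()].
#' @param genotypes optional `genotype_table`; used to place causal variants
#'   inside module genes.
#' @param truth optional ground-truth list from [simulate_phenotypes()]
#'   carrying the causal variant ids.
#' @return list with
#'   \describe{
#'     \item{genes}{data frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'       (1-based inclusive coordinates).}
#'     \item{graph}{an [igraph] undirected simple graph whose vertex names
#'       are gene ids.}
#'     \item{truth}{list with `planted_module_genes` (connected in `graph`)
#'       and `causal_gene_map` (causal variant -> harbouring gene, when
#'       genotypes were supplied).}
#'   }
#' @export
simulate_gene_models_and_network <- function(config, genotypes = NULL,
                                             truth = NULL) {
  validate_sim_config(config)
  if (config$planted_module_size < 2) {
    stopf("configuration error: `planted_module_size` must be at least 2")
  }
  with_seed(derive_seed(config$seed, "genes_network"), {
    n_g <- config$network_n_genes
    m <- config$network_attach_m
    k <- config$planted_module_size

    genes <- tile_gene_models(n_g)

    # scale-free backbone
    g <- igraph::sample_pa(n_g, m = m, directed = FALSE)
    module <- sort(sample.int(n_g, k))
    g <- igraph::add_edges(g, as.vector(t(module_edges(module))))
    g <- igraph::simplify(g)

    # permute gene labels so causal-harbouring genes land in the module
    causal_ids <- c(truth$causal_trait_variants,
                    truth$causal_sensitivity_variants)
    causal_gene_map <- NULL
    label_order <- sample.int(n_g)
    if (!is.null(genotypes) && length(causal_ids)) {
      vmeta <- genotypes$variants[genotypes$variants$variant_id %in% causal_ids, ]
      hit <- map_variants_to_genes(vmeta, genes, window = 0)
      causal_genes <- unique(hit$gene_id[!is.na(hit$gene_id)])
      causal_gene_map <- hit
      gi <- match(causal_genes, genes$gene_id)
      gi <- gi[!is.na(gi)][seq_len(min(length(causal_genes), k))]
      # put causal genes on module vertices, fill the rest randomly
      rest <- setdiff(seq_len(n_g), gi)
      slots <- c(module[seq_along(gi)],
                 sample(setdiff(seq_len(n_g), module[seq_along(gi)])))
      label_order <- integer(n_g)
      label_order[slots] <- c(gi, sample(rest))
    }
    igraph::V(g)$name <- genes$gene_id[label_order]

    list(
      genes = genes,
      graph = g,
      truth = list(
        planted_module_genes = genes$gene_id[label_order][module],
        causal_gene_map = causal_gene_map
      )
    )
  })
}

# Tile n genes across chromosome arms: lengths 0.5-5 kb, gaps 0.2-15 kb.
tile_gene_models <- function(n_g) {
  chroms <- c("2L", "2R", "3L", "3R", "X")
  chrom <- sort(sample(chroms, n_g, replace = TRUE))
  start <- integer(n_g)
  end <- integer(n_g)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    len <- as.integer(stats::runif(length(idx), 500, 5000))
    gap <- as.integer(stats::runif(length(idx), 200, 15000))
    s <- cumsum(gap + c(0L, len[-length(len)]))
    start[idx] <- s + 1L
    end[idx] <- s + len
  }
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n_g)),
             chrom = chrom, start = start, end = end,
             strand = sample(c("+", "-"), n_g, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Random spanning tree over the module plus chords up to mean degree ~5:
# the planted module is a dense subgraph, as in planted-module recovery
# settings and in keeping with the dense wiring of biological pathways.
module_edges <- function(module) {
  k <- length(module)
  perm <- sample(module)
  tree <- cbind(perm[-1], perm[sapply(2:k, function(i) sample.int(i - 1, 1))])
  target_extra <- max(0L, as.integer(round(2.5 * k)) - (k - 1L))
  all_pairs <- t(utils::combn(module, 2))
  in_tree <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
  pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% in_tree), ,
                    drop = FALSE]
  if (target_extra > 0 && nrow(pool) > 0) {
    extra <- pool[sample.int(nrow(pool), min(target_extra, nrow(pool))), ,
                  drop = FALSE]
    rbind(tree, extra)
  } else {
    tree
  }
}
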