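#' Simulate genotypes for a panel of inbred lines
#'
#' Each line is fully inbred, so a biallelic site carries one of two
#' homozygous classes, coded 0 (reference) or 1 (alternative). Per-variant
#' alternative-allele frequencies are drawn uniformly from `maf_range` and
#' lines are sampled independently per site (no linkage disequilibrium).
#' Variants are placed on fly-style chromosome arms with sorted positions and
#' flagged as SNP or indel, so downstream gene-window annotation and
#' SNP/indel tallies are exercised.
#'
#' @param config a [sim_config()].
#' @param prop_indel fraction of variants flagged as indels (default 0.1).
#' @return a `genotype_table`: list with
#'   \describe{
#'     \item{geno}{`n_lines x n_variants` integer matrix of 0/1 codes
#'       (`NA` = missing), rownames line ids, colnames variant ids.}
#'     \item{variants}{data frame with `variant_id`, `chrom`, `pos`
#'       (1-based), `type` ("snp"/"indel"), and the drawn allele frequency
#'       `af`.}
#'     \item{lines}{character vector of line ids.}
#'   }
#' @examples
#' gt <- simulate_genotypes(sim_config(n_lines = 10, n_variants = 50))
#' dim(gt$geno)
#' @export
simulate_genotypes <- function(config, prop_indel = 0.1) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genotypes"), {
    n_l <- config$n_lines
    n_v <- config$n_variants
    lines <- sprintf("line_%03d", seq_len(n_l))

    chroms <- c("2L", "2R", "3L", "3R", "X")
    chrom <- sort(sample(chroms, n_v, replace = TRUE))
    pos <- integer(n_v)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      # span scales with variant count so typical spacing is ~2 kb
      pos[idx] <- sort(sample.int(max(length(idx) * 2000L, 10000L),
                                  length(idx)))
    }
    type <- ifelse(stats::runif(n_v) < prop_indel, "indel", "snp")
    variant_id <- sprintf("%s_%d_%s", chrom, pos, toupper(type))

    af <- stats::runif(n_v, config$maf_range[1], config$maf_range[2])
    geno <- matrix(stats::rbinom(n_l * n_v, 1L, rep(af, each = n_l)),
                   nrow = n_l, ncol = n_v,
                   dimnames = list(lines, variant_id))

    structure(list(
      geno = geno,
      variants = data.frame(variant_id = variant_id, chrom = chrom,
                            pos = pos, type = type, af = af,
                            stringsAsFactors = FALSE),
      lines = lines
    ), class = "genotype_table")
  })
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d lines x %d variants (%d SNPs, %d indels)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$variants$type == "snp"), sum(x$variants$type == "indel")))
  invisible(x)
}
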