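#' Read a line-genotype table
#'
#' Two on-disk formats are supported:
#' \describe{
#'   \item{`tsv`}{the matrix written by [write_genotypes_tsv()]: rows =
#'     variants, columns = `variant_id`, `chrom`, `pos`, `type` then one
#'     column per line with codes 0/1/NA.}
#'   \item{`vcf`}{a VCF with GT fields; only biallelic records are used
#'     (multi-allelic records are skipped with a message). Inbred coding:
#'     `0/0` -> 0, `1/1` -> 1, heterozygous or missing -> `NA`. Requires the
#'     vcfR package.}
#' }
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @return a `genotype_table` (see [simulate_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "type")
  if (!all(need %in% names(d))) {
    stopf("genotype TSV must start with columns: %s", paste(need, collapse = ", "))
  }
  line_cols <- setdiff(names(d), need)
  if (length(line_cols) == 0) stopf("genotype TSV has no line columns")
  geno <- t(as.matrix(d[, line_cols, drop = FALSE]))
  bad <- !(geno %in% c(0L, 1L) | is.na(geno))
  if (any(bad)) {
    stopf("malformed genotype code at data row %d (values must be 0/1/NA)",
          which(bad, arr.ind = TRUE)[1, 2])
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(line_cols, d$variant_id)
  structure(list(
    geno = geno,
    variants = data.frame(variant_id = d$variant_id, chrom = d$chrom,
                          pos = as.integer(d$pos), type = d$type,
                          stringsAsFactors = FALSE),
    lines = line_cols
  ), class = "genotype_table")
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) stopf("no biallelic records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "1/1"] <- 1L
  fix <- fix[keep, , drop = FALSE]
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp", "indel")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- sprintf("%s_%s_%s", fix[noid, "CHROM"], fix[noid, "POS"],
                       toupper(type[noid]))
  geno <- t(code)
  colnames(geno) <- ids
  structure(list(
    geno = geno,
    variants = data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]), type = type,
                          stringsAsFactors = FALSE),
    lines = rownames(geno)
  ), class = "genotype_table")
}

#' Write a genotype table as a TSV matrix
#'
#' Rows are variants (`variant_id`, `chrom`, `pos`, `type`, then one 0/1/NA
#' column per line), the layout read back by [read_genotypes()].
#'
#' @param genotypes a `genotype_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- cbind(genotypes$variants[, c("variant_id", "chrom", "pos", "type")],
             as.data.frame(t(genotypes$geno), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype table as a minimal VCF
#'
#' Biallelic sites with homozygous genotypes only (`0/0`, `1/1`, or `./.`
#' for missing), REF/ALT placeholders A/T for SNPs and A/AT for indels.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt <- t(genotypes$geno)
  gt_chr <- matrix("./.", nrow(gt), ncol(gt))
  gt_chr[gt == 0L] <- "0/0"
  gt_chr[gt == 1L] <- "1/1"
  ref <- ifelse(v$type == "snp", "A", "A")
  alt <- ifelse(v$type == "snp", "T", "AT")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$lines), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, ref, alt, ".", "PASS", ".",
                "GT", apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write phenotype records as CSV
#'
#' Columns: `line_id`, `age`, `treatment`, `block`, `mass_mg`, `trait`,
#' `value`.
#'
#' @param path file path.
#' @return data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_records(d)
  d
}

#' @rdname read_phenotypes
#' @param records phenotype records to write.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write gene models as BED6
#'
#' BED is 0-based half-open on disk; in memory the package uses 1-based
#' inclusive `start`/`end`.
#'
#' @param path BED file.
#' @return data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4) stopf("BED gene models need at least 4 columns")
  data.frame(gene_id = d[[4]], chrom = d[[1]],
             start = as.integer(d[[2]]) + 1L, end = as.integer(d[[3]]),
             strand = if (ncol(d) >= 6) d[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' @rdname read_gene_models
#' @param genes gene-model data frame (1-based inclusive coordinates).
#' @export
write_gene_models <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                    0L, if ("strand" %in% names(genes)) genes$strand else "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write an interaction-network edge list (two-column TSV)
#'
#' @param path TSV file with two columns of gene ids (no header).
#' @return data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("edge list must have two columns")
  stats::setNames(d[, 1:2], c("from", "to"))
}

#' @rdname read_edge_list
#' @param graph an igraph graph or two-column data frame.
#' @export
write_edge_list <- function(graph, path) {
  el <- if (igraph::is_igraph(graph)) {
    igraph::as_edgelist(graph, names = TRUE)
  } else {
    as.matrix(graph[, 1:2])
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
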