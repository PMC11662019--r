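#' Construct gene models
#'
#' Minimal gene annotation used for promoter windows, region annotation and
#' RPKM lengths: one row per gene with its TSS, strand and exon structure.
#' Exons are 0-based half-open and are sorted and must not overlap.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based TSS position per gene.
#' @param exon_starts,exon_ends list of numeric vectors (one per gene), or
#'   comma-separated strings as stored in the TSV representation.
#' @return a `gene_models` data frame with list-columns `exon_starts`,
#'   `exon_ends` and derived columns `span_start`, `span_end`, `length_kb`
#'   (summed exon length in kb).
#' @export
gene_models <- function(gene_id, chrom, strand, tss, exon_starts, exon_ends) {
  parse_list <- function(x) {
    if (is.list(x)) lapply(x, as.numeric)
    else lapply(strsplit(as.character(x), ","), as.numeric)
  }
  es <- parse_list(exon_starts)
  ee <- parse_list(exon_ends)
  n <- length(gene_id)
  stopifnot(length(chrom) == n, length(strand) == n, length(tss) == n,
            length(es) == n, length(ee) == n)
  if (anyDuplicated(gene_id)) stop("duplicated gene_id")
  for (i in seq_len(n)) {
    o <- order(es[[i]])
    es[[i]] <- es[[i]][o]; ee[[i]] <- ee[[i]][o]
    if (length(es[[i]]) == 0 || any(es[[i]] >= ee[[i]]))
      stop("invalid exons for gene ", gene_id[i])
    if (length(es[[i]]) > 1 && any(es[[i]][-1] < ee[[i]][-length(ee[[i]])]))
      stop("overlapping exons for gene ", gene_id[i])
    if (tss[i] < min(es[[i]]) || tss[i] > max(ee[[i]]))
      stop("TSS outside exon span for gene ", gene_id[i])
  }
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  df$exon_starts <- es
  df$exon_ends <- ee
  df$span_start <- vapply(es, min, numeric(1))
  df$span_end <- vapply(ee, max, numeric(1))
  df$length_kb <- mapply(function(s, e) sum(e - s), es, ee) / 1000
  structure(df, class = c("gene_models", "data.frame"))
}

#' Read gene models from a TSV file
#'
#' Expects a headered TSV with columns `gene_id`, `chrom`, `strand`, `tss`,
#' `exon_starts`, `exon_ends` (the last two comma-separated coordinate
#' lists, 0-based half-open).
#'
#' @param path file path.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  if (!all(need %in% names(df))) stop("gene model TSV missing columns")
  gene_models(df$gene_id, df$chrom, df$strand, df$tss,
              df$exon_starts, df$exon_ends)
}

#' Write gene models to TSV
#' @param genes a `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand, tss = genes$tss,
                   exon_starts = vapply(genes$exon_starts, paste, character(1), collapse = ","),
                   exon_ends = vapply(genes$exon_ends, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Promoter windows around TSSs
#'
#' @param genes a `gene_models` object.
#' @param halfwidth window half-width in bp (default 2000, i.e. TSS +/- 2 kb).
#' @return an `interval_set` of clipped-at-zero promoter windows named by gene.
#' @export
promoter_windows <- function(genes, halfwidth = 2000) {
  interval_set(genes$chrom,
               pmax(0, genes$tss - halfwidth),
               genes$tss + halfwidth,
               name = genes$gene_id,
               strand = genes$strand)
}
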