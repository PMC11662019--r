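#' Peak-width quantile thresholds for domain-breadth classification
#'
#' Summary statistics of peak size: the 25/50/75-percentiles of the peak
#' width distribution under linear interpolation between order statistics
#' (`stats::quantile` type 7). In the reference H3K4me3 data these land at
#' roughly Q2 = 2 kb and Q3 = 2.7 kb.
#'
#' @param widths numeric vector of peak widths (bp), all positive.
#' @param type quantile algorithm passed to [stats::quantile()]; default 7
#'   (linear interpolation).
#' @return a `breadth_thresholds` list with `q1`, `q2`, `q3`, `source_n`.
#' @export
compute_breadth_thresholds <- function(widths, type = 7) {
  widths <- as.numeric(widths)
  if (length(widths) < 4) stop("too few peaks: need at least 4 widths")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("widths must be positive and finite")
  q <- stats::quantile(widths, c(0.25, 0.5, 0.75), names = FALSE, type = type)
  structure(list(q1 = q[1], q2 = q[2], q3 = q[3], source_n = length(widths)),
            class = "breadth_thresholds")
}

#' @export
print.breadth_thresholds <- function(x, ...) {
  cat(sprintf("breadth thresholds from %d peaks: Q1=%.1f Q2=%.1f Q3=%.1f bp\n",
              x$source_n, x$q1, x$q2, x$q3))
  invisible(x)
}

#' Classify peaks as broad, medium or narrow domains
#'
#' Exhaustive three-way partition on peak width: width >= Q3 is broad
#' (the top quartile), Q2 <= width < Q3 is medium, width < Q2 is narrow.
#'
#' @param peaks an `interval_set` of peaks.
#' @param thresholds a `breadth_thresholds` object from
#'   [compute_breadth_thresholds()].
#' @return a `breadth_classification` list: `class` (factor broad/medium/
#'   narrow, one per peak), `width`, and the `thresholds` used.
#' @export
classify_breadth <- function(peaks, thresholds) {
  stopifnot(inherits(thresholds, "breadth_thresholds"))
  w <- interval_width(peaks)
  cls <- ifelse(w >= thresholds$q3, "broad",
                ifelse(w >= thresholds$q2, "medium", "narrow"))
  structure(list(class = factor(cls, levels = c("broad", "medium", "narrow")),
                 width = w, thresholds = thresholds),
            class = "breadth_classification")
}

#' Annotate peaks by genomic region
#'
#' Assigns each peak exactly one coarse label with precedence
#' promoter > gene_body > intergenic: a peak overlapping any TSS +/-
#' `promoter_halfwidth` window is a promoter peak; otherwise one
#' overlapping any gene span (min exon start to max exon end) is gene_body;
#' otherwise intergenic. When exon structure is present a finer `detail`
#' label distinguishes exon from intron within gene bodies.
#'
#' @param peaks an `interval_set`.
#' @param genes a `gene_models` object.
#' @param promoter_halfwidth promoter window half-width (bp), default 2000.
#' @return a data frame with one row per peak: `label` (factor promoter/
#'   gene_body/intergenic) and `detail` (promoter/exon/intron/intergenic).
#' @export
annotate_region <- function(peaks, genes, promoter_halfwidth = 2000) {
  n <- nrow(peaks)
  prom <- promoter_windows(genes, promoter_halfwidth)
  in_prom <- intersect_intervals(peaks, prom, "count") > 0
  spans <- interval_set(genes$chrom, genes$span_start, genes$span_end)
  in_gene <- intersect_intervals(peaks, spans, "count") > 0
  exons <- interval_set(rep(genes$chrom, lengths(genes$exon_starts)),
                        unlist(genes$exon_starts), unlist(genes$exon_ends))
  in_exon <- intersect_intervals(peaks, exons, "count") > 0
  label <- ifelse(in_prom, "promoter",
                  ifelse(in_gene, "gene_body", "intergenic"))
  detail <- ifelse(in_prom, "promoter",
                   ifelse(in_gene & in_exon, "exon",
                          ifelse(in_gene, "intron", "intergenic")))
  data.frame(label = factor(label, levels = c("promoter", "gene_body", "intergenic")),
             detail = detail, stringsAsFactors = FALSE)
}

#' Log2 ratios of per-category counts against a reference
#'
#' `log2((obs + 1) / (ref + 1))` per category, the pseudocount keeping
#' ratios finite for empty categories. Used for genomic-distribution
#' comparisons of one peak set against a reference set.
#'
#' @param counts_obs,counts_ref named numeric vectors over identical
#'   category keys.
#' @param pseudocount added to both numerator and denominator; default 1.
#' @return named numeric vector of log2 ratios.
#' @export
distribution_log2_ratio <- function(counts_obs, counts_ref, pseudocount = 1) {
  if (is.null(names(counts_obs)) || is.null(names(counts_ref)) ||
      !setequal(names(counts_obs), names(counts_ref)) ||
      length(counts_obs) != length(counts_ref))
    stop("counts_obs and counts_ref must share the same category keys")
  ref <- counts_ref[names(counts_obs)]
  log2((counts_obs + pseudocount) / (ref + pseudocount))
}

#' Test a breadth-class shift between two peak sets
#'
#' Builds the 2x2 table (focus class vs rest) x (set A vs set B) and
#' returns the two-tailed Fisher exact p-value.
#'
#' @param classA,classB `breadth_classification` objects.
#' @param focus the class tested for enrichment (`"broad"`, `"medium"` or
#'   `"narrow"`).
#' @return list with the 2x2 `table` and the `p.value`.
#' @export
breadth_shift_test <- function(classA, classB, focus = "broad") {
  stopifnot(inherits(classA, "breadth_classification"),
            inherits(classB, "breadth_classification"))
  a <- classA$class; b <- classB$class
  if (length(a) == 0 || length(b) == 0) stop("empty classification")
  focus <- match.arg(focus, levels(a))
  tab <- matrix(c(sum(a == focus), sum(a != focus),
                  sum(b == focus), sum(b != focus)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c(focus, "rest")))
  list(table = tab, p.value = fisher_exact_2x2(tab))
}
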