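#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The two-tailed p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (the probability-mass convention, as in
#' [stats::fisher.test()]).
#'
#' @param t a 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` read row-wise.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  if (!is.matrix(t)) t <- matrix(as.numeric(t), 2, 2, byrow = TRUE)
  if (!all(dim(t) == c(2, 2))) stop("need a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (sum(t) == 0) stop("at least one margin must be positive")
  stats::fisher.test(t, alternative = "two.sided")$p.value
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = counts / (length_kb * library_size / 1e6)`, linear in counts and
#' inverse-linear in library size.
#'
#' @param counts per-gene read counts.
#' @param lengths_kb per-gene summed exon length in kb (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths_kb, library_size) {
  if (any(lengths_kb <= 0)) stop("gene length must be positive")
  if (length(library_size) != 1 || library_size <= 0)
    stop("library_size must be a single positive number")
  counts / (lengths_kb * library_size / 1e6)
}

#' Classify genes by log2 fold change
#'
#' Down-regulated when `log2fc <= -cutoff`, up-regulated when
#' `log2fc >= cutoff` (boundaries inclusive), otherwise unchanged. The
#' default cutoff 0.58 corresponds to a 1.5-fold change.
#'
#' @param log2fc numeric vector of finite log2 fold changes.
#' @param cutoff non-negative threshold; default 0.58.
#' @return factor with levels `up`, `down`, `unchanged`.
#' @export
classify_de <- function(log2fc, cutoff = 0.58) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  cls <- ifelse(log2fc <= -cutoff, "down",
                ifelse(log2fc >= cutoff, "up", "unchanged"))
  factor(cls, levels = c("up", "down", "unchanged"))
}

#' Percentage of a total, rounded half-up to one decimal
#'
#' @param part,total counts with `0 <= part <= total`, `total > 0`.
#' @return `100 * part / total` rounded half-up to one decimal place.
#' @export
percent_of_total <- function(part, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(part < 0) || any(part > total)) stop("need 0 <= part <= total")
  floor(1000 * part / total + 0.5) / 10
}

#' Mean signal profile around a set of anchors
#'
#' Averages a step-function signal track (bedGraph intervals; uncovered
#' bases count as 0) in uniform bins around anchor points, flipping
#' minus-strand anchors so that downstream is positive.
#'
#' @param signal an `interval_set` whose `score` column holds the track
#'   value over each interval (bedGraph semantics).
#' @param anchors a data frame with columns `chrom`, `pos` (0-based
#'   reference point) and optional `strand`.
#' @param half_window profile half-width (bp).
#' @param bin bin width (bp); must divide `2 * half_window`.
#' @return an `aggregate_profile` data frame with `offset` (bin start
#'   relative to the anchor, bp) and `mean_signal`.
#' @export
aggregate_profile <- function(signal, anchors, half_window = 2000, bin = 10) {
  if ((2 * half_window) %% bin != 0) stop("bin must divide 2*half_window")
  nb <- 2 * half_window / bin
  offsets <- seq(-half_window, half_window - bin, by = bin)
  if (is.null(anchors$strand)) anchors$strand <- "+"
  acc <- matrix(0, nrow(anchors), nb)
  sig <- as.data.frame(signal)
  sig_by_chr <- split(sig, sig$chrom)
  for (i in seq_len(nrow(anchors))) {
    s <- sig_by_chr[[anchors$chrom[i]]]
    lo <- anchors$pos[i] - half_window
    starts <- lo + (seq_len(nb) - 1) * bin
    vals <- numeric(nb)
    if (!is.null(s) && nrow(s)) {
      for (j in seq_len(nb)) {
        ov <- pmin(s$end, starts[j] + bin) - pmax(s$start, starts[j])
        hit <- ov > 0
        if (any(hit)) vals[j] <- sum(ov[hit] * s$score[hit]) / bin
      }
    }
    if (anchors$strand[i] == "-") vals <- rev(vals)
    acc[i, ] <- vals
  }
  structure(data.frame(offset = offsets, mean_signal = colMeans(acc)),
            class = c("aggregate_profile", "data.frame"))
}

#' Row-wise z-score matrix
#'
#' Standardizes each row (factor) across columns (classes) to mean 0 and
#' sample standard deviation 1 (n - 1 denominator).
#'
#' @param values numeric matrix (or data frame) with at least 2 columns.
#' @return matrix of z-scores with the input dimnames.
#' @export
zscore_matrix <- function(values) {
  m <- as.matrix(values)
  if (ncol(m) < 2) stop("need at least 2 columns")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    nm <- if (!is.null(rownames(m))) rownames(m)[bad] else as.character(bad)
    stop("zero standard deviation in row ", nm)
  }
  (m - mu) / sdv
}

#' Two-sample location tests
#'
#' Two-tailed Student/Welch t-test or Wilcoxon rank-sum test; the Wilcoxon
#' p-value is exact when the combined sample size is at most 25 and there
#' are no ties.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param kind `"t_two_tailed"` or `"wilcoxon_two_tailed"`.
#' @return the p-value.
#' @export
rank_tests <- function(x, y, kind = c("t_two_tailed", "wilcoxon_two_tailed")) {
  kind <- match.arg(kind)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (kind == "t_two_tailed") {
    if (stats::sd(c(x, y)) == 0) stop("degenerate variance: all values equal")
    return(stats::t.test(x, y, alternative = "two.sided")$p.value)
  }
  exact <- (length(x) + length(y)) <= 25 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value)
}
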