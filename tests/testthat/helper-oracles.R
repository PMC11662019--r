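# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval/statistics code paths.

# per-base occupancy merge on a single toy chromosome
occupancy_merge <- function(starts, ends, max_gap, chrom_len = 1000) {
  cov <- logical(chrom_len)
  for (i in seq_along(starts)) cov[(starts[i] + 1):ends[i]] <- TRUE
  if (max_gap > 0) {
    r <- rle(cov)
    idx <- which(!r$values & r$lengths <= max_gap)
    # only internal gaps (flanked by covered runs) are closed
    idx <- idx[idx > 1 & idx < length(r$values)]
    pos <- cumsum(r$lengths)
    for (j in idx) cov[(pos[j] - r$lengths[j] + 1):pos[j]] <- TRUE
  }
  r <- rle(cov)
  ends_r <- cumsum(r$lengths)
  starts_r <- ends_r - r$lengths
  keep <- r$values
  data.frame(start = starts_r[keep], end = ends_r[keep])
}

# per-base overlap counts of each a-interval against set b
occupancy_overlap_counts <- function(a_start, a_end, b_start, b_end) {
  vapply(seq_along(a_start), function(i) {
    sum(vapply(seq_along(b_start), function(j) {
      min(a_end[i], b_end[j]) - max(a_start[i], b_start[j]) > 0
    }, logical(1)))
  }, integer(1))
}

# two-tailed Fisher p by full hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive per-position G4 run scoring: recompute the run length at each base
g4_naive <- function(seq) {
  ch <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(ch)
  vapply(seq_len(n), function(i) {
    if (!ch[i] %in% c("G", "C")) return(0L)
    lo <- i
    while (lo > 1 && ch[lo - 1] == ch[i]) lo <- lo - 1
    hi <- i
    while (hi < n && ch[hi + 1] == ch[i]) hi <- hi + 1
    L <- as.integer(min(hi - lo + 1, 4L))
    if (ch[i] == "G") L else -L
  }, integer(1))
}

# exhaustive scan for the ROSE cutoff on the min-max scaled ranked curve
rose_cutoff_scan <- function(net) {
  n <- length(net)
  s <- sort(net)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- if (max(s) > min(s)) (s - min(s)) / (max(s) - min(s)) else rep(0, n)
  hit <- NA_integer_
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) > 1) { hit <- i; break }
  }
  if (is.na(hit)) max(net) else s[hit]
}

# random complement of a DNA string for antisymmetry checks
revcomp_chr <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# small, fast synthetic configuration for dataset-level tests
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_chroms = 1, chrom_length = 1.5e6,
                   n_genes = 40, n_k4me3_peaks = 60, n_se = 8, n_tye = 50,
                   n_loops = 30, n_background_pairs = 100,
                   n_mirna_promoter_peaks = 10, ...)
}

random_interval_df <- function(n, chrom_len = 1000) {
  start <- sample(0:(chrom_len - 2), n, replace = TRUE)
  width <- sample(1:50, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + width, chrom_len))
}
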