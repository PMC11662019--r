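#' Stitch enhancer constituents into candidate enhancers
#'
#' ROSE-style stitching: constituent peaks within `stitch_distance` bp of
#' each other are merged into one stitched enhancer; each stitched region
#' records its constituents. When `tss_windows` is given, constituents
#' falling fully inside a TSS window are excluded before stitching (the
#' ROSE TSS exclusion; off by default, matching ROSE default settings).
#'
#' @param peaks an `interval_set` of constituent (H3K27ac) peaks.
#' @param stitch_distance maximum gap (bp) between stitched constituents;
#'   default 12500 (the ROSE default).
#' @param tss_windows optional `interval_set` of promoter windows for
#'   constituent exclusion.
#' @return a `stitched_enhancers` data frame: `chrom`, `start`, `end`,
#'   `n_constituents`, and the list-column `constituents` (a data frame of
#'   constituent coordinates per stitched region).
#' @export
stitch_enhancers <- function(peaks, stitch_distance = 12500, tss_windows = NULL) {
  if (nrow(peaks) == 0) stop("no constituent peaks to stitch")
  if (!is.null(tss_windows) && nrow(tss_windows) > 0) {
    pg <- as_granges(peaks)
    tg <- as_granges(tss_windows)
    inside <- GenomicRanges::countOverlaps(pg, tg, type = "within") > 0
    peaks <- as_interval_set(as.data.frame(peaks)[!inside, , drop = FALSE])
    if (nrow(peaks) == 0) stop("all constituents excluded by TSS windows")
  }
  stitched <- merge_intervals(peaks, max_gap = stitch_distance)
  hits <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(stitched))
  idx <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  pk <- as.data.frame(peaks)
  out <- as.data.frame(stitched)[, c("chrom", "start", "end")]
  out$n_constituents <- 0L
  constituents <- vector("list", nrow(out))
  for (k in seq_len(nrow(out))) {
    i <- idx[[as.character(k)]]
    constituents[[k]] <- pk[sort(i), c("chrom", "start", "end"), drop = FALSE]
    out$n_constituents[k] <- length(i)
  }
  out$constituents <- constituents
  structure(out, class = c("stitched_enhancers", "data.frame"))
}

#' Sum a signal track over stitched enhancers
#'
#' Background-subtracted enhancer signal in the ROSE sense: the summed
#' (value x covered width) of a bedGraph track over each stitched region,
#' minus the same quantity for an optional control track, floored at 0.
#'
#' @param enhancers a `stitched_enhancers` object.
#' @param signal an `interval_set` with bedGraph values in `score`.
#' @param control optional background track of the same form.
#' @return numeric vector of net signals, one per enhancer.
#' @export
enhancer_signal <- function(enhancers, signal, control = NULL) {
  sum_track <- function(track) {
    if (is.null(track) || nrow(track) == 0) return(numeric(nrow(enhancers)))
    eg <- GenomicRanges::GRanges(enhancers$chrom,
                                 IRanges::IRanges(enhancers$start + 1, enhancers$end))
    tg <- as_granges(track)
    hits <- GenomicRanges::findOverlaps(eg, tg)
    if (length(hits) == 0) return(numeric(nrow(enhancers)))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(enhancers$end[qi], track$end[si]) -
      pmax(enhancers$start[qi], track$start[si])
    out <- numeric(nrow(enhancers))
    agg <- tapply(ov * track$score[si], qi, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  pmax(sum_track(signal) - sum_track(control), 0)
}

#' Rank enhancers and place the hockey-stick super-enhancer cutoff
#'
#' Enhancers are sorted by ascending net signal and both axes are min-max
#' scaled to `[0, 1]`. Scanning ascending, the cutoff is the first point at
#' which the discrete slope between adjacent scaled points exceeds 1 (the
#' tangent-slope geometry of the ranked-signal "hockey stick"); enhancers
#' with net signal strictly above the cutoff signal are super-enhancers.
#'
#' @param enhancers a `stitched_enhancers` object.
#' @param signal per-enhancer treatment signal (same order as `enhancers`).
#' @param control optional per-enhancer background signal, subtracted and
#'   floored at 0.
#' @return a `rose_ranking` list: the `enhancers` data frame augmented with
#'   `signal` (net), `rank` (1 = highest signal) and `is_super`; `cutoff`
#'   (list with `cutoff_signal`, `cutoff_rank`); and `curve`, the
#'   hockey-stick table (`rank_scaled`, `signal_scaled`, `is_super`) in
#'   ascending-signal order.
#' @export
rank_and_cutoff <- function(enhancers, signal, control = NULL) {
  n <- nrow(enhancers)
  if (n < 3) stop("need at least 3 enhancers to place a cutoff")
  if (length(signal) != n) stop("signal length must match enhancers")
  if (any(!is.finite(signal))) stop("signal must be finite")
  net <- if (is.null(control)) signal else pmax(signal - control, 0)
  if (all(net == 0)) stop("degenerate ranking: all net signals are zero")
  o <- order(net)
  s <- net[o]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- if (max(s) > min(s)) (s - min(s)) / (max(s) - min(s)) else rep(0, n)
  slope <- diff(y) / diff(x)
  first <- which(slope > 1)[1]
  if (is.na(first)) {
    cutoff_signal <- max(net)
    cutoff_rank <- NA_integer_
  } else {
    cutoff_signal <- s[first]
    cutoff_rank <- first
  }
  is_super_sorted <- s > cutoff_signal
  df <- as.data.frame(enhancers)
  df$signal <- net
  df$rank <- rank(-net, ties.method = "first")
  df$is_super <- net > cutoff_signal
  curve <- data.frame(rank_scaled = x, signal_scaled = y,
                      is_super = is_super_sorted)
  structure(list(enhancers = structure(df, class = c("stitched_enhancers", "data.frame")),
                 cutoff = list(cutoff_signal = cutoff_signal,
                               cutoff_rank = cutoff_rank),
                 curve = curve),
            class = "rose_ranking")
}

#' @export
print.rose_ranking <- function(x, ...) {
  cat(sprintf("ROSE ranking: %d enhancers, %d super-enhancers (cutoff signal %.4g)\n",
              nrow(x$enhancers), sum(x$enhancers$is_super),
              x$cutoff$cutoff_signal))
  invisible(x)
}

#' Classify enhancer size strata
#'
#' Splits super-enhancers (SE) and typical enhancers (TYE) by stitched
#' width: SE broad > 3.2 kb, SE medium 2.3-3.2 kb, SE narrow < 2.3 kb;
#' TYE broad > 0.9 kb, TYE medium 0.6-0.9 kb, TYE narrow < 0.6 kb
#' (lower stratum bounds inclusive).
#'
#' @param enhancers a `stitched_enhancers` data frame carrying `is_super`.
#' @return the input with a `size_class` factor column added.
#' @export
classify_enhancer_size <- function(enhancers) {
  if (is.null(enhancers$is_super)) stop("run rank_and_cutoff first")
  w <- enhancers$end - enhancers$start
  se <- enhancers$is_super
  cls <- ifelse(se,
                ifelse(w > 3200, "SE_broad", ifelse(w >= 2300, "SE_medium", "SE_narrow")),
                ifelse(w > 900, "TYE_broad", ifelse(w >= 600, "TYE_medium", "TYE_narrow")))
  enhancers$size_class <- factor(cls, levels = c("SE_broad", "SE_medium", "SE_narrow",
                                                 "TYE_broad", "TYE_medium", "TYE_narrow"))
  enhancers
}

#' Mark enhancers by miRNA occupancy peaks
#'
#' An enhancer is miRNA-marked when at least one miRNA occupancy peak
#' shares at least one base with one of its constituent peaks (default),
#' or with the full stitched span when `on = "span"`.
#'
#' @param enhancers a `stitched_enhancers` data frame.
#' @param mirna_peaks an `interval_set` of miRNA occupancy peaks.
#' @param on `"constituents"` (default) or `"span"`.
#' @return the input with a logical `mirna_marked` column added.
#' @export
mark_by_mirna <- function(enhancers, mirna_peaks, on = c("constituents", "span")) {
  on <- match.arg(on)
  n <- nrow(enhancers)
  if (nrow(mirna_peaks) == 0) {
    enhancers$mirna_marked <- rep(FALSE, n)
    return(enhancers)
  }
  if (on == "span") {
    span <- interval_set(enhancers$chrom, enhancers$start, enhancers$end)
    enhancers$mirna_marked <- intersect_intervals(span, mirna_peaks, "count") > 0
  } else {
    cons <- do.call(rbind, enhancers$constituents)
    which_enh <- rep(seq_len(n), vapply(enhancers$constituents, nrow, integer(1)))
    cset <- interval_set(cons$chrom, cons$start, cons$end)
    hit <- intersect_intervals(cset, mirna_peaks, "count") > 0
    enhancers$mirna_marked <- seq_len(n) %in% which_enh[hit]
  }
  enhancers
}

#' Marking-enrichment test between SE and TYE classes
#'
#' Percent of marked enhancers per class and the two-tailed Fisher exact
#' p-value on the 2x2 marked/unmarked x SE/TYE table.
#'
#' @param se_marked,se_total,tye_marked,tye_total counts with
#'   `marked <= total` per class.
#' @return list with `se_pct`, `tye_pct` (one decimal), the `table` and
#'   the Fisher `p.value`.
#' @export
marking_enrichment_test <- function(se_marked, se_total, tye_marked, tye_total) {
  if (se_total == 0 || tye_total == 0) stop("class totals must be positive")
  if (se_marked > se_total || tye_marked > tye_total) stop("marked > total")
  tab <- matrix(c(se_marked, se_total - se_marked,
                  tye_marked, tye_total - tye_marked),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("SE", "TYE"), c("marked", "unmarked")))
  list(se_pct = percent_of_total(se_marked, se_total),
       tye_pct = percent_of_total(tye_marked, tye_total),
       table = tab,
       p.value = fisher_exact_2x2(tab))
}

#' Write ROSE-style output tables
#'
#' Emits the full ranked table (all stitched enhancers), the SE subset and
#' the hockey-stick curve table as TSV files.
#'
#' @param ranking a `rose_ranking` object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_rose_tables <- function(ranking, dir, prefix = "rose") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(ranking$enhancers)
  df$constituents <- NULL
  df <- df[order(df$rank), ]
  p1 <- file.path(dir, paste0(prefix, "_all_enhancers.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_superenhancers.tsv"))
  p3 <- file.path(dir, paste0(prefix, "_hockey_stick.tsv"))
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(df[df$is_super, ], p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ranking$curve, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
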