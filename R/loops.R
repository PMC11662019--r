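#' Read chromatin interaction pairs
#'
#' Parses a BEDPE-like 7-column TSV (`chrom1 start1 end1 chrom2 start2
#' end2 frequency`), 0-based half-open anchors.
#'
#' @param path file path.
#' @param condition optional condition label attached to every pair.
#' @return an `interaction_pairs` data frame.
#' @export
read_pairs <- function(path, condition = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 7)
    df <- data.frame(V1 = character(), V2 = numeric(), V3 = numeric(),
                     V4 = character(), V5 = numeric(), V6 = numeric(),
                     V7 = numeric())
  names(df)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "frequency")
  interaction_pairs(df$chrom1, df$start1, df$end1,
                    df$chrom2, df$start2, df$end2,
                    df$frequency, condition)
}

#' Construct interaction pairs
#'
#' Pairs are unordered: anchors are canonicalized so that anchor1 sorts
#' before anchor2 by (chrom, start).
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 anchor coordinates
#'   (0-based half-open).
#' @param frequency non-negative interaction counts.
#' @param condition condition label (recycled).
#' @return an `interaction_pairs` data frame.
#' @export
interaction_pairs <- function(chrom1, start1, end1, chrom2, start2, end2,
                              frequency, condition = NA_character_) {
  if (any(frequency < 0)) stop("frequency must be non-negative")
  if (any(start1 >= end1) || any(start2 >= end2)) stop("start >= end in anchor")
  swap <- chrom2 < chrom1 | (chrom1 == chrom2 & start2 < start1)
  df <- data.frame(
    chrom1 = ifelse(swap, chrom2, chrom1),
    start1 = ifelse(swap, start2, start1),
    end1 = ifelse(swap, end2, end1),
    chrom2 = ifelse(swap, chrom1, chrom2),
    start2 = ifelse(swap, start1, start2),
    end2 = ifelse(swap, end1, end2),
    frequency = as.numeric(frequency),
    condition = rep_len(as.character(condition), length(chrom1)),
    stringsAsFactors = FALSE)
  structure(df, class = c("interaction_pairs", "data.frame"))
}

#' Write interaction pairs as BEDPE-like TSV
#' @param pairs an `interaction_pairs` object.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs)[, c("chrom1", "start1", "end1",
                                              "chrom2", "start2", "end2",
                                              "frequency")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Snap interaction anchors to fixed-resolution bins
#'
#' Each anchor becomes the bin `[floor(start/res)*res, +res)` containing
#' its start; frequencies of coincident binned pairs (per condition) are
#' summed. Total frequency is conserved.
#'
#' @param pairs an `interaction_pairs` object.
#' @param resolution bin size in bp (> 0); default 25000.
#' @return binned `interaction_pairs`.
#' @export
bin_pairs <- function(pairs, resolution = 25000) {
  if (resolution <= 0) stop("resolution must be positive")
  if (nrow(pairs) == 0) return(pairs)
  b1 <- floor(pairs$start1 / resolution) * resolution
  b2 <- floor(pairs$start2 / resolution) * resolution
  p <- interaction_pairs(pairs$chrom1, b1, b1 + resolution,
                         pairs$chrom2, b2, b2 + resolution,
                         pairs$frequency, pairs$condition)
  key <- paste(p$chrom1, p$start1, p$chrom2, p$start2, p$condition, sep = "\r")
  agg <- rowsum(p$frequency, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- p[first, , drop = FALSE]
  out$frequency <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  rownames(out) <- NULL
  structure(out, class = c("interaction_pairs", "data.frame"),
            resolution = resolution)
}

#' Build interaction hubs from binned pairs
#'
#' One hub per distinct anchor bin; its total frequency sums the
#' frequencies of every pair touching the bin, counting self-pairs
#' (both anchors in the bin) once.
#'
#' @param pairs binned `interaction_pairs` (one condition).
#' @param condition condition label recorded on the hubs; defaults to the
#'   pairs' condition.
#' @return an `anchor_hubs` data frame: `chrom`, `start`, `end`,
#'   `total_frequency`, `condition`.
#' @export
build_hubs <- function(pairs, condition = NULL) {
  if (is.null(condition))
    condition <- if (nrow(pairs)) pairs$condition[1] else NA_character_
  if (nrow(pairs) == 0) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), total_frequency = numeric(),
                                condition = character()),
                     class = c("anchor_hubs", "data.frame")))
  }
  self <- pairs$chrom1 == pairs$chrom2 & pairs$start1 == pairs$start2
  anc <- rbind(
    data.frame(chrom = pairs$chrom1, start = pairs$start1, end = pairs$end1,
               frequency = pairs$frequency, stringsAsFactors = FALSE),
    data.frame(chrom = pairs$chrom2[!self], start = pairs$start2[!self],
               end = pairs$end2[!self], frequency = pairs$frequency[!self],
               stringsAsFactors = FALSE))
  key <- paste(anc$chrom, anc$start, sep = "\r")
  agg <- rowsum(anc$frequency, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- anc[first, c("chrom", "start", "end"), drop = FALSE]
  out$total_frequency <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  out$condition <- condition
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("anchor_hubs", "data.frame"))
}

#' Filter hubs by frequency and normalize to the retained-set mean
#'
#' Hubs with total frequency at or above `min_frequency` are retained and
#' their frequencies divided by the mean over the retained set, so that
#' normalized frequencies average exactly 1.
#'
#' @param hubs an `anchor_hubs` data frame.
#' @param min_frequency retention threshold; default 10.
#' @return retained hubs with a `normalized_frequency` column.
#' @export
filter_normalize_hubs <- function(hubs, min_frequency = 10) {
  keep <- hubs$total_frequency >= min_frequency
  if (!any(keep)) stop("empty hub set after filtering")
  out <- hubs[keep, , drop = FALSE]
  out$normalized_frequency <- out$total_frequency / mean(out$total_frequency)
  rownames(out) <- NULL
  out
}

#' Down-sample interaction events without replacement
#'
#' Draws `target_total` interaction events from the pooled events of all
#' pairs (multivariate hypergeometric, proportional to frequency), so the
#' output frequencies sum exactly to the target. Deterministic per seed.
#'
#' @param pairs an `interaction_pairs` object with integer frequencies.
#' @param target_total number of events to keep; at most the total.
#' @param seed RNG seed.
#' @return the pairs with down-sampled frequencies.
#' @export
downsample_pairs <- function(pairs, target_total, seed = 1) {
  freq <- pairs$frequency
  if (any(freq != round(freq))) stop("frequencies must be integer counts")
  total <- sum(freq)
  if (target_total > total) stop("target_total exceeds total frequency")
  if (nrow(pairs) == 0 || target_total == total) return(pairs)
  set.seed(seed)
  remaining <- total
  keep <- target_total
  out <- numeric(length(freq))
  for (i in seq_along(freq)) {
    # draw this pair's share from a hypergeometric, conditioning sequentially
    x <- stats::rhyper(1, freq[i], remaining - freq[i], keep)
    out[i] <- x
    keep <- keep - x
    remaining <- remaining - freq[i]
    if (keep == 0) break
  }
  pairs$frequency <- out
  pairs
}

#' Call promoter-anchored loops
#'
#' Retains the interactions whose one anchor overlaps a TSS window
#' (TSS +/- `tss_halfwidth`) and whose other anchor overlaps an H3K4me3
#' peak. Self-loops (anchors sharing a bin or a TSS window) are dropped.
#' Significance is a transparent frequency-rank filter: within
#' distance-matched strata of the full pair set, a loop must exceed the
#' `1 - p_threshold` frequency quantile of its stratum.
#'
#' @param pairs `interaction_pairs` of one condition.
#' @param h3k4me3_peaks an `interval_set`.
#' @param genes a `gene_models` object.
#' @param tss_halfwidth promoter window half-width (bp); default 2000.
#' @param p_threshold retention threshold on the frequency rank within a
#'   distance stratum; default 0.01 (keep the top 1 percent).
#' @param distance_breaks number of distance strata for the background;
#'   default 10.
#' @return a `loop_calls` data frame: promoter anchor, distal anchor,
#'   `gene_id`, `frequency`, `condition`, `distance`, `significant`.
#' @export
call_promoter_loops <- function(pairs, h3k4me3_peaks, genes,
                                tss_halfwidth = 2000, p_threshold = 0.01,
                                distance_breaks = 10) {
  empty <- data.frame(chrom = character(), promoter_start = numeric(),
                      promoter_end = numeric(), distal_start = numeric(),
                      distal_end = numeric(), gene_id = character(),
                      frequency = numeric(), condition = character(),
                      distance = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(structure(empty, class = c("loop_calls", "data.frame")))
  prom <- promoter_windows(genes, tss_halfwidth)
  a1 <- interval_set(pairs$chrom1, pairs$start1, pairs$end1)
  a2 <- interval_set(pairs$chrom2, pairs$start2, pairs$end2)
  gr_prom <- as_granges(prom)
  gr1 <- as_granges(a1); gr2 <- as_granges(a2)
  gr_k4 <- as_granges(h3k4me3_peaks)
  p1 <- GenomicRanges::countOverlaps(gr1, gr_prom) > 0
  p2 <- GenomicRanges::countOverlaps(gr2, gr_prom) > 0
  k1 <- GenomicRanges::countOverlaps(gr1, gr_k4) > 0
  k2 <- GenomicRanges::countOverlaps(gr2, gr_k4) > 0
  self_bin <- pairs$chrom1 == pairs$chrom2 & pairs$start1 == pairs$start2
  # both anchors inside one TSS window is a promoter self-loop
  ov1 <- GenomicRanges::findOverlaps(gr1, gr_prom)
  ov2 <- GenomicRanges::findOverlaps(gr2, gr_prom)
  shared <- intersect(
    paste(S4Vectors::queryHits(ov1), S4Vectors::subjectHits(ov1)),
    paste(S4Vectors::queryHits(ov2), S4Vectors::subjectHits(ov2)))
  self_tss <- seq_len(nrow(pairs)) %in%
    as.integer(sub(" .*", "", shared))
  orient1 <- p1 & k2       # anchor1 promoter, anchor2 distal
  orient2 <- p2 & k1
  keep <- (orient1 | orient2) & !self_bin & !self_tss
  # distance-matched frequency-rank background over the whole pair set
  cis <- pairs$chrom1 == pairs$chrom2
  dist <- ifelse(cis, abs(pairs$start2 - pairs$start1), NA)
  sig <- logical(nrow(pairs))
  if (any(cis)) {
    qs <- unique(stats::quantile(dist[cis], probs = seq(0, 1, length.out = distance_breaks + 1),
                                 names = FALSE, type = 7))
    strat <- cut(dist[cis], breaks = qs, include.lowest = TRUE)
    thr <- tapply(pairs$frequency[cis], strat,
                  function(f) stats::quantile(f, 1 - p_threshold, names = FALSE, type = 7))
    sig[cis] <- pairs$frequency[cis] > thr[as.integer(strat)]
  }
  idx <- which(keep)
  if (length(idx) == 0) return(structure(empty, class = c("loop_calls", "data.frame")))
  use1 <- orient1[idx]    # TRUE: anchor1 is the promoter anchor
  pchrom <- pairs$chrom1[idx]
  ps <- ifelse(use1, pairs$start1[idx], pairs$start2[idx])
  pe <- ifelse(use1, pairs$end1[idx], pairs$end2[idx])
  ds <- ifelse(use1, pairs$start2[idx], pairs$start1[idx])
  de <- ifelse(use1, pairs$end2[idx], pairs$end1[idx])
  panc <- interval_set(pchrom, ps, pe)
  ovp <- GenomicRanges::findOverlaps(as_granges(panc), gr_prom)
  gene_id <- rep(NA_character_, length(idx))
  first_hit <- !duplicated(S4Vectors::queryHits(ovp))
  gene_id[S4Vectors::queryHits(ovp)[first_hit]] <-
    prom$name[S4Vectors::subjectHits(ovp)[first_hit]]
  out <- data.frame(chrom = pchrom, promoter_start = ps, promoter_end = pe,
                    distal_start = ds, distal_end = de, gene_id = gene_id,
                    frequency = pairs$frequency[idx],
                    condition = pairs$condition[idx],
                    distance = dist[idx], significant = sig[idx],
                    stringsAsFactors = FALSE)
  structure(out, class = c("loop_calls", "data.frame"))
}

#' Write loops as a WashU/IGV-compatible track
#'
#' One line per loop: `chr:start-end<tab>chr:start-end<tab>score`.
#'
#' @param loops a `loop_calls` data frame.
#' @param path output path.
#' @export
write_loop_track <- function(loops, path) {
  lines <- sprintf("%s:%d-%d\t%s:%d-%d\t%g",
                   loops$chrom, as.integer(loops$promoter_start),
                   as.integer(loops$promoter_end),
                   loops$chrom, as.integer(loops$distal_start),
                   as.integer(loops$distal_end), loops$frequency)
  writeLines(lines, path)
  invisible(path)
}

#' Cluster condition-response interaction profiles
#'
#' Per locus, the profile is `log2((freq_c + pseudocount) /
#' (freq_Ctrl + pseudocount))` for every non-control condition; profiles
#' are clustered with k-means (Lloyd iterations) from a deterministic
#' seeded initialization. Empty clusters are re-seeded from the point
#' farthest from its centroid. Degenerate inputs with fewer distinct
#' profiles than `k` are assigned by profile identity and the centroid set
#' padded to `k`.
#'
#' @param freq_by_condition numeric matrix or data frame, loci x
#'   conditions, containing a control column.
#' @param k number of clusters; default 4.
#' @param pseudocount added to numerator and denominator; default 1.
#' @param seed RNG seed for initialization.
#' @param ctrl name of the control column; default `"Ctrl"`.
#' @return a `cluster_result` list: `profiles` (loci x non-control
#'   conditions log2 ratios), `cluster` (assignments 1..k), `centroids`
#'   (k x conditions), `sizes`, `seed`.
#' @export
cluster_interaction_profiles <- function(freq_by_condition, k = 4,
                                         pseudocount = 1, seed = 1,
                                         ctrl = "Ctrl") {
  m <- as.matrix(freq_by_condition)
  if (!ctrl %in% colnames(m)) stop("no control column '", ctrl, "'")
  if (nrow(m) < k) stop("fewer loci than clusters")
  other <- setdiff(colnames(m), ctrl)
  prof <- log2((m[, other, drop = FALSE] + pseudocount) /
                 (m[, ctrl] + pseudocount))
  uniq <- unique(prof)
  if (nrow(uniq) <= k) {
    cl <- match(apply(prof, 1, paste, collapse = "\r"),
                apply(uniq, 1, paste, collapse = "\r"))
    cent <- uniq[c(seq_len(nrow(uniq)), rep(1, k - nrow(uniq))), , drop = FALSE]
    fit <- list(cluster = cl, centers = cent)
  } else {
    set.seed(seed)
    fit <- try(stats::kmeans(prof, centers = k, iter.max = 100, nstart = 50),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      # rare degenerate starts: re-seed deterministically from the point
      # farthest from the chosen centers until k non-empty clusters exist
      set.seed(seed)
      centers <- prof[sample(nrow(prof), k), , drop = FALSE]
      fit <- NULL
      for (attempt in 1:25) {
        res <- try(stats::kmeans(prof, centers = centers, iter.max = 100,
                                 algorithm = "Lloyd"),
                   silent = TRUE)
        if (!inherits(res, "try-error")) { fit <- res; break }
        d <- as.matrix(stats::dist(rbind(centers, prof)))[seq_len(k), -seq_len(k), drop = FALSE]
        far <- which.max(apply(d, 2, min))
        centers[((attempt - 1) %% k) + 1, ] <- prof[far, ]
      }
      if (is.null(fit)) stop("k-means failed to converge to k non-empty clusters")
    }
  }
  sizes <- tabulate(fit$cluster, nbins = k)
  structure(list(profiles = prof, cluster = fit$cluster,
                 centroids = matrix(as.numeric(fit$centers), k,
                                    dimnames = list(NULL, other)),
                 sizes = sizes, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means interaction clusters:", paste(x$sizes, collapse = ", "),
      "loci per cluster\n")
  invisible(x)
}

#' Fraction of hubs overlapping a peak set
#'
#' @param hubs an `anchor_hubs` data frame.
#' @param peaks an `interval_set`.
#' @return list with `n_overlapping`, `n_total` and `percentage` (one
#'   decimal).
#' @export
count_hub_overlap_with_peaks <- function(hubs, peaks) {
  if (nrow(hubs) == 0) stop("no hubs")
  anchors <- interval_set(hubs$chrom, hubs$start, hubs$end)
  n_ov <- sum(intersect_intervals(anchors, peaks, "count") > 0)
  list(n_overlapping = n_ov, n_total = nrow(hubs),
       percentage = percent_of_total(n_ov, nrow(hubs)))
}
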