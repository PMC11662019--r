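#' Per-base G-quadruplex propensity scores
#'
#' G4Hunter-style run scoring: every G in a maximal G-run of length L
#' scores `+min(L, 4)`, every C in a C-run of length L scores `-min(L, 4)`,
#' and A/T/U/N score 0. Case-insensitive; U is treated as T.
#'
#' @param seq a nucleotide string over `A C G T U N`.
#' @return integer vector of per-base scores in `[-4, 4]`.
#' @export
g4_base_scores <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return(integer(0))
  chars[chars == "U"] <- "T"
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad))
    stop("non-IUPAC character '", chars[which(bad)[1]], "' at position ", which(bad)[1])
  r <- rle(chars)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4),
                ifelse(r$values == "C", -pmin(r$lengths, 4), 0L))
  rep(as.integer(val), r$lengths)
}

#' Sliding-window mean of G4 base scores
#'
#' Arithmetic mean of the per-base scores over every window of the given
#' width, anchored at the window's first base. Sequences shorter than the
#' window yield a single mean over the whole sequence.
#'
#' @param base_scores integer vector from [g4_base_scores()].
#' @param window window width in nt; default 25 (the genome-scan default).
#' @return numeric vector of window means.
#' @export
g4_window_scores <- function(base_scores, window = 25) {
  if (window < 1) stop("window must be >= 1")
  n <- length(base_scores)
  if (n == 0) return(numeric(0))
  if (n < window) return(mean(base_scores))
  cs <- c(0, cumsum(as.numeric(base_scores)))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' G4 propensity profile of a sequence
#'
#' @param seq nucleotide string.
#' @param window window width (nt); default 25.
#' @param sequence_id label carried into called regions; default `"seq"`.
#' @return a `g4_profile` list with `sequence_id`, `base_scores`,
#'   `window_scores` and `window`.
#' @export
g4_profile <- function(seq, window = 25, sequence_id = "seq") {
  bs <- g4_base_scores(seq)
  structure(list(sequence_id = sequence_id, base_scores = bs,
                 window_scores = g4_window_scores(bs, window), window = window),
            class = "g4_profile")
}

#' Call candidate G4 regions from a profile
#'
#' Maximal runs of consecutive windows with window score at or above the
#' threshold are merged into one region spanning the first window's start
#' to the last window's end; the mean score is recomputed over the merged
#' span. Coordinates are reported on the genome via `offset_chrom` /
#' `offset_start` (the origin of the scored sequence).
#'
#' @param profile a `g4_profile`.
#' @param threshold minimum window score; default 1.2 (the genome-scan
#'   default).
#' @param offset_chrom,offset_start genomic origin of the sequence;
#'   defaults `sequence_id` and 0.
#' @return an `interval_set` of G4 regions with columns `mean_score` and
#'   `max_window_score` (in `score`).
#' @export
call_g4_regions <- function(profile, threshold = 1.2,
                            offset_chrom = profile$sequence_id, offset_start = 0) {
  ws <- profile$window_scores
  n_seq <- length(profile$base_scores)
  win <- min(profile$window, n_seq)
  pass <- ws >= threshold
  if (!any(pass)) return(interval_set())
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ri <- which(r$values)
  reg_start <- starts[ri] - 1                      # 0-based on the sequence
  reg_end <- pmin(ends[ri] - 1 + win, n_seq)
  mean_score <- mapply(function(a, b) mean(profile$base_scores[(a + 1):b]),
                       reg_start, reg_end)
  max_ws <- mapply(function(a, b) max(ws[a:b]), starts[ri], ends[ri])
  out <- interval_set(rep(offset_chrom, length(ri)),
                      offset_start + reg_start, offset_start + reg_end,
                      score = max_ws)
  out$mean_score <- mean_score
  out$max_window_score <- max_ws
  out
}

#' Scan a genome for G4 regions
#'
#' Convenience wrapper scoring every sequence of a FASTA file (or named
#' character vector) and calling candidate regions on genomic coordinates.
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences.
#' @param window,threshold as in [g4_profile()] and [call_g4_regions()].
#' @return an `interval_set` of G4 regions across all sequences.
#' @export
scan_genome_g4 <- function(fasta, window = 25, threshold = 1.2) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else fasta
  res <- lapply(names(seqs), function(nm) {
    call_g4_regions(g4_profile(seqs[[nm]], window, sequence_id = nm),
                    threshold, offset_chrom = nm, offset_start = 0)
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (length(res) == 0) return(interval_set())
  as_interval_set(do.call(rbind, lapply(res, as.data.frame)))
}

#' Filter peaks by overlap with G4 regions
#'
#' Retains the peaks sharing at least one base with a called G4 region
#' (the G4-coordinate filtering contract).
#'
#' @param peaks an `interval_set` of peaks.
#' @param g4 an `interval_set` of G4 regions.
#' @return the retained peaks.
#' @export
filter_peaks_by_g4 <- function(peaks, g4) {
  intersect_intervals(peaks, g4, "report_a")
}

#' Scan a sequence with an IUPAC degenerate motif
#'
#' Reports every 0-based offset at which the sequence matches the motif at
#' all degenerate positions (IUPAC codes; U and T equivalent; N in the
#' scanned sequence is a mismatch). With `both_strands` the reverse
#' complement of the motif is scanned too and hits are labelled by strand.
#'
#' @param seq nucleotide string to scan.
#' @param motif IUPAC pattern, e.g. the expanded nuclear-shuttling motif
#'   `"AKYACCWUUUGRUWA"`.
#' @param both_strands also scan the minus strand; default `FALSE`.
#' @return data frame with `start` (0-based), `end` (exclusive), `strand`.
#' @export
scan_iupac_motif <- function(seq, motif, both_strands = FALSE) {
  clean <- function(s) gsub("U", "T", toupper(s))
  subject <- Biostrings::DNAString(clean(seq))
  pat <- Biostrings::DNAString(clean(motif))
  hit_df <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subject,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    if (length(m) == 0)
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    data.frame(start = Biostrings::start(m) - 1, end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- hit_df(pat, "+")
  if (both_strands)
    out <- rbind(out, hit_df(Biostrings::reverseComplement(pat), "-"))
  if (nrow(out)) {
    # an N in the scanned sequence never satisfies a degenerate position
    n_pos <- which(strsplit(as.character(subject), "")[[1]] == "N")
    if (length(n_pos)) {
      keep <- vapply(seq_len(nrow(out)), function(i) {
        !any(n_pos > out$start[i] & n_pos <= out$end[i])
      }, logical(1))
      out <- out[keep, , drop = FALSE]
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}
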