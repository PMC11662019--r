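#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct an interval set
#'
#' The package-wide container for genomic intervals: a data frame with
#' columns `chrom`, `start`, `end` (0-based half-open, BED convention) and
#' optional `name`, `score`, `strand`, carrying extra columns untouched.
#' An optional genome (named vector of chromosome lengths) can be attached,
#' in which case intervals must fit their chromosomes.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like coordinates, 0-based half-open; `start < end`.
#' @param name,score,strand optional per-interval annotation; `strand` must
#'   be one of `"+"`, `"-"`, `"."` when given.
#' @param ... further per-interval columns, preserved verbatim.
#' @param genome optional named numeric vector of chromosome lengths (bp).
#' @return An object of class `interval_set` (a data frame).
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer(),
                         name = NULL, score = NULL, strand = NULL, ...,
                         genome = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  df$name <- if (is.null(name)) rep(NA_character_, n) else as.character(name)
  df$score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  df$strand <- if (is.null(strand)) rep(".", n) else as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_interval_set(df, genome)
  structure(df, genome = genome, class = c("interval_set", "data.frame"))
}

validate_interval_set <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(TRUE))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("chromosome names must be non-empty")
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop("interval coordinates must be finite")
  if (any(df$start < 0)) stop("negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("start >= end for interval ", bad[1])
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(genome)) {
    len <- genome[df$chrom]
    if (any(is.na(len)))
      stop("interval on chromosome absent from genome: ",
           df$chrom[which(is.na(len))[1]])
    if (any(df$end > len))
      stop("interval end exceeds chromosome length")
  }
  invisible(TRUE)
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set with", nrow(x), "intervals\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

# internal: data.frame -> interval_set without revalidation overhead
as_interval_set <- function(df, genome = NULL) {
  for (col in c("name", "score", "strand")) {
    if (is.null(df[[col]]))
      df[[col]] <- switch(col, name = NA_character_, score = NA_real_, strand = ".")
  }
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("interval_set", "data.frame"))
}

# internal: interval_set -> GRanges (0-based half-open -> 1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

#' Sort an interval set
#'
#' Deterministic order by (chrom, start, end, name); ties in name broken
#' lexicographically with `NA` last.
#'
#' @param x an `interval_set`.
#' @return the sorted `interval_set`.
#' @export
sort_intervals <- function(x) {
  o <- order(x$chrom, x$start, x$end, x$name, method = "radix")
  as_interval_set(as.data.frame(x)[o, , drop = FALSE], attr(x, "genome"))
}

#' Interval widths
#' @param x an `interval_set`.
#' @return numeric vector of widths (bp).
#' @export
interval_width <- function(x) x$end - x$start

#' Read genomic intervals from BED-family or TSV files
#'
#' Parses BED3/BED6, narrowPeak, broadPeak (extra columns preserved as
#' opaque payload) or a headered TSV with `chrom`/`start`/`end` columns.
#' Coordinates are taken as 0-based half-open. `track`, `browser` and `#`
#' comment lines are skipped. For narrowPeak/broadPeak the 7th column
#' (signalValue) is mapped to `score`.
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"broadPeak"`, `"tsv"`.
#' @param genome optional named vector of chromosome lengths to attach.
#' @return an `interval_set`.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "broadPeak", "tsv"),
                           genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (format == "tsv") {
    if (length(lines) == 0) return(interval_set(genome = genome))
    df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("TSV must have columns chrom, start, end")
    bad <- which(df$start >= df$end)
    if (length(bad)) stop("start >= end at line ", bad[1] + 1)
    out <- interval_set(df$chrom, df$start, df$end,
                        name = df$name, score = df$score, strand = df$strand,
                        genome = genome)
    keep <- setdiff(names(df), c("chrom", "start", "end", "name", "score", "strand"))
    for (nm in keep) out[[nm]] <- df[[nm]]
    return(out)
  }
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(interval_set(genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop("fewer than 3 columns at line ", lineno[which(ncol < 3)[1]])
  ncmax <- max(ncol)
  mat <- matrix(NA_character_, length(fields), ncmax)
  for (i in seq_along(fields)) mat[i, seq_len(ncol[i])] <- fields[[i]]
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  if (any(is.na(start) | is.na(end)))
    stop("non-numeric coordinate at line ", lineno[which(is.na(start) | is.na(end))[1]])
  bad <- which(start >= end)
  if (length(bad)) stop("start >= end at line ", lineno[bad[1]])
  df <- data.frame(chrom = mat[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (ncmax >= 4) mat[, 4] else NA_character_
  peak_like <- format %in% c("narrowPeak", "broadPeak")
  score_col <- if (peak_like && ncmax >= 7) 7L else if (ncmax >= 5) 5L else NA
  df$score <- if (is.na(score_col)) NA_real_ else suppressWarnings(as.numeric(mat[, score_col]))
  df$strand <- if (ncmax >= 6) ifelse(is.na(mat[, 6]), ".", mat[, 6]) else "."
  if (ncmax > 6) {
    for (j in 7:ncmax) df[[paste0("V", j)]] <- mat[, j]
  }
  validate_interval_set(df, genome)
  as_interval_set(df, genome)
}

#' Write an interval set to BED or TSV
#'
#' BED output emits exactly the columns present: 3 columns when no
#' name/score/strand annotation exists, 6 when it does, plus any extra
#' payload columns. Round-trips bit-exactly with [read_intervals()] for
#' BED3/BED6 content.
#'
#' @param x an `interval_set`.
#' @param path output file path.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_intervals <- function(x, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = ".")
    return(invisible(path))
  }
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  fmt_num <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "." else format(z, scientific = FALSE, trim = TRUE, digits = 15)
    }, character(1))
    out
  }
  extra <- setdiff(names(df), c("chrom", "start", "end", "name", "score", "strand"))
  has6 <- any(!is.na(df$name)) || any(!is.na(df$score)) ||
    any(df$strand != ".") || length(extra) > 0
  cols <- list(df$chrom, fmt_num(df$start), fmt_num(df$end))
  if (has6) {
    cols <- c(cols, list(ifelse(is.na(df$name), ".", df$name),
                         fmt_num(df$score), df$strand))
    for (nm in extra) cols <- c(cols, list(as.character(df[[nm]])))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Merge intervals within a gap distance
#'
#' Per chromosome, merges any two intervals whose gap is at most `max_gap`
#' bp; overlapping or bookended intervals always merge at `max_gap = 0`.
#' Strand is ignored. Equivalent to `bedtools merge -d max_gap`.
#'
#' @param x an `interval_set`.
#' @param max_gap non-negative gap (bp); default 0.
#' @return a sorted `interval_set` of pairwise non-overlapping intervals.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  sort_intervals(as_interval_set(out, attr(x, "genome")))
}

#' Intersect two interval sets
#'
#' Overlap means at least one shared base under half-open semantics
#' (bookended intervals do not overlap); strand is ignored.
#'
#' @param a,b `interval_set` objects.
#' @param mode `"report_a"` returns each `a` interval overlapping at least
#'   one `b` interval exactly once; `"exclude_a"` returns the `a` intervals
#'   with zero overlap (the blacklist-removal contract, `bedtools intersect
#'   -wa -v`); `"count"` returns the per-`a`-interval overlap count.
#' @return an `interval_set`, or an integer vector for `mode = "count"`.
#' @export
intersect_intervals <- function(a, b, mode = c("report_a", "count", "exclude_a")) {
  mode <- match.arg(mode)
  if (nrow(a) == 0) {
    return(if (mode == "count") integer(0) else a)
  }
  nhit <- if (nrow(b) == 0) integer(nrow(a)) else
    GenomicRanges::countOverlaps(as_granges(a), as_granges(b))
  switch(mode,
    count = nhit,
    report_a = as_interval_set(as.data.frame(a)[nhit > 0, , drop = FALSE],
                               attr(a, "genome")),
    exclude_a = as_interval_set(as.data.frame(a)[nhit == 0, , drop = FALSE],
                                attr(a, "genome")))
}
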