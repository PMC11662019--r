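test_that("run scoring caps at 4 and signs G against C runs", {
  expect_equal(g4_base_scores("GGGG"), rep(4L, 4))
  expect_equal(g4_base_scores("GGGGG"), rep(4L, 5))
  expect_equal(g4_base_scores("ACGT"), c(0L, -1L, 1L, 0L))
  expect_equal(g4_base_scores("accGGt"), c(0L, -2L, -2L, 2L, 2L, 0L))
  expect_equal(g4_base_scores("NUN"), c(0L, 0L, 0L))
  expect_error(g4_base_scores("ACGX"), "non-IUPAC character 'X' at position 4")
})

test_that("window means follow the sliding-window contract", {
  expect_equal(g4_window_scores(rep(2, 10), 4), rep(2, 7))
  expect_equal(g4_window_scores(g4_base_scores("GGTTGGTTGGTTGG"), 14), 16 / 14)
  expect_equal(g4_window_scores(c(4, 4, 4, 4, 0, 0, 0, 0), 4), c(4, 3, 2, 1, 0))
  # shorter than the window: one mean over the whole sequence
  expect_equal(g4_window_scores(c(1, 2, 3), 25), 2)
  expect_error(g4_window_scores(1:5, 0), "window")
})

test_that("run scoring equals the naive per-position oracle on random sequences", {
  set.seed(44)
  for (rep in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.28, 0.02)), collapse = "")
    expect_identical(g4_base_scores(seq), g4_naive(seq))
  }
})

test_that("reverse complement negates and reverses the score profile", {
  set.seed(45)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    fwd <- g4_base_scores(seq)
    rev <- g4_base_scores(revcomp_chr(seq))
    expect_identical(rev, -rev(fwd))
    expect_equal(g4_window_scores(rev, 25), -rev(g4_window_scores(fwd, 25)))
  }
})

test_that("region calling merges qualifying window runs", {
  # all windows below the threshold
  p <- g4_profile("ATATATATATATATAT", window = 4)
  expect_equal(nrow(call_g4_regions(p, 1.2)), 0)

  # a single window exactly at the threshold is boundary-inclusive
  bs <- c(2, 2, 2, 0, 0, 0, 0, 0)
  prof <- structure(list(sequence_id = "s", base_scores = bs,
                         window_scores = g4_window_scores(bs, 5), window = 5),
                    class = "g4_profile")
  r <- call_g4_regions(prof, threshold = 1.2)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 5))

  # two qualifying runs separated by a failing window give two regions
  seq2 <- paste0("GGGGG", "CCCCCCCC", "GGGGG")
  p2 <- g4_profile(seq2, window = 5)
  r2 <- call_g4_regions(p2, threshold = 2)
  expect_equal(nrow(r2), 2)
  expect_true(all(r2$mean_score >= 0 | r2$max_window_score >= 2))

  # genomic offset is applied
  r3 <- call_g4_regions(prof, 1.2, offset_chrom = "chr7", offset_start = 1000)
  expect_equal(r3$chrom, "chr7")
  expect_equal(r3$start, 1000)
})

test_that("peak filtering keeps exactly the G4-overlapping peaks", {
  peaks <- interval_set(rep("chr1", 3), c(0, 100, 200), c(50, 150, 250))
  g4 <- interval_set("chr1", 120, 130)
  kept <- filter_peaks_by_g4(peaks, g4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 100)
  expect_equal(nrow(filter_peaks_by_g4(peaks, interval_set())), 0)
})

test_that("IUPAC scanning honours degenerate codes, strand and N", {
  motif <- "AKYACCWUUUGRUWA"
  hit <- scan_iupac_motif("AGCACCATTTGATAA", motif)
  expect_equal(hit$start, 0)
  expect_equal(hit$end, 15)

  expect_equal(nrow(scan_iupac_motif("AGCACC", motif)), 0)
  # violate the invariant C at position 5
  expect_equal(nrow(scan_iupac_motif("AGCAGCATTTGATAA", motif)), 0)
  # N in the scanned sequence is a mismatch
  expect_equal(nrow(scan_iupac_motif("AGCACCATTTGANAA", motif)), 0)

  # minus-strand hit found via the reverse complement
  rc <- revcomp_chr("AGCACCATTTGATAA")
  expect_equal(nrow(scan_iupac_motif(rc, motif)), 0)
  m <- scan_iupac_motif(rc, motif, both_strands = TRUE)
  expect_equal(m$strand, "-")
  expect_equal(m$start, 0)
})

test_that("genome scanning recovers planted G-quadruplex tracts", {
  set.seed(77)
  bg <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
               prob = c(0.29, 0.21, 0.21, 0.29))
  planted <- list()
  for (i in 1:12) {
    loops <- sample(1:3, 3, replace = TRUE)
    tract <- unlist(lapply(1:4, function(k)
      c(rep("G", 3), if (k < 4) sample(c("A", "T"), loops[k], replace = TRUE))))
    pos <- 1000 + (i - 1) * 1500
    bg[(pos + 1):(pos + length(tract))] <- tract
    planted[[i]] <- c(pos, pos + length(tract))
  }
  regions <- scan_genome_g4(c(chrT = paste(bg, collapse = "")))
  truth <- interval_set(rep("chrT", 12),
                        vapply(planted, `[`, numeric(1), 1),
                        vapply(planted, `[`, numeric(1), 2))
  expect_gte(mean(intersect_intervals(truth, regions, "count") > 0), 0.95)
})
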