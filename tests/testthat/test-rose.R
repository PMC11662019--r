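test_that("stitching merges constituents within the stitch distance", {
  p <- interval_set(c("chr1", "chr1"), c(0, 11000), c(1000, 12000))
  s <- stitch_enhancers(p)     # gap 10 kb <= 12.5 kb
  expect_equal(nrow(s), 1)
  expect_equal(s$n_constituents, 2)
  expect_equal(nrow(s$constituents[[1]]), 2)

  far <- interval_set(c("chr1", "chr1"), c(0, 14000), c(1000, 15000))
  expect_equal(nrow(stitch_enhancers(far)), 2)   # gap 13 kb

  one <- interval_set("chr1", 100, 900)
  s1 <- stitch_enhancers(one)
  expect_equal(c(s1$start, s1$end), c(100, 900))

  # order invariance and idempotence of the stitched regions
  set.seed(21)
  df <- random_interval_df(40, 100000)
  x <- interval_set(rep("chr1", 40), df$start * 100, df$end * 100)
  perm <- as.data.frame(x)[sample(40), ]
  y <- structure(perm, genome = NULL, class = c("interval_set", "data.frame"))
  s_a <- stitch_enhancers(x, 5000)
  s_b <- stitch_enhancers(y, 5000)
  expect_equal(s_a[, c("chrom", "start", "end")], s_b[, c("chrom", "start", "end")])
})

test_that("TSS-window exclusion removes fully contained constituents", {
  p <- interval_set(c("chr1", "chr1"), c(1000, 30000), c(2000, 31000))
  tss <- interval_set("chr1", 500, 2500)
  s <- stitch_enhancers(p, tss_windows = tss)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 30000)
  expect_error(stitch_enhancers(interval_set("chr1", 1000, 2000),
                                tss_windows = tss), "all constituents excluded")
})

test_that("hockey-stick cutoff follows the scaled tangent-slope geometry", {
  enh <- function(n) {
    structure(data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                         end = (0:(n - 1)) * 1e5 + 1000,
                         n_constituents = 1,
                         constituents = I(replicate(n, data.frame(), simplify = FALSE))),
              class = c("stitched_enhancers", "data.frame"))
  }
  flat <- rank_and_cutoff(enh(5), rep(3, 5))
  expect_equal(sum(flat$enhancers$is_super), 0)

  sig <- c(rep(1, 9), 100)
  r <- rank_and_cutoff(enh(10), sig)
  expect_equal(sum(r$enhancers$is_super), 1)
  expect_true(r$enhancers$is_super[which.max(sig)])

  # shifting every signal by a constant leaves the SE partition unchanged
  set.seed(9)
  s0 <- rlnorm(50, 3, 1.2)
  base <- rank_and_cutoff(enh(50), s0)
  shifted <- rank_and_cutoff(enh(50), s0 + 17)
  expect_equal(base$enhancers$is_super, shifted$enhancers$is_super)

  # control subtraction floors at zero
  ctl <- rank_and_cutoff(enh(5), c(5, 5, 5, 5, 50), control = rep(10, 5))
  expect_equal(ctl$enhancers$signal, c(0, 0, 0, 0, 40))

  expect_error(rank_and_cutoff(enh(5), rep(0, 5)), "degenerate ranking")
  expect_error(rank_and_cutoff(enh(2), c(1, 2)), "at least 3")
})

test_that("cutoff equals the exhaustive slope scan on random signal vectors", {
  set.seed(33)
  enh <- function(n) {
    structure(data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                         end = (0:(n - 1)) * 1e5 + 1000,
                         n_constituents = 1,
                         constituents = I(replicate(n, data.frame(), simplify = FALSE))),
              class = c("stitched_enhancers", "data.frame"))
  }
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    s <- rlnorm(n, 2, sample(c(0.5, 1, 2), 1))
    r <- rank_and_cutoff(enh(n), s)
    expect_equal(r$cutoff$cutoff_signal, rose_cutoff_scan(s))
  }
})

test_that("enhancer signal sums track coverage over the stitched span", {
  s <- stitch_enhancers(interval_set(c("chr1", "chr1"), c(0, 5000),
                                     c(1000, 6000)), 12500)
  track <- interval_set(c("chr1", "chr1"), c(0, 5500), c(1000, 5600),
                        score = c(2, 10))
  expect_equal(enhancer_signal(s, track), 1000 * 2 + 100 * 10)
  expect_equal(enhancer_signal(s, track, control = track), 0)
})

test_that("size strata match the published boundaries", {
  enh <- data.frame(chrom = "chr1",
                    start = 0,
                    end = c(3300, 3200, 2300, 2299, 500, 901, 900, 600, 599),
                    is_super = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                                 FALSE, FALSE))
  out <- classify_enhancer_size(enh)
  expect_equal(as.character(out$size_class),
               c("SE_broad", "SE_medium", "SE_medium", "SE_narrow",
                 "TYE_narrow", "TYE_broad", "TYE_medium", "TYE_medium",
                 "TYE_narrow"))
  expect_error(classify_enhancer_size(enh[, 1:3]), "rank_and_cutoff")
})

test_that("miRNA marking tests overlap against constituents, not gaps", {
  p <- interval_set(c("chr1", "chr1"), c(0, 10000), c(500, 10500))
  s <- stitch_enhancers(p, 12500)
  expect_equal(nrow(s), 1)

  m1 <- mark_by_mirna(s, interval_set("chr1", 499, 600))
  expect_true(m1$mirna_marked)

  gap_peak <- interval_set("chr1", 2000, 3000)   # inside the stitched gap
  expect_false(mark_by_mirna(s, gap_peak)$mirna_marked)
  expect_true(mark_by_mirna(s, gap_peak, on = "span")$mirna_marked)

  expect_false(mark_by_mirna(s, interval_set())$mirna_marked)
})

test_that("marking enrichment reports percentages and an exact Fisher p", {
  r <- marking_enrichment_test(10, 40, 2, 50)
  expect_equal(r$se_pct, 25.0)
  expect_equal(r$tye_pct, 4.0)
  expect_equal(r$p.value, fisher_enum(10, 30, 2, 48), tolerance = 1e-7)

  eq <- marking_enrichment_test(5, 10, 10, 20)
  expect_equal(eq$p.value, 1)
  z <- marking_enrichment_test(0, 7, 0, 9)
  expect_equal(c(z$se_pct, z$tye_pct, z$p.value), c(0, 0, 1))
  expect_error(marking_enrichment_test(1, 0, 0, 5), "positive")
})
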