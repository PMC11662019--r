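test_that("BED-family parsing maps fields and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200\tp1\t5.0"), f)
  x <- read_intervals(f)
  expect_equal(nrow(x), 1)
  expect_equal(x$chrom, "chr1")
  expect_equal(x$start, 100)
  expect_equal(x$end, 200)
  expect_equal(x$name, "p1")
  expect_equal(x$score, 5)

  writeLines(character(), f)
  expect_equal(nrow(read_intervals(f)), 0)

  writeLines("chr1\t200\t100", f)
  expect_error(read_intervals(f), "start >= end at line 1")

  writeLines(c("chr1\t1\t2", "chr1\t5"), f)
  expect_error(read_intervals(f), "line 2")

  # narrowPeak: signalValue (column 7) becomes the score
  writeLines("chr1\t0\t50\tpk\t900\t.\t7.25\t12\t9\t25", f)
  np <- read_intervals(f, "narrowPeak")
  expect_equal(np$score, 7.25)
})

test_that("write/read round-trips BED3 and BED6 content bit-exactly", {
  x <- interval_set(c("chr2", "chr1", "chr1"), c(10, 0, 500), c(40, 100, 800),
                    name = c("a", "b", "c"), score = c(1, 2.5, 3),
                    strand = c("+", "-", "."))
  f <- withr::local_tempfile(fileext = ".bed")
  write_intervals(x, f)
  y <- read_intervals(f)
  expect_identical(as.data.frame(y), as.data.frame(x))
  write_intervals(y, paste0(f, "2"))
  expect_identical(readLines(f), readLines(paste0(f, "2")))

  bare <- interval_set("chr1", 5, 9)
  write_intervals(bare, f)
  expect_identical(readLines(f), "chr1\t5\t9")
  expect_identical(as.data.frame(read_intervals(f)), as.data.frame(bare))

  write_intervals(interval_set(), f)
  expect_identical(readLines(f), character(0))
})

test_that("merging honours the gap threshold at its boundary", {
  s <- interval_set(c("chr1", "chr1"), c(0, 10), c(10, 20))
  m <- merge_intervals(s, 0)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 20))

  g <- interval_set(c("chr1", "chr1"), c(0, 15), c(10, 20))
  expect_equal(nrow(merge_intervals(g, 4)), 2)
  m5 <- merge_intervals(g, 5)
  expect_equal(nrow(m5), 1)
  expect_equal(c(m5$start, m5$end), c(0, 20))

  one <- interval_set("chrX", 3, 9)
  expect_equal(as.data.frame(merge_intervals(one, 0))[, 1:3],
               as.data.frame(one)[, 1:3])
  expect_error(merge_intervals(s, -1), "non-negative")
})

test_that("intersection uses half-open semantics and exact set algebra", {
  a <- interval_set("chr1", 0, 10)
  b <- interval_set("chr1", 9, 20)
  expect_equal(nrow(intersect_intervals(a, b, "report_a")), 1)
  b2 <- interval_set("chr1", 10, 20)
  expect_equal(nrow(intersect_intervals(a, b2, "report_a")), 0)

  a3 <- interval_set(c("chr1", "chr1"), c(0, 20), c(5, 30))
  b3 <- interval_set("chr1", 21, 22)
  ex <- intersect_intervals(a3, b3, "exclude_a")
  expect_equal(nrow(ex), 1)
  expect_equal(c(ex$start, ex$end), c(0, 5))
  expect_error(intersect_intervals(a3, b3, "bogus"))
})

test_that("merge and intersect agree with per-base occupancy on random sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    df <- random_interval_df(n)
    s <- interval_set(rep("chr1", n), df$start, df$end)
    gap <- sample(0:20, 1)
    got <- merge_intervals(s, gap)
    want <- occupancy_merge(df$start, df$end, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # idempotence
    again <- merge_intervals(got, gap)
    expect_equal(as.data.frame(again), as.data.frame(got))

    db <- random_interval_df(sample(1:30, 1))
    b <- interval_set(rep("chr1", nrow(db)), db$start, db$end)
    cnt <- intersect_intervals(s, b, "count")
    expect_equal(cnt, occupancy_overlap_counts(df$start, df$end, db$start, db$end))
    rep_a <- intersect_intervals(s, b, "report_a")
    exc_a <- intersect_intervals(s, b, "exclude_a")
    expect_equal(nrow(rep_a) + nrow(exc_a), n)
    expect_equal(nrow(rep_a), sum(cnt > 0))
  }
})

test_that("interval invariants are enforced at construction", {
  expect_error(interval_set("chr1", 5, 5), "start >= end")
  expect_error(interval_set("", 0, 5), "non-empty")
  expect_error(interval_set("chr1", 0, 5, strand = "x"), "strand")
  expect_error(interval_set("chr1", 0, 2e6, genome = c(chr1 = 1e6)),
               "exceeds chromosome length")
  expect_error(interval_set("chr9", 0, 10, genome = c(chr1 = 1e6)),
               "absent from genome")
})

test_that("gene models validate exon structure and derive promoter windows", {
  g <- gene_models("g1", "chr1", "+", 1000,
                   list(c(1000, 3000)), list(c(1500, 3600)))
  expect_equal(g$length_kb, 1.1)
  expect_equal(g$span_start, 1000)
  pw <- promoter_windows(g, 2000)
  expect_equal(c(pw$start, pw$end), c(0, 3000))  # clipped at zero
  expect_error(gene_models("g1", "chr1", "+", 99,
                           list(c(1000, 3000)), list(c(1500, 3600))),
               "TSS outside")
  expect_error(gene_models("g1", "chr1", "+", 1000,
                           list(c(1000, 1200)), list(c(1500, 1600))),
               "overlapping exons")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(g, f)
  g2 <- read_gene_models(f)
  expect_equal(g2$exon_starts, g$exon_starts)
  expect_equal(g2$length_kb, g$length_kb)
})
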