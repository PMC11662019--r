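test_that("binning snaps anchors and aggregates coincident pairs", {
  p <- interaction_pairs("chr1", 12000, 12500, "chr1", 12900, 13000, 3)
  b <- bin_pairs(p, 25000)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start1, b$end1, b$start2, b$end2), c(0, 25000, 0, 25000))

  two <- interaction_pairs(c("chr1", "chr1"), c(1000, 2000), c(1500, 2500),
                           c("chr1", "chr1"), c(60000, 61000), c(60500, 61500),
                           c(3, 4))
  b2 <- bin_pairs(two, 25000)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$frequency, 7)
  expect_equal(sum(b2$frequency), sum(two$frequency))  # conservation

  empty <- interaction_pairs(character(), numeric(), numeric(),
                             character(), numeric(), numeric(), numeric())
  expect_equal(nrow(bin_pairs(empty, 25000)), 0)
})

test_that("hub totals count every touching pair, self-pairs once", {
  p <- interaction_pairs(c("chr1", "chr1"), c(0, 0), c(25000, 25000),
                         c("chr1", "chr1"), c(50000, 100000), c(75000, 125000),
                         c(5, 7))
  h <- build_hubs(p)
  expect_equal(h$total_frequency[h$start == 0], 12)
  expect_equal(h$total_frequency[h$start == 50000], 5)
  expect_equal(h$total_frequency[h$start == 100000], 7)

  self <- interaction_pairs("chr1", 0, 25000, "chr1", 0, 25000, 4)
  expect_equal(build_hubs(self)$total_frequency, 4)
  # hub grand total = 2 * non-self + self frequencies
  expect_equal(sum(build_hubs(p)$total_frequency), 2 * (5 + 7))
  expect_equal(nrow(build_hubs(p[0, ])), 0)
})

test_that("hub filtering and mean-normalization are exact", {
  h <- data.frame(chrom = "chr1", start = c(0, 1, 2, 3) * 25000,
                  end = c(1, 2, 3, 4) * 25000,
                  total_frequency = c(12, 5, 20, 10), condition = "Ctrl")
  f <- filter_normalize_hubs(h, 10)
  expect_equal(f$total_frequency, c(12, 20, 10))
  expect_equal(f$normalized_frequency, c(12, 20, 10) / 14)
  expect_equal(mean(f$normalized_frequency), 1, tolerance = 1e-12)

  one <- filter_normalize_hubs(h[1, ], 10)
  expect_equal(one$normalized_frequency, 1)
  all10 <- h; all10$total_frequency <- rep(10, 4)
  expect_equal(filter_normalize_hubs(all10, 10)$normalized_frequency, rep(1, 4))
  expect_error(filter_normalize_hubs(h, 100), "empty hub set")
})

test_that("down-sampling conserves the target exactly and is seeded", {
  p <- interaction_pairs(c("chr1", "chr2"), c(0, 0), c(1000, 1000),
                         c("chr1", "chr2"), c(50000, 50000), c(51000, 51000),
                         c(1000, 1000))
  expect_equal(downsample_pairs(p, 2000)$frequency, c(1000, 1000))
  expect_equal(downsample_pairs(p, 0, seed = 1)$frequency, c(0, 0))
  d1 <- downsample_pairs(p, 700, seed = 42)
  d2 <- downsample_pairs(p, 700, seed = 42)
  expect_identical(d1$frequency, d2$frequency)
  expect_equal(sum(d1$frequency), 700)
  expect_error(downsample_pairs(p, 5000), "exceeds")

  # expected share is hypergeometric: mean over 200 seeds within 3 sigma
  draws <- vapply(1:200, function(s)
    downsample_pairs(p, 1000, seed = s)$frequency[1], numeric(1))
  sigma <- sqrt(1000 * 0.5 * 0.5 * (2000 - 1000) / (2000 - 1))
  expect_lt(abs(mean(draws) - 500), 3 * sigma / sqrt(200))
})

test_that("promoter loop calling applies the anchor rule and drops self-loops", {
  genes <- gene_models(c("gA", "gB"), rep("chr1", 2), rep("+", 2),
                       c(10000, 500000),
                       list(10000, 500000), list(15000, 505000))
  k4 <- interval_set("chr1", 100000, 102000)
  pr <- interaction_pairs(
    c("chr1", "chr1", "chr1"),
    c(9000, 200000, 9000), c(11000, 202000, 11000),
    c("chr1", "chr1", "chr1"),
    c(100500, 300000, 9500), c(101500, 302000, 11500),
    c(50, 8, 40), "Ctrl")
  loops <- call_promoter_loops(pr, k4, genes)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$gene_id, "gA")
  expect_equal(loops$frequency, 50)
  expect_equal(loops$distal_start, 100500)
})

test_that("response clustering recovers planted archetypes and handles degeneracy", {
  set.seed(1)
  arch <- matrix(c(2, 2, 2, -2, 0, 0, -2, -2), 4, 2, byrow = TRUE)
  truth <- rep(1:4, each = 50)
  base <- 100
  freq <- cbind(
    Ctrl = rep(base, 200),
    TGFB1 = round(base * 2^(arch[truth, 1] + rnorm(200, 0, 0.1))),
    TGFB1_LOF = round(base * 2^(arch[truth, 2] + rnorm(200, 0, 0.1))))
  rownames(freq) <- paste0("locus", 1:200)
  cl <- cluster_interaction_profiles(freq, k = 4, seed = 1)
  expect_equal(sum(cl$sizes), 200)
  expect_gte(cluster_agreement(truth, cl$cluster, 4), 0.9)

  # all-identical profiles: one populated cluster, centroid set still k
  same <- cbind(Ctrl = rep(10, 6), TGFB1 = rep(20, 6))
  cs <- cluster_interaction_profiles(same, k = 4, seed = 1)
  expect_equal(nrow(cs$centroids), 4)
  expect_equal(length(unique(cs$cluster)), 1)

  # frequencies equal to control give all-zero profiles
  eqf <- cbind(Ctrl = c(5, 10, 20, 40), TGFB1 = c(5, 10, 20, 40))
  ce <- cluster_interaction_profiles(eqf, k = 2, seed = 1)
  expect_true(all(ce$profiles == 0))

  expect_error(cluster_interaction_profiles(freq[1:3, ], k = 4), "fewer loci")
  expect_error(cluster_interaction_profiles(freq, k = 4, ctrl = "none"),
               "control column")
})

test_that("hub-peak overlap percentages are exact counts", {
  h <- data.frame(chrom = "chr1", start = (0:7) * 25000, end = (1:8) * 25000,
                  total_frequency = 10, condition = "Ctrl")
  pk <- interval_set(c("chr1", "chr1"), c(100, 30000), c(200, 30100))
  ov <- count_hub_overlap_with_peaks(h, pk)
  expect_equal(ov$n_overlapping, 2)
  expect_equal(ov$percentage, 25.0)
  expect_equal(count_hub_overlap_with_peaks(h, interval_set())$percentage, 0)
  allpk <- interval_set("chr1", 0, 8 * 25000)
  expect_equal(count_hub_overlap_with_peaks(h, allpk)$percentage, 100)
})

test_that("pair files round-trip and canonicalize anchor order", {
  p <- interaction_pairs("chr1", 50000, 51000, "chr1", 1000, 2000, 9, "Ctrl")
  expect_equal(p$start1, 1000)   # swapped to canonical order
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_pairs(p, f)
  q <- read_pairs(f, "Ctrl")
  expect_equal(as.data.frame(q), as.data.frame(p))
})
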