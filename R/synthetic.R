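#' Configuration for the synthetic-data generator
#'
#' Defaults define a toy study: a 2 x 5 Mb genome, 300 genes, an H3K4me3
#' peak set whose widths come from a three-mode breadth mixture aligned
#' with the Q2/Q3 quantile rule (narrow 50%, medium 25%, broad 25% with
#' disjoint width ranges), 60 super-enhancer constituent clusters over 600
#' typical enhancers with an order-of-magnitude aggregate-signal gap,
#' planted G-quadruplex tracts of the form (GGG N1-3)x4, miRNA occupancy
#' marking SEs at 0.25 versus TYEs at 0.04, three-condition promoter-SE
#' interactions with four response archetypes at |log2| = 2 and log-noise
#' 0.1, and an expression table with 20% affected genes split 73.5% down /
#' 26.5% up at |log2FC| = 1.2.
#'
#' @param seed integer RNG seed; every emitted byte is a deterministic
#'   function of it.
#' @param ... named overrides of any default listed above (see the source
#'   for the full set of fields).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chroms = 2,
    chrom_length = 5e6,
    gc = 0.42,
    # genes
    n_genes = 300,
    # H3K4me3 breadth mixture: fractions aligned with the Q2/Q3 partition
    breadth_fractions = c(broad = 0.25, medium = 0.25, narrow = 0.50),
    breadth_mean = c(broad = 3400, medium = 2350, narrow = 1400),
    breadth_sd = c(broad = 300, medium = 140, narrow = 250),
    breadth_range = list(broad = c(2800, 5200), medium = c(2050, 2650),
                         narrow = c(800, 1900)),
    n_k4me3_peaks = 400,
    # enhancers
    n_se = 60,
    n_tye = 400,
    constituents_per_se = 6,      # Poisson mean on top of a minimum of 2
    se_const_width = c(800, 2000),
    se_const_gap = c(1000, 4000),
    tye_width = c(400, 1200),
    se_density_meanlog = log(15), se_density_sdlog = 0.3,
    tye_density_meanlog = log(2.5), tye_density_sdlog = 0.25,
    mirna_marking_prob_se = 0.25,
    mirna_marking_prob_tye = 0.04,
    n_mirna_promoter_peaks = 50,
    # G4 tracts
    g4_tract_rate = 10,           # per Mb
    g4_loop_max = 3,
    # interactions
    conditions = c("Ctrl", "TGFB1", "TGFB1_LOF"),
    n_loops = 200,
    loop_baseline_mean = 50, loop_nb_size = 20,
    response_log2 = matrix(c(2, 0,    # up after TGFB1, reverted by LOF
                             2, 2,    # up, not reverted
                             0, 0,    # flat
                             -2, -2), # down in both
                           nrow = 4, byrow = TRUE,
                           dimnames = list(NULL, c("TGFB1", "TGFB1_LOF"))),
    loop_noise_sd = 0.1,
    n_background_pairs = 800,
    bin_resolution = 25000,
    # expression
    expr_conditions = c("Ctrl", "LOF"),
    frac_affected = 0.2,
    frac_down_among_affected = 0.735,
    de_effect_log2 = 1.2,
    expr_mu_meanlog = log(500), expr_mu_sdlog = 1,
    expr_nb_size = 80
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field: ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  stopifnot(abs(sum(cfg$breadth_fractions) - 1) < 1e-9,
            all(unlist(cfg[c("mirna_marking_prob_se", "mirna_marking_prob_tye")]) >= 0),
            all(unlist(cfg[c("mirna_marking_prob_se", "mirna_marking_prob_tye")]) <= 1))
  structure(cfg, class = "synthetic_config")
}

# truncated-normal widths by rejection; deterministic given the RNG state
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

# sequential layout along the chromosomes: elements (given footprints, in a
# caller-shuffled order) are placed left to right with random gaps, keeping
# every pair separated by more than the stitching distance
layout_sequential <- function(footprints, chrom_names, chrom_length,
                              margin = 50000, gap_range = c(13000, 20000)) {
  n <- length(footprints)
  chrom <- character(n); start <- numeric(n)
  ci <- 1
  cursor <- margin
  for (i in seq_len(n)) {
    cursor <- cursor + round(stats::runif(1, gap_range[1], gap_range[2]))
    if (cursor + footprints[i] > chrom_length - margin) {
      ci <- ci + 1
      if (ci > length(chrom_names))
        stop("chromosomes too short for requested layout")
      cursor <- margin + round(stats::runif(1, gap_range[1], gap_range[2]))
    }
    chrom[i] <- chrom_names[ci]
    start[i] <- cursor
    cursor <- cursor + footprints[i]
  }
  data.frame(chrom = chrom, start = start, stringsAsFactors = FALSE)
}

# non-overlapping placements on a jittered slot grid
place_on_grid <- function(n, chrom_names, chrom_length, slot, margin = 50000,
                          jitter = 0.3) {
  slots_per_chrom <- floor((chrom_length - 2 * margin) / slot)
  total <- slots_per_chrom * length(chrom_names)
  if (n > total) stop("too many placements requested")
  pick <- sort(sample(total, n))
  chrom_i <- (pick - 1) %/% slots_per_chrom
  slot_i <- (pick - 1) %% slots_per_chrom
  pos <- margin + slot_i * slot +
    round(stats::runif(n, 0, jitter * slot))
  data.frame(chrom = chrom_names[chrom_i + 1], pos = pos,
             stringsAsFactors = FALSE)
}

#' Generate the toy genome with planted G-quadruplex tracts
#'
#' Random background sequence at the configured GC content; G4 tracts of
#' the form `GGG (N-loop GGG) x 3` with A/T loops of 1 to `g4_loop_max` nt
#' are substituted at the configured rate and their coordinates recorded.
#'
#' @param cfg a `synthetic_config`.
#' @return list with `sequences` (named character vector), `chrom_sizes`
#'   (named vector) and `g4_truth` (`interval_set` of planted tracts).
#'   Does not touch the RNG stream beyond its own draws; call within
#'   [generate_all()] for file output.
#' @export
generate_genome <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
                  G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  seqs <- list()
  truth <- list()
  n_tracts <- round(cfg$g4_tract_rate * cfg$chrom_length / 1e6)
  for (ch in chroms) {
    s <- sample(names(base_probs), cfg$chrom_length, replace = TRUE,
                prob = base_probs)
    if (n_tracts > 0) {
      at <- place_on_grid(n_tracts, ch, cfg$chrom_length,
                          slot = floor(cfg$chrom_length / (n_tracts + 2)),
                          margin = 1000, jitter = 0.5)
      starts <- numeric(n_tracts); ends <- numeric(n_tracts)
      for (i in seq_len(n_tracts)) {
        loops <- sample(cfg$g4_loop_max, 3, replace = TRUE)
        tract <- unlist(lapply(1:4, function(k) {
          c(rep("G", 3),
            if (k < 4) sample(c("A", "T"), loops[k], replace = TRUE))
        }))
        p0 <- at$pos[i]
        s[(p0 + 1):(p0 + length(tract))] <- tract
        starts[i] <- p0
        ends[i] <- p0 + length(tract)
      }
      truth[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                                stringsAsFactors = FALSE)
    }
    seqs[[ch]] <- paste(s, collapse = "")
  }
  g4_truth <- if (length(truth)) {
    df <- do.call(rbind, truth)
    interval_set(df$chrom, df$start, df$end)
  } else interval_set()
  list(sequences = unlist(seqs),
       chrom_sizes = stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms),
       g4_truth = g4_truth)
}

# internal: random gene models on the slot grid
generate_genes <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  at <- place_on_grid(cfg$n_genes, chroms, cfg$chrom_length, slot = 30000)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  es <- vector("list", cfg$n_genes); ee <- vector("list", cfg$n_genes)
  tss <- numeric(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    k <- sample(3:8, 1)
    exlen <- sample(150:800, k, replace = TRUE)
    inlen <- sample(500:3000, k - 1, replace = TRUE)
    starts <- at$pos[i] + c(0, cumsum(exlen[-k] + inlen))
    es[[i]] <- starts
    ee[[i]] <- starts + exlen
    tss[i] <- if (strand[i] == "+") starts[1] else max(ee[[i]]) - 1
  }
  gene_models(sprintf("gene%03d", seq_len(cfg$n_genes)), at$chrom, strand,
              tss, es, ee)
}

#' Generate peak sets, signal track and marking truth
#'
#' Emits H3K4me3 peaks with planted breadth classes (widths from the
#' three-mode mixture; peaks at gene TSSs, at SE centers and intergenic),
#' H3K27ac constituents in SE clusters and TYE singletons with an
#' SE-biased per-bp signal density, and miRNA occupancy peaks overlapping
#' SE constituents with probability `mirna_marking_prob_se` and TYEs with
#' `mirna_marking_prob_tye`.
#'
#' @param cfg a `synthetic_config`.
#' @param genes a `gene_models` object (from the same seeded run).
#' @return list with `k4me3`, `k27ac`, `mirna` (`interval_set`s), `signal`
#'   (bedGraph-style `interval_set`), and truth tables `breadth_truth`,
#'   `se_truth` (planted SE/TYE regions with `is_super` and
#'   `mirna_marked`).
#' @export
generate_peaks <- function(cfg, genes) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  n <- cfg$n_k4me3_peaks
  counts <- round(n * cfg$breadth_fractions)
  counts["narrow"] <- n - counts["broad"] - counts["medium"]
  cls <- sample(rep(names(counts), counts))
  widths <- numeric(n)
  for (cl in names(counts)) {
    i <- which(cls == cl)
    widths[i] <- rtrunc_norm(length(i), cfg$breadth_mean[cl], cfg$breadth_sd[cl],
                             cfg$breadth_range[[cl]][1], cfg$breadth_range[[cl]][2])
  }
  # --- enhancer clusters first (their centers also host K4me3 peaks) ---
  # draw per-SE constituent structure, then lay SEs and TYEs out along the
  # chromosomes in shuffled order, always > stitch distance apart
  se_struct <- lapply(seq_len(cfg$n_se), function(i) {
    nc <- 2 + stats::rpois(1, cfg$constituents_per_se - 2)
    w <- round(stats::runif(nc, cfg$se_const_width[1], cfg$se_const_width[2]))
    g <- round(stats::runif(nc, cfg$se_const_gap[1], cfg$se_const_gap[2]))
    offs <- c(0, cumsum(w[-nc] + g[-nc]))
    list(w = w, offs = offs, span = offs[nc] + w[nc])
  })
  tye_w <- round(stats::runif(cfg$n_tye, cfg$tye_width[1], cfg$tye_width[2]))
  footprints <- c(vapply(se_struct, `[[`, numeric(1), "span"), tye_w)
  ord <- sample(length(footprints))
  at <- layout_sequential(footprints[ord], chroms, cfg$chrom_length,
                          margin = 80000)
  at <- at[order(ord), , drop = FALSE]     # back to SE-then-TYE order
  se_at <- at[seq_len(cfg$n_se), ]
  tye_at <- at[cfg$n_se + seq_len(cfg$n_tye), ]
  k27 <- list(); se_regions <- list()
  for (i in seq_len(cfg$n_se)) {
    st <- se_struct[[i]]
    nc <- length(st$w)
    starts <- se_at$start[i] + st$offs
    dens <- stats::rlnorm(nc, cfg$se_density_meanlog, cfg$se_density_sdlog)
    k27[[i]] <- data.frame(chrom = se_at$chrom[i], start = starts,
                           end = starts + st$w, dens = dens,
                           enh = paste0("SE", i), stringsAsFactors = FALSE)
    se_regions[[i]] <- data.frame(chrom = se_at$chrom[i], start = starts[1],
                                  end = starts[nc] + st$w[nc], name = paste0("SE", i),
                                  is_super = TRUE, stringsAsFactors = FALSE)
  }
  tye_dens <- stats::rlnorm(cfg$n_tye, cfg$tye_density_meanlog, cfg$tye_density_sdlog)
  tye_df <- data.frame(chrom = tye_at$chrom, start = tye_at$start,
                       end = tye_at$start + tye_w, dens = tye_dens,
                       enh = paste0("TYE", seq_len(cfg$n_tye)),
                       stringsAsFactors = FALSE)
  k27df <- rbind(do.call(rbind, k27), tye_df)
  se_truth <- rbind(do.call(rbind, se_regions),
                    data.frame(chrom = tye_df$chrom, start = tye_df$start,
                               end = tye_df$end, name = tye_df$enh,
                               is_super = FALSE, stringsAsFactors = FALSE))
  # --- K4me3 peak placement: gene TSSs, SE centers, then intergenic ---
  n_at_tss <- min(cfg$n_genes, n - cfg$n_se)
  centers <- c(genes$tss[seq_len(n_at_tss)] + sample(-200:200, n_at_tss, replace = TRUE),
               round((se_truth$start[seq_len(cfg$n_se)] +
                        se_truth$end[seq_len(cfg$n_se)]) / 2))
  center_chrom <- c(genes$chrom[seq_len(n_at_tss)], se_truth$chrom[seq_len(cfg$n_se)])
  n_rest <- n - length(centers)
  if (n_rest > 0) {
    rest <- place_on_grid(n_rest, chroms, cfg$chrom_length, slot = 40000,
                          margin = 60000, jitter = 0.2)
    centers <- c(centers, rest$pos)
    center_chrom <- c(center_chrom, rest$chrom)
  }
  k4_start <- pmax(0, centers - floor(widths / 2))
  k4 <- interval_set(center_chrom, k4_start, k4_start + widths,
                     name = sprintf("k4me3_%03d", seq_len(n)))
  breadth_truth <- data.frame(name = k4$name, width = widths, class = cls,
                              stringsAsFactors = FALSE)
  # --- miRNA occupancy peaks ---
  mark_se <- stats::runif(cfg$n_se) < cfg$mirna_marking_prob_se
  mark_tye <- stats::runif(cfg$n_tye) < cfg$mirna_marking_prob_tye
  se_truth$mirna_marked <- c(mark_se, mark_tye)
  mir <- list()
  for (i in which(mark_se)) {
    const <- k27[[i]]
    j <- sample(nrow(const), 1)
    w <- sample(300:800, 1)
    st <- const$start[j] + sample(0:max(1, const$end[j] - const$start[j] - w), 1)
    mir[[length(mir) + 1]] <- data.frame(chrom = const$chrom[j], start = st,
                                         end = st + w, stringsAsFactors = FALSE)
  }
  for (i in which(mark_tye)) {
    w <- sample(300:800, 1)
    st <- tye_df$start[i] + sample(0:max(1, tye_df$end[i] - tye_df$start[i] - 50), 1) - w %/% 2
    mir[[length(mir) + 1]] <- data.frame(chrom = tye_df$chrom[i],
                                         start = max(0, st), end = max(0, st) + w,
                                         stringsAsFactors = FALSE)
  }
  if (cfg$n_mirna_promoter_peaks > 0) {
    gi <- sample(cfg$n_genes, cfg$n_mirna_promoter_peaks)
    w <- sample(300:800, cfg$n_mirna_promoter_peaks, replace = TRUE)
    st <- pmax(0, genes$tss[gi] - w %/% 2)
    mir[[length(mir) + 1]] <- data.frame(chrom = genes$chrom[gi], start = st,
                                         end = st + w, stringsAsFactors = FALSE)
  }
  mirdf <- do.call(rbind, mir)
  mirna <- if (is.null(mirdf)) interval_set() else
    sort_intervals(interval_set(mirdf$chrom, mirdf$start, mirdf$end,
                                name = sprintf("mir_%03d", seq_len(nrow(mirdf)))))
  list(k4me3 = k4,
       k27ac = interval_set(k27df$chrom, k27df$start, k27df$end, name = k27df$enh),
       mirna = mirna,
       signal = interval_set(k27df$chrom, k27df$start, k27df$end,
                             score = round(k27df$dens, 4)),
       breadth_truth = breadth_truth,
       se_truth = se_truth)
}

#' Generate condition-dependent promoter-enhancer interactions
#'
#' Plants `n_loops` promoter-SE pairs with negative-binomial baseline
#' frequencies and one of four response archetypes (per-condition log2
#' multipliers from `cfg$response_log2` plus log-normal noise), and adds
#' distance-decaying background pairs.
#'
#' @param cfg a `synthetic_config`.
#' @param genes a `gene_models` object.
#' @param se_truth the SE truth table from [generate_peaks()].
#' @return list with `pairs` (an `interaction_pairs` data frame over all
#'   conditions) and `loop_truth` (locus, gene, anchors, planted archetype
#'   and per-condition frequency).
#' @export
generate_interactions <- function(cfg, genes, se_truth) {
  se <- se_truth[se_truth$is_super, , drop = FALSE]
  conds <- cfg$conditions
  ctrl <- conds[1]
  n <- cfg$n_loops
  gi <- integer(n); si <- integer(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- sample(nrow(se), 1)
      cand <- which(genes$chrom == se$chrom[s])
      g <- cand[sample(length(cand), 1)]
      if (!paste(g, s) %in% seen) break
    }
    seen <- c(seen, paste(g, s))
    gi[i] <- g
    si[i] <- s
  }
  arch <- sample(nrow(cfg$response_log2), n, replace = TRUE)
  baseline <- stats::rnbinom(n, mu = cfg$loop_baseline_mean, size = cfg$loop_nb_size) + 5
  se_center <- round((se$start[si] + se$end[si]) / 2)
  prom_start <- pmax(0, genes$tss[gi] - 2000)
  freq <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  freq[, ctrl] <- pmax(1, round(baseline * 2^stats::rnorm(n, 0, cfg$loop_noise_sd)))
  for (cc in setdiff(conds, ctrl)) {
    mult <- cfg$response_log2[arch, cc]
    freq[, cc] <- pmax(0, round(baseline * 2^(mult + stats::rnorm(n, 0, cfg$loop_noise_sd))))
  }
  planted <- lapply(conds, function(cc) {
    interaction_pairs(genes$chrom[gi], prom_start, prom_start + 4000,
                      se$chrom[si], se_center - 1000, se_center + 1000,
                      freq[, cc], cc)
  })
  # distance-decay background pairs, independent counts per condition
  nb <- cfg$n_background_pairs
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  bchrom <- sample(chroms, nb, replace = TRUE)
  b1 <- round(stats::runif(nb, 5e4, cfg$chrom_length - 2e5))
  d <- round(stats::rexp(nb, rate = 1 / 4e5)) + 3e4
  b2 <- pmin(b1 + d, cfg$chrom_length - 6e4)
  bg <- lapply(conds, function(cc) {
    mu <- pmax(0.5, 8 * (5e4 / d)^0.7)
    interaction_pairs(bchrom, b1, b1 + 2000, bchrom, b2, b2 + 2000,
                      stats::rnbinom(nb, mu = mu, size = 2) + 1, cc)
  })
  all_pairs <- do.call(rbind, c(planted, bg))
  loop_truth <- data.frame(locus = sprintf("loop%03d", seq_len(n)),
                           gene_id = genes$gene_id[gi], se_name = se$name[si],
                           chrom = genes$chrom[gi],
                           promoter_start = prom_start,
                           distal_start = se_center - 1000,
                           archetype = arch, stringsAsFactors = FALSE)
  for (cc in conds) loop_truth[[paste0("freq_", cc)]] <- freq[, cc]
  list(pairs = structure(all_pairs, class = c("interaction_pairs", "data.frame")),
       loop_truth = loop_truth)
}

#' Generate an expression count table with planted regulation
#'
#' Negative-binomial counts per gene and condition; a configured fraction
#' of genes carries a planted effect (split down/up per
#' `frac_down_among_affected`) of magnitude `de_effect_log2` in the
#' non-control condition.
#'
#' @param cfg a `synthetic_config`.
#' @param genes a `gene_models` object.
#' @return list with `expression` (data frame gene_id, length_kb, one
#'   count column per condition) and `de_truth` (gene_id, planted class).
#' @export
generate_expression <- function(cfg, genes) {
  n <- nrow(genes)
  mu <- stats::rlnorm(n, cfg$expr_mu_meanlog, cfg$expr_mu_sdlog)
  n_aff <- round(cfg$frac_affected * n)
  n_down <- round(cfg$frac_down_among_affected * n_aff)
  cls <- rep("unchanged", n)
  aff <- sample(n, n_aff)
  cls[aff[seq_len(n_down)]] <- "down"
  cls[aff[-seq_len(n_down)]] <- "up"
  eff <- ifelse(cls == "down", -cfg$de_effect_log2,
                ifelse(cls == "up", cfg$de_effect_log2, 0))
  conds <- cfg$expr_conditions
  out <- data.frame(gene_id = genes$gene_id, length_kb = genes$length_kb,
                    stringsAsFactors = FALSE)
  out[[paste0("count_", conds[1])]] <- stats::rnbinom(n, mu = mu, size = cfg$expr_nb_size)
  for (cc in conds[-1])
    out[[paste0("count_", cc)]] <- stats::rnbinom(n, mu = mu * 2^eff,
                                                  size = cfg$expr_nb_size)
  list(expression = out,
       de_truth = data.frame(gene_id = genes$gene_id, de_class = cls,
                             stringsAsFactors = FALSE))
}

#' Generate the full synthetic dataset on disk
#'
#' Runs every generator stage under one seed and writes FASTA,
#' chrom.sizes, BED peak sets, the bedGraph signal track, per-condition
#' BEDPE pair files, the expression table, the gene models and a `truth/`
#' directory with the planted ground-truth tables.
#'
#' @param cfg a `synthetic_config`.
#' @param dir output directory (created).
#' @return invisibly, a list of all generated objects plus `paths`.
#' @export
generate_all <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  genome <- generate_genome(cfg)
  genes <- generate_genes(cfg)
  peaks <- generate_peaks(cfg, genes)
  inter <- generate_interactions(cfg, genes, peaks$se_truth)
  expr <- generate_expression(cfg, genes)

  p <- function(...) file.path(dir, ...)
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, p("genome.fa"))
  writeLines(paste(names(genome$chrom_sizes), genome$chrom_sizes, sep = "\t"),
             p("chrom.sizes"))
  write_gene_models(genes, p("gene_models.tsv"))
  write_intervals(peaks$k4me3, p("h3k4me3.bed"))
  write_intervals(peaks$k27ac, p("h3k27ac.bed"))
  write_intervals(peaks$mirna, p("mir9.bed"))
  sig <- as.data.frame(peaks$signal)
  utils::write.table(sig[, c("chrom", "start", "end", "score")],
                     p("h3k27ac.bedgraph"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (cc in cfg$conditions)
    write_pairs(inter$pairs[inter$pairs$condition == cc, ],
                p(paste0("pairs_", cc, ".bedpe")))
  utils::write.table(expr$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_intervals(genome$g4_truth, p("truth", "g4_tracts.bed"))
  utils::write.table(peaks$breadth_truth, p("truth", "breadth_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(peaks$se_truth, p("truth", "enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inter$loop_truth, p("truth", "loops.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$de_truth, p("truth", "de_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cfg = cfg, genome = genome, genes = genes, peaks = peaks,
                 interactions = inter, expression = expr,
                 paths = list(dir = dir)))
}

#' Audit a generated dataset against its truth files
#'
#' Self-consistency checks: every truth record corresponds to emitted
#' data (planted G4 tracts lie inside the genome and spell G-runs; truth
#' peak names and widths match the BED files; per-condition BEDPE
#' frequencies match the loop truth).
#'
#' @param dir a directory written by [generate_all()].
#' @return `TRUE` (invisibly) or an error describing the inconsistency.
#' @export
audit_synthetic <- function(dir) {
  p <- function(...) file.path(dir, ...)
  sizes <- utils::read.delim(p("chrom.sizes"), header = FALSE)
  genome <- stats::setNames(sizes$V2, sizes$V1)
  g4 <- read_intervals(p("truth", "g4_tracts.bed"), genome = genome)
  seqs <- Biostrings::readDNAStringSet(p("genome.fa"))
  for (i in seq_len(nrow(g4))) {
    tract <- as.character(Biostrings::subseq(seqs[[g4$chrom[i]]],
                                             g4$start[i] + 1, g4$end[i]))
    if (!grepl("^GGG", tract) || !grepl("GGG$", tract))
      stop("planted G4 tract ", i, " does not start/end with a G-run")
  }
  k4 <- read_intervals(p("h3k4me3.bed"), genome = genome)
  bt <- utils::read.delim(p("truth", "breadth_classes.tsv"))
  if (!identical(bt$name, k4$name) || !identical(as.numeric(bt$width), interval_width(k4)))
    stop("breadth truth does not match h3k4me3.bed")
  lt <- utils::read.delim(p("truth", "loops.tsv"))
  for (cc in grep("^freq_", names(lt), value = TRUE)) {
    cond <- sub("^freq_", "", cc)
    pr <- read_pairs(p(paste0("pairs_", cond, ".bedpe")), cond)
    key <- paste(pr$chrom1, pr$start1, pr$start2)
    # pairs are canonicalized unordered; match either anchor orientation
    m1 <- match(paste(lt$chrom, lt$promoter_start, lt$distal_start), key)
    m2 <- match(paste(lt$chrom, lt$distal_start, lt$promoter_start), key)
    m <- ifelse(is.na(m1), m2, m1)
    if (any(is.na(m)) || !all(pr$frequency[m] == lt[[cc]]))
      stop("loop truth does not match pairs_", cond, ".bedpe")
  }
  invisible(TRUE)
}
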