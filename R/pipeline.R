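#' Best-permutation agreement between planted labels and clusters
#'
#' Fraction of loci on which the clustering agrees with the planted
#' labels under the best one-to-one relabelling of clusters (exact search
#' over all permutations; intended for small k).
#'
#' @param truth integer planted labels in `1..k`.
#' @param cluster integer cluster assignments in `1..k`.
#' @param k number of clusters.
#' @return agreement in `[0, 1]`.
#' @export
cluster_agreement <- function(truth, cluster, k = max(c(truth, cluster))) {
  stopifnot(length(truth) == length(cluster))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[cluster] == truth))
  best
}

#' Run the full analysis on a dataset directory
#'
#' Executes every stage of the analysis on the files written by
#' [generate_all()] (or real data in the same layout): breadth
#' classification and region annotation of H3K4me3 peaks, ROSE-style SE
#' calling with miRNA marking and enrichment test, genome G4 scanning and
#' peak filtering, hub construction/normalization, promoter-loop calling
#' and condition-response clustering, and expression classification.
#'
#' @param dir dataset directory.
#' @param params named list of stage parameters overriding the defaults
#'   (`stitch_distance` 12500, `g4_window` 25, `g4_threshold` 1.2,
#'   `min_hub_frequency` 10, `bin_resolution` 25000, `k` 4,
#'   `promoter_halfwidth` 2000, `de_cutoff` 0.58, `ctrl` `"Ctrl"`,
#'   `cluster_seed` 1).
#' @return an `analysis_result` list with one element per stage.
#' @export
analyze_dataset <- function(dir, params = list()) {
  pp <- list(stitch_distance = 12500, g4_window = 25, g4_threshold = 1.2,
             min_hub_frequency = 10, bin_resolution = 25000, k = 4,
             promoter_halfwidth = 2000, de_cutoff = 0.58, ctrl = "Ctrl",
             cluster_seed = 1)
  pp[names(params)] <- params
  p <- function(...) file.path(dir, ...)
  for (f in c("chrom.sizes", "h3k4me3.bed", "h3k27ac.bed", "mir9.bed",
              "h3k27ac.bedgraph", "gene_models.tsv", "expression.tsv"))
    if (!file.exists(p(f))) stop("missing input file: ", p(f))
  sizes <- utils::read.delim(p("chrom.sizes"), header = FALSE)
  genome <- stats::setNames(sizes$V2, sizes$V1)
  genes <- read_gene_models(p("gene_models.tsv"))
  k4 <- read_intervals(p("h3k4me3.bed"), genome = genome)
  k27 <- read_intervals(p("h3k27ac.bed"), genome = genome)
  mir <- read_intervals(p("mir9.bed"), genome = genome)
  bg <- utils::read.delim(p("h3k27ac.bedgraph"), header = FALSE)
  signal <- interval_set(bg$V1, bg$V2, bg$V3, score = bg$V4)

  # --- breadth ---
  thresholds <- compute_breadth_thresholds(interval_width(k4))
  breadth <- classify_breadth(k4, thresholds)
  regions <- annotate_region(k4, genes, pp$promoter_halfwidth)
  region_counts <- table(regions$label)

  # --- super-enhancers ---
  stitched <- stitch_enhancers(k27, pp$stitch_distance)
  sig_sum <- enhancer_signal(stitched, signal)
  ranking <- rank_and_cutoff(stitched, sig_sum)
  enh <- classify_enhancer_size(ranking$enhancers)
  enh <- mark_by_mirna(enh, mir)
  marking <- marking_enrichment_test(sum(enh$is_super & enh$mirna_marked),
                                     sum(enh$is_super),
                                     sum(!enh$is_super & enh$mirna_marked),
                                     sum(!enh$is_super))

  # --- G4 ---
  g4 <- if (file.exists(p("genome.fa")))
    scan_genome_g4(p("genome.fa"), pp$g4_window, pp$g4_threshold)
  else interval_set()
  mir_g4 <- filter_peaks_by_g4(mir, g4)

  # --- loops and hubs ---
  pair_files <- list.files(dir, pattern = "^pairs_.*\\.bedpe$", full.names = TRUE)
  conds <- sub("^pairs_(.*)\\.bedpe$", "\\1", basename(pair_files))
  hubs <- list(); loops <- list()
  for (i in seq_along(pair_files)) {
    pr <- read_pairs(pair_files[i], conds[i])
    binned <- bin_pairs(pr, pp$bin_resolution)
    hubs[[conds[i]]] <- filter_normalize_hubs(build_hubs(binned),
                                              pp$min_hub_frequency)
    loops[[conds[i]]] <- call_promoter_loops(pr, k4, genes,
                                             pp$promoter_halfwidth)
  }
  clusters <- NULL
  if (pp$ctrl %in% conds && length(conds) > 1) {
    keyed <- lapply(loops, function(l)
      stats::setNames(l$frequency,
                      paste(l$chrom, l$promoter_start, l$distal_start)))
    common <- Reduce(intersect, lapply(keyed, names))
    if (length(common) >= pp$k) {
      tab <- vapply(keyed, function(v) v[common], numeric(length(common)))
      rownames(tab) <- common
      clusters <- cluster_interaction_profiles(tab, k = pp$k,
                                               seed = pp$cluster_seed,
                                               ctrl = pp$ctrl)
    }
  }
  hub_mir_overlap <- if (pp$ctrl %in% conds)
    count_hub_overlap_with_peaks(hubs[[pp$ctrl]], mir) else NULL

  # --- expression ---
  expr <- utils::read.delim(p("expression.tsv"))
  count_cols <- grep("^count_", names(expr), value = TRUE)
  rp <- vapply(count_cols, function(cc)
    rpkm(expr[[cc]], expr$length_kb, sum(expr[[cc]])), numeric(nrow(expr)))
  lfc <- log2((rp[, 2] + 0.01) / (rp[, 1] + 0.01))
  de <- classify_de(lfc, pp$de_cutoff)

  structure(list(params = pp, genome = genome,
                 thresholds = thresholds, breadth = breadth,
                 regions = regions, region_counts = region_counts,
                 ranking = ranking, enhancers = enh, marking = marking,
                 g4_regions = g4, mir_g4 = mir_g4,
                 hubs = hubs, loops = loops, clusters = clusters,
                 hub_mir_overlap = hub_mir_overlap,
                 expression = expr, log2fc = lfc, de = de,
                 k4 = k4, mir = mir, genes = genes),
            class = "analysis_result")
}

#' Compare an analysis against the planted truth
#'
#' @param dir dataset directory written by [generate_all()].
#' @param res optional precomputed [analyze_dataset()] result for `dir`.
#' @return list of recovery metrics: `breadth_accuracy`, `se_precision`,
#'   `se_recall`, `g4_tract_coverage`, `cluster_agreement`,
#'   `marking_p`, `pct_se_marked`, `pct_tye_marked`, `pct_de_down`,
#'   `pct_de_up`, `hub_mir_pct`.
#' @export
planted_recovery_metrics <- function(dir, res = analyze_dataset(dir)) {
  p <- function(...) file.path(dir, ...)
  bt <- utils::read.delim(p("truth", "breadth_classes.tsv"))
  breadth_accuracy <- mean(as.character(res$breadth$class) ==
                             bt$class[match(res$k4$name, bt$name)])
  st <- utils::read.delim(p("truth", "enhancers.tsv"))
  true_se <- interval_set(st$chrom[st$is_super], st$start[st$is_super],
                          st$end[st$is_super])
  called <- res$enhancers[res$enhancers$is_super, , drop = FALSE]
  called_set <- if (nrow(called))
    interval_set(called$chrom, called$start, called$end) else interval_set()
  se_precision <- if (nrow(called))
    mean(intersect_intervals(called_set, true_se, "count") > 0) else 0
  se_recall <- mean(intersect_intervals(true_se, called_set, "count") > 0)
  g4t <- read_intervals(p("truth", "g4_tracts.bed"))
  g4_tract_coverage <- if (nrow(g4t))
    mean(intersect_intervals(g4t, res$g4_regions, "count") > 0) else NA_real_
  agreement <- NA_real_
  if (!is.null(res$clusters)) {
    lt <- utils::read.delim(p("truth", "loops.tsv"))
    truth_key <- paste(lt$chrom, lt$promoter_start, lt$distal_start)
    m <- match(rownames(res$clusters$profiles), truth_key)
    ok <- !is.na(m)
    if (any(ok))
      agreement <- cluster_agreement(lt$archetype[m[ok]],
                                     res$clusters$cluster[ok],
                                     k = nrow(res$clusters$centroids))
  }
  dt <- utils::read.delim(p("truth", "de_classes.tsv"))
  de <- as.character(res$de)
  n_de <- sum(de != "unchanged")
  list(breadth_accuracy = breadth_accuracy,
       se_precision = se_precision, se_recall = se_recall,
       g4_tract_coverage = g4_tract_coverage,
       cluster_agreement = agreement,
       marking_p = res$marking$p.value,
       pct_se_marked = res$marking$se_pct,
       pct_tye_marked = res$marking$tye_pct,
       pct_de_down = if (n_de) percent_of_total(sum(de == "down"), n_de) else NA_real_,
       pct_de_up = if (n_de) percent_of_total(sum(de == "up"), n_de) else NA_real_,
       de_truth_agreement = mean(de == dt$de_class[match(res$expression$gene_id,
                                                         dt$gene_id)]),
       hub_mir_pct = if (!is.null(res$hub_mir_overlap))
         res$hub_mir_overlap$percentage else NA_real_)
}

#' Run the complete pipeline
#'
#' Orchestrates synthetic generation (optional), breadth classification,
#' SE calling and marking, G4 scanning, loop/hub analysis with response
#' clustering, and expression statistics; writes per-stage TSV outputs
#' and a machine-readable JSON report of every headline statistic.
#'
#' @param config a named list or path to a YAML file. Recognized keys:
#'   `outdir` (required), `seed` (default 1), `simulate` (default `TRUE`;
#'   when `FALSE`, `data_dir` must point to an existing dataset), plus any
#'   parameter accepted by [analyze_dataset()] and any
#'   [synthetic_config()] override under `generator`.
#' @return invisibly, the report list (also written to
#'   `outdir/report.json`).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config must name an outdir")
  outdir <- config$outdir
  seed <- if (is.null(config$seed)) 1 else config$seed
  simulate <- if (is.null(config$simulate)) TRUE else isTRUE(config$simulate)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) {
    gen_args <- if (is.null(config$generator)) list() else config$generator
    cfg <- do.call(synthetic_config, c(list(seed = seed), gen_args))
    data_dir <- file.path(outdir, "data")
    message("stage simulate: seed=", seed, " -> ", data_dir)
    generate_all(cfg, data_dir)
  } else {
    data_dir <- config$data_dir
    if (is.null(data_dir) || !dir.exists(data_dir))
      stop("missing input path: ", if (is.null(data_dir)) "(data_dir unset)" else data_dir)
  }
  par_keys <- intersect(names(config),
                        c("stitch_distance", "g4_window", "g4_threshold",
                          "min_hub_frequency", "bin_resolution", "k",
                          "promoter_halfwidth", "de_cutoff", "ctrl",
                          "cluster_seed"))
  message("stage analyze: ", data_dir,
          if (length(par_keys)) paste0(" [", paste(par_keys, collapse = ","), "]"))
  res <- analyze_dataset(data_dir, config[par_keys])

  # per-stage outputs
  bo <- data.frame(name = res$k4$name, chrom = res$k4$chrom,
                   start = res$k4$start, end = res$k4$end,
                   width = res$breadth$width,
                   class = as.character(res$breadth$class),
                   region = as.character(res$regions$label))
  utils::write.table(bo, file.path(outdir, "breadth_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_rose_tables(res$ranking, outdir)
  enh_out <- as.data.frame(res$enhancers)
  enh_out$constituents <- NULL
  utils::write.table(enh_out, file.path(outdir, "enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_intervals(res$g4_regions, file.path(outdir, "g4_regions.bed"))
  for (cc in names(res$hubs))
    utils::write.table(res$hubs[[cc]], file.path(outdir, paste0("hubs_", cc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (cc in names(res$loops)) {
    utils::write.table(res$loops[[cc]],
                       file.path(outdir, paste0("loops_", cc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_loop_track(res$loops[[cc]],
                     file.path(outdir, paste0("loops_", cc, ".washu.txt")))
  }
  if (!is.null(res$clusters))
    utils::write.table(data.frame(locus = rownames(res$clusters$profiles),
                                  round(res$clusters$profiles, 4),
                                  cluster = res$clusters$cluster),
                       file.path(outdir, "interaction_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  de_out <- data.frame(gene_id = res$expression$gene_id,
                       log2fc = round(res$log2fc, 4),
                       de_class = as.character(res$de))
  utils::write.table(de_out, file.path(outdir, "de_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  de <- as.character(res$de)
  n_de <- sum(de != "unchanged")
  report <- list(
    seed = seed,
    breadth = list(q2 = res$thresholds$q2, q3 = res$thresholds$q3,
                   counts = as.list(table(res$breadth$class)),
                   region_counts = as.list(res$region_counts)),
    enhancers = list(n_total = nrow(res$enhancers),
                     n_super = sum(res$enhancers$is_super),
                     cutoff_signal = res$ranking$cutoff$cutoff_signal,
                     pct_se_marked = res$marking$se_pct,
                     pct_tye_marked = res$marking$tye_pct,
                     marking_fisher_p = res$marking$p.value,
                     size_classes = as.list(table(res$enhancers$size_class))),
    g4 = list(n_regions = nrow(res$g4_regions),
              n_mirna_peaks_on_g4 = nrow(res$mir_g4)),
    hubs = lapply(res$hubs, function(h)
      list(n = nrow(h), mean_normalized = mean(h$normalized_frequency))),
    hub_mirna_overlap_pct = if (!is.null(res$hub_mir_overlap))
      res$hub_mir_overlap$percentage else NULL,
    clusters = if (!is.null(res$clusters))
      list(sizes = res$clusters$sizes,
           centroids = apply(res$clusters$centroids, 1, round, digits = 4)) else NULL,
    expression = list(n_genes = nrow(res$expression), n_de = n_de,
                      pct_down = if (n_de) percent_of_total(sum(de == "down"), n_de) else NA,
                      pct_up = if (n_de) percent_of_total(sum(de == "up"), n_de) else NA))
  if (simulate)
    report$recovery <- planted_recovery_metrics(data_dir, res)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
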