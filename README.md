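# regmir

Integrative regulatory-genomics analysis of how a nuclear microRNA shapes
chromatin. The package is aimed at epigenomics analysts who have peak sets,
signal tracks, chromatin-interaction pairs and expression tables (BED /
bedGraph / BEDPE-like pairs / TSV / FASTA) and want a reproducible,
fully-tested implementation of five linked analyses:

1. **Histone-domain breadth** — classify H3K4me3 peaks as broad / medium /
   narrow by width quantiles: broad when width ≥ Q3, medium when
   Q2 ≤ width < Q3, narrow when width < Q2 (linear-interpolation
   percentiles), with promoter / gene-body / intergenic annotation and
   Fisher breadth-shift tests.
2. **Super-enhancer calling (ROSE-style)** — stitch H3K27ac constituents
   within 12.5 kb, rank by background-subtracted signal, min–max scale both
   axes of the ranked curve and cut at the first point where the discrete
   slope exceeds 1 (the "hockey stick" tangent rule); stratify SE/TYE by
   size and mark enhancers whose constituents are overlapped by miRNA
   occupancy peaks, with marked-fraction enrichment statistics.
3. **G-quadruplex propensity (G4Hunter-style)** — per-base run scores
   (+min(L,4) per G in a G-run of length L, −min(L,4) per C), sliding
   window means (25 nt), candidate-region calling at threshold 1.2, peak
   filtering by G4 coordinates, and IUPAC degenerate motif scanning
   (e.g. the nuclear-shuttling motif `AKYACCWUUUGRUWA`).
4. **Loops and hubs (HiChIP-derived)** — bin interaction anchors (25 kb),
   aggregate per-anchor interaction hubs, filter at frequency ≥ 10 and
   normalize to the retained-set mean, call promoter (TSS ± 2 kb) to
   H3K4me3 loops, down-sample conditions exactly, and k-means-cluster
   per-locus `log2((f + 1)/(f_Ctrl + 1))` response profiles (k = 4).
5. **Shared statistics** — two-tailed Fisher exact tests, RPKM, inclusive
   |log2FC| ≥ 0.58 differential classes, aggregate signal profiles,
   row-wise z-score matrices, exact Wilcoxon/t tests, half-up percentage
   reporting.

A seeded synthetic-data generator (`synthetic_config()` / `generate_all()`)
plants ground truth for every analysis — breadth classes, true SEs, G4
tracts, marking flags, loop-response archetypes, regulated genes — so the
whole pipeline is exercised end-to-end with known answers.

## Worked example

```r
library(regmir)

d <- file.path(tempdir(), "demo")
invisible(generate_all(synthetic_config(seed = 1), d))   # synthetic study
res <- analyze_dataset(d)                                # run every stage

res$thresholds
#> breadth thresholds from 400 peaks: Q1=1407.8 Q2=1974.5 Q3=2677.0 bp
table(res$breadth$class)
#>  broad medium narrow
#>    100    100    200
res$ranking
#> ROSE ranking: 460 enhancers, 60 super-enhancers (cutoff signal 4839)
m <- res$marking
sprintf("SE marked: %.1f%%  TYE marked: %.1f%%  Fisher p = %.2g",
        m$se_pct, m$tye_pct, m$p.value)
#> "SE marked: 26.7%  TYE marked: 3.8%  Fisher p = 6.9e-08"
res$clusters
#> k-means interaction clusters: 81, 51, 48, 49 loci per cluster
```

The breadth quantiles land near 2.0/2.7 kb (the scale seen in real H3K4me3
data); the ranked-signal cutoff separates exactly the 60 planted
super-enhancers from 400 typical enhancers; miRNA occupancy is enriched at
SEs (26.7% vs 3.8%, exact Fisher p ≈ 7e-08); and the four interaction
clusters recover the planted condition-response archetypes (the largest
cluster also absorbs background loops with flat profiles).
`planted_recovery_metrics(d)` quantifies each recovery against the truth
tables under `d/truth/`.

The same stages run from one configuration with
`run_all(list(outdir = "out", seed = 1))` (or a YAML file; see
`inst/scripts/regmir-pipeline.R` for a shell entry point), writing
per-stage TSVs and a machine-readable `report.json`.

## Layout

```
R/                  implementation (intervals, breadth, rose, g4, loops,
                    stats, synthetic, pipeline)
tests/testthat/     unit, property and acceptance suites with independent
                    brute-force oracles
vignettes/          methods vignette: models, conventions, design choices
scripts/            acceptance script
inst/scripts/       command-line pipeline wrapper
```
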