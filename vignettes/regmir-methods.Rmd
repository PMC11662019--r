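---
title: "Methods and design of the regmir analysis pipeline"
author: "regmir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the regmir analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmir)
```

## Scope

`regmir` implements an integrative regulatory-genomics workflow for studying
how a nuclear microRNA (the motivating system is nuclear miR-9 in mouse lung
cells) relates to chromatin structure. Five analytical components are
chained: (i) quantile-based breadth classification of H3K4me3 domains,
(ii) ROSE-style super-enhancer (SE) calling with miRNA-occupancy marking,
(iii) G4Hunter-style G-quadruplex (G4) propensity scoring,
(iv) HiChIP-derived promoter–enhancer loop and interaction-hub analysis with
condition-response clustering, and (v) the shared enrichment statistics.
A seeded synthetic-data generator with planted ground truth exercises the
whole chain end to end; real peak/pair/count files in the same standard
formats (BED, bedGraph, BEDPE-like pairs, TSV, FASTA) can be substituted
directly.

## Coordinate and interval model

All coordinates are 0-based half-open (BED convention); any 1-based input
must be converted at the reader boundary. Overlap means at least one shared
base, so bookended intervals (`[0,10)`, `[10,20)`) do not overlap but do
merge at gap 0. Strand is carried but ignored by every overlap operation.
Sorting ties break by `(chrom, start, end, name)` so outputs are
deterministic. Interval algebra is delegated to `GenomicRanges`/`IRanges`
internally; the package's tests nevertheless verify `merge_intervals()` and
`intersect_intervals()` against a per-base occupancy computation on toy
chromosomes, because every downstream result depends on these semantics.

## Breadth classification of histone domains

Peak widths are summarized by their 25/50/75-percentiles under linear
interpolation between order statistics (`stats::quantile`, type 7 — the most
common default; the type is configurable). The partition is exhaustive:

* broad: width ≥ Q3 (the top quartile),
* medium: Q2 ≤ width < Q3,
* narrow: width < Q2.

In the motivating H3K4me3 data these thresholds land near 2.0 kb (Q2) and
2.7 kb (Q3). A narrower reading that labels only the bottom quartile as
"narrow" would leave peaks between Q1 and Q2 unclassified; the exhaustive
Q2/Q3 partition was chosen so that every peak receives exactly one class,
which the tests assert. Region annotation gives each peak one coarse label
with precedence promoter (any overlap with TSS ± 2 kb) over gene body (any
overlap with the exon span) over intergenic; with exon structure available a
finer exon/intron detail is reported. Genomic-distribution comparisons use
`log2((obs + 1)/(ref + 1))` per category — the pseudocount of 1 keeps ratios
finite for empty categories. Breadth shifts between two peak sets are tested
with a two-tailed Fisher exact test on the (focus class vs rest) × (set A vs
set B) table.

## Super-enhancer calling

Constituent H3K27ac peaks within 12,500 bp of each other are stitched into
candidate enhancers (the ROSE default; TSS-window exclusion is available but
off by default, matching "default settings"). Enhancer signal is the summed
bedGraph coverage (value × covered width) over the stitched span, minus an
optional control track, floored at zero.

The hockey-stick cutoff follows the published ROSE geometry in an exactly
reproducible discrete form: enhancers are sorted by ascending net signal,
both axes are min–max scaled to [0, 1], and the cutoff is the signal at the
first ascending index where the slope between adjacent scaled points exceeds
1. Enhancers strictly above the cutoff signal are SEs; everything else is a
typical enhancer (TYE). Consequences asserted by tests: a flat signal vector
calls no SE; the partition is invariant to adding a constant to every signal
(scaling removes location); and the cutoff equals an exhaustive scan over
all candidate split points.

Size strata use the published boundaries — SE broad > 3.2 kb, SE medium
2.3–3.2 kb, SE narrow < 2.3 kb; TYE broad > 0.9 kb, TYE medium 0.6–0.9 kb,
TYE narrow < 0.6 kb. Because "broad" is a strict inequality, the medium
upper boundary is inclusive (a 3.2 kb SE is medium); the lower boundary is
inclusive as well. This is the only exhaustive assignment consistent with
the strict outer inequalities.

An enhancer is miRNA-marked when an occupancy peak shares at least one base
with a *constituent* peak — not with the stitched gap between constituents.
The rule reads "a miRNA peak overlaps an H3K27ac peak", which points at
constituents; a configuration switch (`on = "span"`) tests the full stitched
span instead for sensitivity analyses. Marking enrichment between SE and TYE
uses the two-tailed Fisher exact test on the marked/unmarked × SE/TYE table,
with percentages reported per class.

## G-quadruplex propensity

Per-base scores follow the G4Hunter run scheme: each G in a maximal G-run of
length L scores +min(L, 4), each C in a C-run scores −min(L, 4), everything
else (A/T/U/N) scores 0; U ≡ T throughout. Window scores are arithmetic
means over a sliding window, defaulting to 25 nt with a calling threshold of
1.2 — the published genome-scan defaults; both are configurable because the
original analysis only states "default settings". Candidate regions are
maximal runs of qualifying windows, spanning the first window's start to the
last window's end, with the mean score recomputed over the merged span.
No sub-window refinement (trimming to the maximal-scoring core) is
performed; regions are window-run unions, the simplest reproducible
definition. Peak filtering by G4 coordinates is plain interval intersection
(`report_a` semantics).

The strand antisymmetry property — the reverse complement's score profile is
the negated reverse of the original's — is asserted as an invariant, and the
run-based implementation is checked against a naive per-position oracle that
recomputes the run length at every base.

The degenerate nuclear-shuttling motif (e.g. `AKYACCWUUUGRUWA`) is scanned
with IUPAC semantics via `Biostrings`: K = G/T, Y = C/T, W = A/T, R = A/G,
with U ≡ T; an N in the scanned sequence never satisfies a degenerate
position, and minus-strand hits are found by scanning the reverse-complement
pattern.

## Loops, hubs and response clustering

Interaction pairs are unordered anchor pairs with non-negative counts.
Anchors snap to fixed-resolution bins (default 25 kb) and coincident binned
pairs aggregate; binning conserves total frequency. A *hub* is a distinct
anchor bin with the summed frequency of every pair touching it (self-pairs
counted once) — a transparent, anchor-centric stand-in for tool-internal hub
definitions that cannot be reproduced exactly. Hubs with total frequency
≥ 10 are retained and normalized to the retained-set mean, so normalized
frequencies average exactly 1 (asserted to 1e-12).

Promoter loops retain pairs with one anchor on a TSS ± 2 kb window and the
other on an H3K4me3 peak; self-loops (anchors sharing a bin or a TSS
window) are excluded. The original "significant interaction" model is
tool-internal; it is replaced by a transparent frequency-rank filter —
a loop must exceed the 0.99 quantile of frequency within its
distance-matched stratum (ten distance strata by default), echoing the
stated p ≤ 0.01 without re-implementing another tool's likelihood model.

Down-sampling to a target interaction total draws without replacement from
the pooled events (sequential hypergeometric conditioning), conserving the
target exactly and reproducibly per seed.

Response profiles are `log2((f_cond + 1)/(f_Ctrl + 1))` per locus — the
pseudocount avoids division by zero. Profiles are clustered with k-means
(k = 4) under a fixed seed with 50 random starts; multiple starts are the
standard guard against the bad local optima a single start produced on
well-separated archetypes. Degenerate inputs (fewer distinct profiles than
k) are assigned by profile identity with the centroid set padded to k, and
failed starts are re-seeded deterministically from the point farthest from
its centroid. Profiles are clustered raw (no per-locus standardization):
the magnitude of a response is part of the signal being grouped;
standardization is exposed upstream by transforming the table if desired.

## Statistics conventions

* Fisher exact tests are two-tailed by the probability-mass rule (sum of
  tables as or less probable than the observed one), the `stats::fisher.test`
  convention; the tests verify it against exhaustive hypergeometric
  enumeration.
* RPKM is `counts / (length_kb × library_size / 1e6)` with total mapped
  reads as the library size.
* Differential classes use inclusive boundaries at |log2FC| = 0.58
  (1.5-fold).
* Percentages are rounded half-up to one decimal, matching the reporting
  style of the source field (note `round()` in R rounds half to even, so a
  dedicated helper is used).
* Z-score matrices standardize rows with the sample (n − 1) standard
  deviation; a constant row is an error naming the offending factor.
* Wilcoxon tests are exact for combined n ≤ 25 without ties.
* No multiple-testing correction is applied by default (none of the
  reproduced analyses states one); `stats::p.adjust` can be applied to any
  returned p-value vector.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
sequencing reads. Defaults (all configurable through `synthetic_config()`):

* **Genome** — 2 chromosomes × 5 Mb at GC 0.42, large enough for stable
  quantiles and hundreds of enhancers, small enough to run the whole
  pipeline in well under a minute.
* **Breadth mixture** — 400 H3K4me3 peaks, 50% narrow / 25% medium / 25%
  broad with disjoint width ranges (0.8–1.9, 2.05–2.65, 2.8–5.2 kb,
  truncated normals). The fractions are deliberately aligned with the Q2/Q3
  classification rule: with exact class counts, the empirical median and
  upper quartile fall in the gaps between width modes, so planted classes
  are recoverable. Any mixture whose median falls inside a width mode would
  make perfect recovery impossible by construction — a property of the
  quantile rule, not of the implementation.
* **Enhancers** — 60 SE clusters (2+ constituents, Poisson mean 6, widths
  0.8–2 kb, gaps 1–4 kb) and 400 TYE singletons (0.4–1.2 kb), laid out
  sequentially along the chromosomes in shuffled order with 13–20 kb
  inter-enhancer gaps so stitching never merges distinct enhancers.
  Per-bp signal density is log-normal with SE mean 15 vs TYE mean 2.5,
  giving the order-of-magnitude aggregate-signal gap real hockey sticks
  show.
* **Marking** — miRNA peaks overlap SE constituents with probability 0.25
  and TYEs with 0.04 (the planted enrichment), plus 50 promoter peaks.
* **G4 tracts** — `(GGG N1–3)×4` with A/T loops, 10 per Mb. Loops are kept
  short so that a 25-nt window over a tract always averages above the 1.2
  threshold; with longer loops detectability would depend on flanking
  sequence.
* **Interactions** — 200 promoter–SE pairs with negative-binomial baselines
  (mean 50, size 20) and four response archetypes at |log2| = 2 with
  log-normal noise σ = 0.1 (TGFB1-up/LOF-reverted, up/up, flat, down/down),
  plus 800 distance-decaying background pairs per condition across
  conditions Ctrl / TGFB1 / TGFB1_LOF.
* **Expression** — 300 genes, negative-binomial counts (size 80), 20%
  affected, split 73.5% down / 26.5% up at |log2FC| = 1.2.

Everything is a deterministic function of one integer seed (R's default
RNG; no time or locale dependence), and truth tables are written as TSVs so
tests never re-derive ground truth through generation code paths.
`audit_synthetic()` re-checks emitted files against the truth.

What the generator does **not** emulate: mappability and blacklist
artifacts, chromatin-state autocorrelation, read-level noise, overlapping
or nested peaks, inter-chromosomal contacts, and replicate structure.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the planted model, not performance on real sequencing
data.

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere (configurable at the breadth boundary).
* All-equal signal vectors: no slope exceeds 1, so no SE is called;
  all-zero net signal is an error ("degenerate ranking").
* Empty hub set after frequency filtering is an error rather than an empty
  result, because a mean-normalization over nothing is undefined.
* `percent_of_total` rounds half-up via `floor(10 * x + 0.5) / 10`.
* Fisher enumeration tolerance: probabilities compared with a 1e-7 relative
  slack when accumulating the two-tailed mass.
* Down-sampling uses sequential `rhyper` conditioning — exact multivariate
  hypergeometric sampling without materializing individual events.

## Problem sizes

The default test and validation runs use the generator defaults above
(10 Mb genome, 400 peaks, 460 enhancers, ~1,000 pairs per condition ×
3 conditions, 300 genes); the oracle-equivalence suites use 46k exhaustive
2×2 tables plus seeded samples, 200 random 500-nt sequences, 100 random
signal vectors, and ≤ 50-interval toy chromosomes. These sizes were chosen
so the full suite and an end-to-end run each complete in minutes on a
single CPU while keeping every statistical check well-powered.

## Known limitations

* The hub definition is a fixed-resolution anchor-bin aggregate; numbers
  are not comparable to tool-specific hub counts from the motivating study.
* Loop significance is a rank filter, not a background likelihood model.
* The G4 caller reports window-run unions without maximal-core refinement.
* Region annotation implements the coarse promoter/gene-body/intergenic
  scheme only (plus exon/intron detail), not full annotator emulation.
* `rank_and_cutoff` assumes one signal column; replicate handling is left
  to the caller (e.g. average tracks before summing).
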