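---
title: "Methods: consensus variant prioritization and sequence hotspot detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus variant prioritization and sequence hotspot detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varhotspot)
```

# The problem

Population sequencing databases report thousands of rare missense variants
per gene, most of them variants of uncertain significance. For a gene with
a clinical phenotype — the motivating case is *NUP155*, an inner-ring
nucleoporin whose R391H and L503F missense alleles are associated with
atrial fibrillation — the analyst wants to know three things:

1. which reported variants are plausibly deleterious, judged jointly by
   several orthogonal predictors;
2. whether the plausible ones cluster in a contiguous stretch of the
   protein (a mutational hotspot, suggesting a functionally sensitive
   subdomain); and
3. how the gene's protein sits in its interaction network — whether its
   neighborhood has hub architecture whose disruption would propagate.

`varhotspot` implements this pipeline over plain annotation exports: no
live database queries, no score recomputation. Scores are consumed as
annotations, which keeps the package applicable to any gene with a
dbNSFP/gnomAD-style export.

# Consensus prioritization

Each variant carries up to six metrics: PolyPhen-2 class and score (0–1),
Grantham distance (5–215), PROVEAN (more negative = more deleterious),
SIFT (0–1, low = deleterious), PhastCons (0–1) and GERP (−12.3 to 6.17).
Per-metric pass rules, all configurable via `threshold_config()`:

| metric      | pass rule                                   | default cutoff |
|-------------|---------------------------------------------|----------------|
| PolyPhen-2  | class = probably-damaging AND score ≥ min   | 0.85           |
| Grantham    | ≥ cutoff (boundary inclusive)               | 125            |
| PROVEAN     | < cutoff (strict)                           | −2.5           |
| SIFT        | < cutoff (strict)                           | 0.05           |
| PhastCons   | ≥ cutoff                                    | 0.95           |
| GERP        | ≥ cutoff                                    | 2.0            |

A missing score is flagged `missing` and never passes. The Grantham
boundary is inclusive because published starred (deleterious) values
include 125 itself; PROVEAN and SIFT boundaries are strict per their usual
conventions. No standard numeric cutoffs exist for PhastCons/GERP; the
defaults were chosen once so that clearly conserved sites (PhastCons near
1, GERP above ~2) pass, and both are excluded from the class-only rule.

Three consensus modes are provided because the de facto practice in
prioritization studies is looser than "all metrics must pass": the
packaged 24-variant NUP155 list is reproduced by `class_only` with a
PolyPhen-2 score minimum of 0.97 (all 24 scores are ≥ 0.971, while many
fail the strict Grantham/PROVEAN/SIFT cutoffs); `all_metrics` gives the
strict reading (it selects the trio R672G, G754R, D429V from the packaged
table); `k_of_n` interpolates.

MAF benchmarking compares each variant's allele frequency (strictly
less-than) against the gnomAD frequencies of two confirmed pathogenic
*SCN5A* alleles: S216L (6.5×10⁻⁴, the strict-rare tier) and F2004L
(1.9×10⁻³, the second tier). Ranking uses the descending key
(`n_pass`, PolyPhen-2 score, −SIFT, −PROVEAN) with rsID as the final
tie-break; the key is not canonical in the field — it was chosen as the
simplest ordering that puts the strongest all-metric passers first and is
deterministic under ties.

# Hotspot detection

Given the `m` prioritized variant positions on a protein of length `L`
(default 1391, the NUP155 residue count):

1. **Candidates.** Every ordered pair `(i ≤ j)` of distinct position
   values defines a candidate cluster spanning `v[i]..v[j]`; `d` distinct
   values give `d(d+1)/2` candidates. No cluster size or length is
   pre-specified. Duplicate positions add multiplicity to interval counts
   but no extra candidates.
2. **Null model.** `B` bootstrap replicates (default 1000) each place `m`
   positions i.i.d. uniformly over `1..L` (with replacement — a residue
   can be hit twice). For each replicate and each `c ≤ m` the minimal span
   of a window containing `c` resampled positions is recorded.
3. **P-values.** A candidate with `n` variants over span `s` gets
   `p = (1 + #{replicates: min_width(c = n) ≤ s}) / (B + 1)`. The
   pseudocount keeps p-values strictly positive under a finite null; `p`
   is monotone (non-decreasing in span, non-increasing in `n`), and on
   tiny problems it matches exhaustive enumeration of all `L^m` draws
   (a property the test suite checks directly).
4. **Multiplicity.** Benjamini–Hochberg step-up across all candidates,
   significance at `q ≤ α` (default 0.05).
5. **Track.** Per-residue counts of covering significant clusters; the
   track sums to the total span of significant clusters and is written as
   bedGraph-like text (0-based half-open).

The procedure is deterministic given a seed, which is threaded through
`build_null()` without disturbing the caller's RNG stream.

**Bootstrap size and power.** The method's bootstrap size is `B = 1000`.
This matters for detection power, not just precision: with `B` replicates
the smallest attainable p-value is `1/(B+1)`, and BH across the ~300
candidates that 24 distinct positions generate needs roughly
`α·i/300 ≥ 1/(B+1)` at step `i`, so a small `B` imposes a hard floor on
how many near-floor candidates must co-occur before anything is callable.
Simulations during development (a planted cluster of 12 of 24 positions in
a 100-residue window of a 1391-residue protein) put recovery at about
85–90% with `B = 200` but essentially 100% with the default `B = 1000`,
at negligible cost (~40 ms per scan). The package therefore treats
`B = 1000` as the operating default; the test suite uses `B = 200` only
for null-calibration checks, where the p-value floor is conservative
rather than anti-conservative.

Under a uniform null (no planted structure) the same simulations call any
significant cluster in well under 10% of runs, consistent with FDR
control; with highly dependent candidate intervals BH is not exactly
nominal, but the dependence here is positive (shared null table, nested
intervals), the benign direction for step-up control.

# Domain assignment and enrichment

Subdomain intervals are 1-based inclusive protein coordinates
(`name`, `start`, `end`), validated to be non-overlapping; a position maps
to the unique covering interval or `"unassigned"`. Enrichment of `m`
positions in a domain of span `w` uses the exact one-sided binomial tail
`P(X ≥ observed)`, `X ~ Binomial(m, w/L)` — a deliberately transparent
choice with a trivially computable oracle, testing the same
uniform-placement null as the hotspot scan but at a fixed, biologically
named interval.

The packaged NUP155 subdomain file is a synthetic illustration (the
β-propeller/crescent/C-terminal stack boundaries are not published at
residue resolution) and is named accordingly; real analyses should supply
curated intervals.

# Network topology

Graphs are undirected and simple; SIF and 2/3-column TSV inputs are
supported, duplicate and reversed edges collapse, self-loops are dropped
with a warning. Conventions follow the Cytoscape Network Analyzer
tradition so that exported metrics are comparable:

* betweenness normalized by `(n−1)(n−2)/2`;
* closeness with fraction-reachable scaling for disconnected graphs,
  `(r/(n−1)) · (r/Σd)` over the `r` reachable nodes (isolates get 0),
  which reduces to ordinary normalized closeness on connected graphs;
* neighborhood connectivity = mean neighbor degree (`NaN` for isolates).

Disassortativity — the signature of hub architecture — is read from the
sign of the least-squares slope of log mean neighborhood connectivity
against log degree over degree classes, with a 10⁻⁹ tolerance around
zero; magnitude is not interpreted, since it depends on binning. Hub
ranking sorts by the chosen centrality, breaking ties by the other
centrality and then by label, so results are reproducible under label
permutation up to symmetry.

Computation is delegated to `igraph`; the test suite verifies all three
metrics against an independent path-enumeration oracle on every labeled
graph with up to six nodes, plus closed forms (path, complete graph,
star).

# Synthetic data

`gen_variant_table()` emulates what the pipeline assumes about real
exports: positions from a mixture of uniform background and weighted
hotspot intervals; a damaging/benign class label per variant
(`class_mix`); per-class beta-distributed scores over each metric's
declared range, shaped so that default thresholds separate the classes
imperfectly (roughly 5–15% overlap per metric) — a perfect separator
would make prioritization tests vacuous; log-uniform allele frequencies
over `10^[-5.4, -3.15]` (about 4×10⁻⁶–7×10⁻⁴, the observed span for rare
pathogenic-candidate missense alleles); heterozygous-only genotype
counts. Truth labels (class, in-hotspot status, position) ride along for
power and calibration tests.

What it does **not** emulate: linkage between position and damaging
class, population structure, site-specific mutability, annotation
missingness patterns, or correlated predictor scores. Passing tests
therefore demonstrate calibration and power under the stated generative
model, not performance on any particular real cohort.

`gen_ppi_graph()` grows preferential-attachment graphs (attachment weight
degree + 1, times a boost of 20 for planted hub labels seeded into the
initial core), giving heavy-tailed degree distributions and
disassortative mixing like curated interaction subnetworks (35 nodes per
subnetwork by convention; 175 for a merged five-subnetwork graph).

# Degenerate inputs and numerical choices

* Empty variant table: every stage returns an empty result; the pipeline
  skips the hotspot and domain stages when no positions remain.
* All-missing population counts: dominant population `"unknown"`.
* Ties in population counts: lexicographically smallest label, flagged.
* Duplicate rsIDs: first occurrence by row order wins (the filter order
  is indels → missing rsIDs → duplicates).
* Regular graphs (one degree class): assortativity slope is `NA`,
  mixing `"neutral/undefined"`.
* A domain covering the whole protein: enrichment `p = 1` with a warning.
* Pipeline manifests contain versions, seeds, digests and counts but no
  timestamps, so a fixed seed makes full runs bit-identical.

# Test problem sizes

The suite exercises: exhaustive p-value enumeration at `m ≤ 3, L ≤ 10`;
hotspot calibration and power at `m = 24, L = 1391` over 50 seeded runs
(`B = 200` for the null check, `B = 1000` for planted recovery);
exhaustive network-metric verification over all labeled graphs with
`n ≤ 6`; and 20-seed batches of 175-node preferential-attachment graphs.
These sizes keep the full suite in the minutes range on a single core
while leaving every statistical check with comfortable margins.

# Limitations

* The hotspot scan is one-dimensional; residues adjacent in 3-D but
  distant in sequence will not cluster.
* BH across overlapping interval candidates controls FDR only
  approximately under dependence (see above).
* The consensus rules treat predictors as independent oracles; correlated
  predictors (e.g. two conservation scores) are double-counted in
  `k_of_n`.
* Cross-database intersection joins on rsID only; variants lacking a
  stable rsID cannot be matched across sources.
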