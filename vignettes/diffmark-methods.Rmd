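---
title: "Methods: replicate-aware differential analysis of histone-mark peaks"
author: "diffmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-aware differential analysis of histone-mark peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

H3K4me3 is a chromatin mark of active promoters and, in male meiosis, of
recombination-initiation sites positioned by PRDM9. A toxicant exposure (or
any two-condition contrast) can redistribute these marks genome-wide.
`diffmark` implements the downstream computational analysis for such a
study: given replicate peak sets from a two-condition ChIP-seq experiment
it decides which peaks changed, where those changes fall in the genome,
whether they coincide with meiotic DSB hotspots, and how they relate to
gene-expression changes measured on arrays.

The package assumes peaks have already been called per sample (e.g. by
MACS); peak calling from read pileups, read alignment and IDR mixture-model
fitting are out of scope.

# The differential-peak procedure

The procedure is a fixed five-stage chain. The order matters and is tested:
the low-signal filter is computed over *reproducible* peaks only, never
over the raw peak sets.

1. **Reproducibility.** Within each condition, a peak is kept iff it shares
   at least `min_overlap` bases (default 1 bp) with a peak in every other
   replicate of that condition. This overlap screen replaces copula-based
   IDR: with two replicates per condition it asks the same question — is
   this peak supported twice? — with one transparent parameter. A kept
   peak is extended to the union span of itself and its partners, so no
   reproducible signal is clipped.
2. **Consensus.** The union of the control-reproducible and
   treated-reproducible sets is merged into disjoint consensus intervals
   (`mergeIntervals()`), each labelled `control-reproducible`,
   `treated-reproducible` or `both`, with ids assigned in chromosome
   order. The union-span choice keeps every testable base; a
   condition-specific peak still enters testing, which is what lets the
   test see gains and losses.
3. **Quantification.** Tags falling inside each consensus interval are
   counted per sample; library sizes are total tag counts (tags outside
   all peaks and on other chromosomes still count toward depth).
   Precomputed count matrices are accepted interchangeably.
4. **Normalization and filtering.** Counts are multiplied by
   `target / library_size` (target defaults to the mean library size —
   equivalent up to a constant to counts-per-million, but keeps values on
   the scale of raw tags), then transformed as `log2(x + 1)`. The
   pseudocount is configurable; 1 keeps zero counts at zero. Features
   whose mean log signal across all samples is not strictly above the
   nearest-rank (type-1) 5% quantile of those means are dropped. "Above"
   is strict, so a fully tied matrix is rejected with an instructive
   error rather than silently emptied. The mean is taken across all four
   samples, not per condition: filtering must not see the group labels,
   or it biases the test.
5. **Testing and calling.** A moderated two-group t-test (below) with
   Benjamini–Hochberg FDR adjustment; a peak is called differential iff
   its linear fold change satisfies `2^|log2FC| > 1.5` *and* `q < 0.05`,
   symmetric for gains and losses. Up/down tallies always partition the
   called set.

## The moderated t-test

With two replicates per condition, per-peak variance estimates have two
degrees of freedom and an ordinary t-test is hopeless. The empirical-Bayes
remedy treats the per-feature variances \(s_g^2\) (pooled within-group,
\(d_g = n_1 + n_2 - 2\) df) as draws from a scaled inverse-chi-square prior
with parameters \(d_0\) (prior df) and \(s_0^2\) (prior variance), and
replaces each \(s_g^2\) with the posterior mean

\[
\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
t_g = \frac{\bar{y}_{g,T} - \bar{y}_{g,C}}{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}},
\]

with two-sided p-values on \(d_0 + d_g\) degrees of freedom. The prior is
fitted by the method of moments on log variances: under the model,
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\) has mean
\(\log s_0^2 + \log(d_0/2) - \psi(d_0/2)\) and variance
\(\psi'(d_g/2) + \psi'(d_0/2)\), so matching the sample mean and variance
of \(e_g\) gives \(d_0\) through the trigamma inverse (Newton iteration)
and then \(s_0^2\). When the observed spread of log variances does not
exceed the \(\psi'(d_g/2)\) floor, the variances carry no evidence of
heterogeneity and \(d_0 = \infty\) (complete shrinkage to \(s_0^2\), a
normal reference distribution) is returned. Exact maximum likelihood
buys little here and the moment fit is closed-form, transparent, and in
the test suite agrees with the `limma` reference implementation to
\(10^{-10}\) on shared data. Two limiting cases are tested exactly:
\(d_0 = 0\) reproduces the ordinary pooled t-test, \(d_0 = \infty\) the
common-variance z-like test.

The test operates on `log2(scaled count + 1)`. Counts are not
variance-stabilized beyond this; the moderation absorbs the residual
mean-variance trend well enough at this design size, and the choice keeps
the fold-change scale directly interpretable (the FC threshold is applied
on the linear scale).

## Thresholds

| parameter | default | meaning |
|---|---|---|
| `min_overlap` | 1 bp | replicate/feature overlap rule everywhere |
| `fc_cut` | 1.5 | linear fold-change threshold, symmetric |
| `fdr_cut` | 0.05 | BH q-value threshold |
| `quantile_cut` | 0.05 | nearest-rank low-signal filter |
| `pseudocount` | 1 | log2 offset |
| `genic_flank` | 1000 bp | gene body extension for genic/intergenic |
| `tss_window` | 1000 bp | half-width around the TSS |
| `at_min_len` | 8 bp | minimal AT-stretch run length |

The 1-bp overlap convention is the permissive default throughout; all
overlap-based counts shrink monotonically as `min_overlap` grows (tested).
Chromosome names are compared as exact strings — no `chr` prefix
normalization.

# Downstream analyses

**Annotation.** A called peak is *genic* iff it overlaps a gene body
extended by ±1 kb, else intergenic; the two counts always partition the
total. The TSS fraction uses windows `[tss − w, tss + w)`. ncRNA overlap
deliberately uses *no* flank, contrasting with the flanked genic rule, and
reports the nearest coding gene strictly left and right of the peak
midpoint (distance from midpoint to the gene's nearest boundary; a gene
spanning the midpoint is reported on both sides at distance 0). These
categories are non-exclusive counters — a peak may be both at a TSS and on
an ncRNA — because any precedence rule would be arbitrary. Per-chromosome
counts come with the Pearson correlation against chromosome length.

**DSB hotspots.** Hotspot maps are BED4 with a DMC1 SSDS tag count per
hotspot. Association is the 1-bp overlap rule. Intensities are compared as
natural-log tag counts (`log(#tags)`, per-hotspot totals rather than
per-bp densities); zero-tag hotspots cannot be logged and are excluded
from both groups with a message. Associated vs all hotspots are compared
by medians plus a Mann–Whitney rank-sum p (normal approximation,
midranks for ties) — rank-based, so invariant under monotone rescaling of
the tag counts, which is tested.

**Region signal.** For a configured region (a PAR-like region in the
motivating design — PAR coordinates are always config values, never
hard-coded), per-sample tag counts are scale-normalized, averaged within
condition, and reported as a treated/control ratio. A zero control mean
yields an explicit `undefined` flag rather than an infinite ratio.

**Sequence features.** AT content excludes ambiguous bases from the
denominator; AT stretches are maximal runs of A/T of length at least
`at_min_len`, broken by any other character; CpG counting is
orientation-aware (`CG`, not `GC`). There is no field-standard definition
of an "AT stretch" length threshold, so the threshold is a visible
parameter echoed in every output table rather than a hidden constant.
AT content and CpG count are reverse-complement invariant (A↔T, C↔G, and
CpG is its own reverse complement); both properties are tested on random
sequences.

**Expression and integration.** Array-style DE calling reuses the
moderated t-test on log2 intensities and thresholds *raw* p (< 0.05) plus
linear FC (> 1.5) — raw p rather than FDR deliberately, matching common
small-design microarray practice; q-values are still reported. A stricter
shortlist keeps |FC| ≥ 2 (inclusive boundary). Integration finds, for each
DE gene, the consensus peaks overlapping its ±1 kb TSS window and reports
the ratio of mean normalized treated to mean normalized control signal
averaged over those peaks (averaging, because a window may hold several
peaks and choosing one would be arbitrary); genes with no TSS peak are
reported with the literal `ND`. Every DE gene yields exactly one record.

# The synthetic-data generator

`simConfig()` defaults encode the study design the pipeline targets, and
they are the conditions under which the acceptance properties are stated:

* two conditions × two ChIP replicates with imbalanced library sizes
  (1.0, 1.2, 0.85, 1.1 × 10^6);
* ~2000 consensus peaks, 5% differential at linear FC 3 with a strongly
  asymmetric 97:3 up:down split;
* negative-binomial tag counts, dispersion 0.05, mean depth 50 per peak.
  Per-peak baselines sit exactly at the mean depth by default
  (`depth_sdlog = 0`), matching the stated conditions; a log-normal
  spread is available as an explicit option for robustness studies;
* replicate structure by independent 5% peak dropout and ±50 bp boundary
  jitter (jitter never inverts a peak);
* log-normal DMC1 hotspot intensities (meanlog log 100, sdlog 1 — a heavy
  tail, so "hottest hotspots" dominate), hotspot counts per chromosome
  proportional to length, and peak placement on hotspots weighted by
  intensity so marked hotspots skew hot;
* a PAR-like region at the end of the last chromosome losing half its
  signal in the treated condition (ratio 0.5 at control depth 200);
* a 6-chromosome, ~11 Mb genome with ~300 non-overlapping genes, 15%
  ncRNA, and 3 very large (≥ 0.5 Mb) genes whose sequence is AT-enriched
  (0.64 vs background 0.58, mouse-like);
* 3 vs 3 expression replicates, Gaussian log2 intensities (baseline
  N(8, 1), noise sd 0.25), 5% DE genes at FC 2, 80% of them linked to a
  same-sign differential TSS peak.

Every generator draws from a stream derived from the single mandatory
seed and restores the caller's RNG state, so a run is fully deterministic
and leaves no global side effects (tested by byte-identical reruns of the
whole pipeline).

What the generator does *not* emulate: read-level artefacts (mappability,
GC bias, duplicate reads), fragment-length effects, spatial
autocorrelation of background, copy-number variation, and the heavy
peak-width tails of real H3K4me3 domains. Tests passing on this generator
therefore validate the statistical and interval machinery, not robustness
to those real-data artefacts.

# Numerical and degenerate-input choices

* Coordinates are BED-style 0-based half-open on disk and 1-based closed
  `GRanges` in memory; the conversion at the I/O boundary preserves
  half-open semantics exactly (touching intervals never overlap), which
  is tested explicitly.
* `mergeIntervals()` merges only truly overlapping ranges; adjacent
  (touching) intervals are disjoint under half-open semantics and stay
  separate.
* Nearest-rank (type-1) quantile with strict ">" in the filter; ties at
  the threshold are dropped, and an all-tied input errors with advice.
* The trigamma inverse uses Newton iteration with asymptotic guards at
  both ends; the moderation fit falls back to d0 = ∞ when the log-variance
  spread is at or below its theoretical floor.
* Rank tests use midranks; chi-square uses no continuity correction; all
  p-values are two-sided.
* Division-by-zero cases (zero library, zero control signal, zero-tag
  hotspots, all-N sequences) error or flag explicitly — never silent
  `Inf`/`NaN`.

# Problem sizes in the test suite

The acceptance-level properties are computed at the scale the procedure
is specified for: interval-operation equivalence against brute-force
oracles on 120 random instances of up to 200 intervals; type-I control
over 200 null simulations of 2000 peaks; recovery over 50 paper-like
simulations of 2000 peaks; moderation recovery from 5000 simulated
variances; reverse-complement invariance over 1000 random sequences; and
byte-identical reruns of the full pipeline on a 3-chromosome genome.

# Known limitations

* Only two-condition designs; no covariates, batch terms or paired
  designs (the moderated test is a two-group contrast, not a general
  linear model).
* Reproducibility is overlap-based; it has one parameter but, unlike IDR,
  no calibrated error rate.
* The quantile filter interacts with BH: filtering is label-blind, but
  the FDR guarantee is conditional on the filtered set.
* Hypergeometric term enrichment assumes independent features; no
  kappa-style term clustering.
* Gene-level expression matrices are assumed; probe-to-gene mapping and
  array normalization are upstream concerns.
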