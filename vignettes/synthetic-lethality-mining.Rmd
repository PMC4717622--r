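---
title: "Mining mutually exclusive loss-of-function: models and design choices"
author: "synlethal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining mutually exclusive loss-of-function: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlethal)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Rationale

A synthetic lethal pair leaves a footprint in observational panels: the two
genes' loss-of-function events avoid each other, because doubly-lost cells
are not viable. Loss can be genetic (deleterious mutation, deletion) or
transcriptional (a gene silenced into a low expression mode). The package
therefore needs two ingredients: a way to call "low expression" that is
robust across homogeneous cell-line panels and heterogeneous tumours, and a
family of exclusivity tests over matched matrices.

## Calling bimodal expression

### The mixture index

For one gene's log2 profile across samples we fit a two-component Gaussian
mixture with a *shared* standard deviation by EM. The shared sigma is not a
simplification of convenience: the standardized separation `delta =
(mu_high - mu_low)/sigma` needs a single standardizer to be comparable
across genes, and the preset thresholds below assume that comparability. An
unequal-variance fit would need a pooling rule for sigma and would make
`delta` depend on it. The fit is summarized by the bimodality index
`BI = sqrt(pi(1-pi)) * delta`, which rewards separation and balance
jointly: a tiny low mode or a small separation both pull BI down.

Numerical choices:

* **Initialization.** EM is started deterministically from the hard split
  at the gap midpoint (below). This removes label-switching and restart
  variance; with a deterministic start, identical inputs give identical
  fits, which the workflow determinism guarantees rely on.
* **Termination.** At most 500 iterations, absolute log-likelihood
  tolerance 1e-6. A non-converged fit is flagged and reported with
  `BI = 0` so it can never pass a filter.
* **Degenerate inputs.** Fewer than 10 finite values is an error; an
  exactly constant vector returns `delta = 0, BI = 0` without running EM.
  Component weights and sigma are floored (1e-6 relative) so likelihood
  evaluations never collapse; the floors are scale-relative, keeping the
  fit invariant under affine transforms of the input — a property the test
  suite asserts directly.
* **Honesty about the unimodal limit.** The ML equal-variance mixture
  fitted to pure Gaussian noise does *not* report `delta = 0`; it reports a
  genuine split with `delta` around 2 and BI around 1 (the package's EM
  agrees with an independent mixture fitter to the fourth decimal here).
  Flat genes are rejected by the `delta` thresholds, not by BI alone, and
  unimodal genes leak past the `cell_line` preset at the percent level in
  small panels. This is exactly why the stricter `_low` presets exist and
  are the prescribed setting below ~200 samples.

### The gap midpoint

The mixture means are a poor midpoint estimate for diluted, non-normal
profiles (heterogeneous tumours, very small low modes). The midpoint is
therefore located non-parametrically: sort the values, compute every gap
between consecutive sorted values, and take the centre of the widest gap
whose lower flank lies inside the rank-quantile band
`[tail_exclusion, 1 - tail_exclusion]`. The band (default 0.10) exists
because a single outlier in either tail would otherwise own the widest gap.
Ties between equally wide gaps are broken toward the gap whose centre is
closest to the sample median, then toward the lower gap — a deterministic
rule chosen so that permutations of the input can never change the answer.
The tests hold this implementation against an exhaustive brute-force scan
on thousands of random vectors; agreement is exact.

### Presets and the unassigned window

Four presets trade stringency against expected mode dilution:
`cell_line` (BI ≥ 0.7, δ ≥ 2.5), `cell_line_low` (1.1, 3.5), `patient`
(0.5, 2.5), `patient_low` (0.9, 3.0); the `_low` variants are for panels
under ~200 samples, where delta estimates are noisier.

Around the midpoint, samples are labeled `low`/`high` except inside a
window whose width is

```
w = 0.05 * (1 - 2 * min(pi, 1 - pi)) * (midpoint - min(values))
```

i.e. up to 5 % of the distance from the midpoint to the distribution
floor. The interpolation in `pi` is one concrete realization of a
qualitative requirement — balanced, well-separated fits should get no
window; extreme minority modes, where overlap near the midpoint is likely,
should get the full 5 % — and it is deliberately exposed as a single small
function so the policy can be replaced. The window extends **below the
midpoint only**: the overlap that motivates it comes from a diluted low
mode smearing upward, and the distance that scales it is defined down to
the floor of the dynamic range. Samples inside the window are excluded
from both modes in every downstream denominator, in both `bigee` and
`beem`; counting them would dilute exclusivity evidence with samples whose
mode call is not trusted.

## The three exclusivity screens

**memu.** All pairs of genes with MUT rate ≥ 5 % (inclusive) are tested
two-tailed on the table `[both-MUT, a-only; b-only, both-WT]`. On this
orientation exclusivity *depresses* the both-MUT cell, so the odds-ratio
filter is `OR < 2.5`; the source material states the threshold with both
inequality directions in different places, and this package fixes the
orientation and documents it rather than guessing intent — the threshold
itself is configurable. Pairs with no exclusive calls at all (both
off-diagonals zero) are excluded before testing: no exclusivity signal is
possible and they would only dilute the FDR correction, which is
Benjamini–Hochberg over all tested pairs.

**bigee.** Admission is the exclusivity rule itself — fewer than 1 % of
the samples classifiable for *both* genes are low-low — and the S score
only ranks admitted pairs. S is the plain six-term sum of both genes' π,
BI and δ, with π taken as the minority-mode proportion (∈ (0, 0.5]) so
that better balance increases the score; the source equation's typography
is ambiguous, and the plain sum is the reading consistent with its gloss
(wider separation and evener balance score higher). No p-value is attached
to the 1 % rule: that is faithful to the method's design, where admission
is a threshold rule and confidence comes from downstream validation.

**beem.** Each (bimodal gene, mutation gene) pair is tested one-sided for
MUT enrichment in the high mode, because the stated hypothesis is
directional — mutation should be enriched in, or exclusive to, the high
expression mode. A `freq_mut_high > freq_mut_low` guard removes pairs that
reach small p through the wrong direction under two-sided use (the
sidedness is a flag). The liberal default `p < 0.25` maximizes inclusion
of pairs whose low mode is small and is deliberately not multiplicity
corrected; the screen is a recall-oriented filter, not an inference.

## Functional redundancy

The redundancy score is Wang's graph-based semantic similarity with
best-match-average combination, computed natively over a user-supplied OBO
file and annotation table (two-column TSV or GAF 2.x). Contribution
factors are 0.8 per `is_a` and 0.6 per `part_of` edge; each term's
ancestors receive the maximum over paths of the product of edge factors,
and two terms score the shared-ancestor weight mass over their total
weight mass. This measure was chosen because it needs only the ontology
graph itself — no information-content corpus — so the toolkit has no
runtime dependency on curated annotation services; the ontology arrives as
a file. Genes without usable annotation get `NA`, never 0: "unknown" and
"unrelated" are different statements. When the annotation carries aspects,
similarity is computed per aspect and averaged over aspects where both
genes are annotated.

## Validation statistics

Candidate lists are compared to a reference pair set by drawing the same
number of unordered pairs uniformly from a gene universe (default 10,000
draws) and counting overlap; the p-value uses the add-one rule
`(k + 1)/(N + 1)`, so the smallest attainable p is `1/(N + 1)` and p is
never zero. A `partial` mode counts candidates with at least one gene in
the reference set, for sparse references. Gene-set enrichment is a
two-tailed Fisher test over the universe. The dependency test splits a
knock-down screen's cell lines by loss of the partner gene and applies a
one-sided rank-sum test for lower phenotype scores (greater dependency)
under partner loss — one-sided because the hypothesis is directional,
with the sidedness again a flag; multiple knock-down solutions per gene
are tested separately, and empty groups are recorded as skipped with a
reason rather than silently dropped.

## The synthetic-data generator

`generate_sl_dataset()` emulates the study conditions end to end: 500
genes by 300 samples, 50 bimodal genes with `delta ~ U(4, 12)`,
`pi ~ U(0.2, 0.5)` and shared within-mode sigma 0.4 log2 units (a typical
within-mode spread for normalized array data), background mutation genes
with independent rates in `[0.02, 0.15]`, and five planted pairs per
mechanism: disjoint low modes, MUT confined to a partner's high mode (30 %
of that mode), and disjoint 20 % MUT sets. These sizes are also what the
acceptance checks run at. The generator draws from the same distributional
families the detection model assumes — by design, so that ground truth is
well defined — plus an optional heavy-tailed contamination fraction to
stress the midpoint's tail-exclusion band. It does **not** emulate probe
effects, count noise, batch structure, correlated expression programs, or
tumour purity gradients; passing tests therefore demonstrate correctness
of the algorithms under their own model, not robustness to everything real
data does. The exception is deliberate: the midpoint locator is exercised
under contamination and heavy tails, where its tail band matters.

## Problem sizes and tolerances in the checks

The automated checks use: 100 simulated bimodal genes at 200 samples for
mixture recovery (median |pi error| ≤ 0.05, median relative delta error
≤ 15 %); 1,000 random vectors for exact midpoint-oracle agreement; every
2×2 table with total ≤ 40 for Fisher enumeration agreement at 1e-12 and
all group sizes with combined n ≤ 12 for the rank-sum test; ten generator
seeds at the default conditions for ≥ 80 % planted-pair recovery with zero
exclusivity-rule violations; 200 repetitions for the null calibrations and
the permutation-uniformity check. These sizes were chosen so each property
is measured with comfortable Monte-Carlo margin while the whole suite
stays a desk-scale computation. One calibration subtlety: the one-sided
exact test is discrete, so its null pass rate at `p < 0.25` sits *below*
0.25 (observed around 0.19 at the simulated counts); the checks assert the
bound the threshold actually dictates rather than pretending continuity.

## Known limitations

* Strictly two modes: multi-modal profiles are folded into the best
  two-component description.
* Missing values are not supported; matrices must be complete, as they are
  after standard normalization pipelines.
* The 1–100 linear rescaling uses one global min/max. Per-gene scaling
  would destroy the cross-gene comparability the delta thresholds assume;
  the cost is sensitivity of the rescaled floor to a single extreme value,
  which the downstream midpoint search tolerates via its tail band.
* Pan-dataset analysis only: no per-tumour-type stratification, so
  relationships contradicted across types can surface as false positives.
* Exclusivity screens are correlational; the outputs are ranked
  hypotheses for loss-of-function screens, not validated interactions.
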