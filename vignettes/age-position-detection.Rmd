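---
title: "Detecting age-positions in cross-sectional expression trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-positions in cross-sectional expression trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agebend)
```

## The problem

Human tissues age on unknown schedules. Longitudinal sampling of the same
subjects is rarely feasible, so transcriptome-wide aging studies measure
each subject once and span a broad age range — a *cross-sectional* design.
The question agebend addresses is not merely *which* transcripts associate
with age, but *when* their expression trends change: the chronological age
at which the dominant trends bend, which we call an **age-position**.

The pipeline has five stages:

1. **Screening.** A dataset-level permutation test decides whether the
   genome-wide profile associates with age at all; per-probe analysis of a
   dataset that fails this screen mostly harvests false positives.
2. **Smoothing.** Each probe's expression is smoothed against age with a
   quadratic regression, the model class selected among five competitors
   by leave-one-out cross-validation (LOOCV).
3. **Filtering.** Probes are kept when the quadratic model beats the
   no-age-association null in an F test at unadjusted p < 0.05; dataset
   permutations quantify how many such probes a random ordering yields.
4. **Clustering.** The smoothed, per-probe mean-centered trends are
   clustered by k-means, either under Euclidean distance or under
   absolute-correlation distance `d(x, c) = 1 - |r(x, c)|`, which treats a
   trend and its mirror image as identical and therefore merges
   *reciprocal* (up/down) trend pairs into one cluster.
5. **Age-position estimation.** Within an absolute-correlation cluster
   the two reciprocal subgroups are separated by the sign of their
   correlation with the centroid; the age where the subgroup mean trends
   intersect — equivalently, where the 95th-percentile band closes in on
   the centroid — is the age-position. Its ± range comes from repeating
   the detection at k = 2, 3, 4 clusters.

Member genes of each age-position can then be tested for gene-set
over-representation (Fisher's exact test against a user-supplied GMT
collection, with ontology-based grouping of significant terms).

## Models and assumptions

**Global screen.** The statistic is a score-type quantity
$Q = \mathrm{mean}_i\,[(z_i \cdot a_c)^2]/(n-1)$, with $z_i$ the
standardized expression row of probe $i$ and $a_c$ the centered age
vector; large $Q$ means many probes co-vary with age. Its null
distribution is obtained by permuting the age labels, giving
$p = (1 + \#\{Q_{perm} \ge Q\})/(B+1)$ with $B$ = 999 by default. The
permutation form assumes exchangeability of samples under the null —
exactly the no-age-association hypothesis — and needs no distributional
assumptions on expression values. Sex is removed beforehand
(`correctSex()`) so a sex-age imbalance cannot masquerade as age signal.

**Per-probe model.** The working model is the quadratic
$y = \beta_0 + \beta_1 t + \beta_2 t^2 + \varepsilon$. Linear models
assume a constant rate of change over six decades, which is biologically
implausible; the quadratic is the smallest extension that can represent a
bend. Cubic polynomials, quadratic B-splines and LOESS are offered for
the model-selection step (`compareModels()`), which compares per-probe
LOOCV errors; in our synthetic experiments the quadratic roughly halves
the linear model's LOOCV error while the cubic's differs from the
quadratic's by only a few percent (the acceptance script reports both
ratios). The filter F statistic
$F = \frac{(SSE_0 - SSE_2)/2}{SSE_2/(n-3)}$ has an exact F(2, n-3) null
under Gaussian residuals; its level on simulated Gaussian noise is part
of the acceptance checks.

**Clustering.** Centering each smoothed trend to its grid average makes
clustering compare *shapes* (fold change, log2) rather than expression
levels. Under absolute correlation the centroid update sign-flips members
negatively correlated with the current centroid before averaging, so the
centroid represents the cluster's common orientation; the distance is
invariant to per-probe affine maps $x \mapsto ax+b$ ($a \neq 0$), which
is what makes reciprocal trends coincide.

**Age-position.** On exactly mirrored subgroups the intersection of the
subgroup means and the narrowest point of the 95th-percentile band
coincide (asserted within one grid step in the tests); on real data the
intersection is primary and the band minimum is the fallback when no
crossing exists, recorded in the `method` field.

## Tunable parameters

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| `alpha` (probe filter) | 0.05 | `filterProbes()` | unadjusted by design: the dataset passes two filters (global screen + permutation summary), and the permutation analysis estimates the false-positive load directly |
| `nPermutations` (screen) | 999 | `globalAgeTest()` | p-value resolution 1/1000; ≥ 99 enforced |
| `nPermutations` (summary) | 100 | `permutationSummary()` | enough to place the chronological count among permuted counts |
| `offset` (glog) | 1 | `normalizeGlog()` | shifted log2 of non-negative intensities; offset in raw-intensity units |
| `span` | 0.75 | loess option | the classical default; surfaced because it is the method's main tuning knob |
| qbspline knots | age terciles | `fitTrend()` | data-adaptive and deterministic; no control points to choose |
| `metric` | abscorrelation for positions | `kmeansTrends()` | merges reciprocal trends; euclidean for trend taxonomy |
| `restarts` | 25 | `kmeansTrends()` | best-of-restarts with k-means++ style seeding |
| `kValues` | 2, 3, 4 | `findAgePositions()` | the ± range is the half-spread of matched estimates across these k, rounded up to whole years |
| k scan | 24, 16, 12, 8, 6, 4 | `stabilityScan()` | decreasing re-clustering; recommended k = smallest with ≥ 50% of restarts converging to the best partition |
| grid step | 1 year | `ageGridFor()` | matches the 1-year resolution at which positions are reported |

## The synthetic-data generator

`simulateDataset()` emulates the structure of cross-sectional microarray
studies: 25–75 subjects aged roughly 25–95 with evenly populated decades
(equal counts per decade, remainder to the oldest decades — mirroring
typical inclusion criteria), thousands of probes of which a minority
carry reciprocal signal, plus an additive per-probe sex offset on a
subset of probes. A signal probe follows

$$y(t) = \mathrm{baseline} + \mathrm{slope}\,(t - t_{min}) \pm
  \Delta\, S\!\left(\frac{t - t_{bend}}{h}\right) + \varepsilon$$

with $S$ the logistic sigmoid: expression shifts smoothly by $\Delta$
log2 units around the bend, over a transition of half-width $h$ (default
3 years) — a smooth bend rather than a hard change-point, consistent
with how real expression trends look. Defaults: n = 60, ages 25–95,
2000 probes, bends at 45 and 75 years with 300 reciprocal probes each,
$\Delta = 1$, noise sd 0.5, sex offsets drawn with sd 0.5 on 30% of
probes. All randomness flows from one master seed (sub-seeds drawn once
via `sample.int`), so outputs are bit-reproducible.

What the generator does **not** emulate: probe-probe correlation (real
co-expression makes effective test counts smaller), array batch and
spatial artifacts, heavy-tailed residuals, and platform-specific
intensity distributions. Passing recovery tests on this generator
therefore demonstrates the pipeline's statistical logic, not robustness
to every failure mode of real arrays.

## Numerical choices

* Ages are centered and scaled inside polynomial fitting; coefficients
  are mapped back to the raw-age scale through an explicit basis-change
  matrix, so reported coefficients are in interpretable units.
* LOOCV for the linear-in-parameters models uses the exact leave-one-out
  identity (residual over one minus leverage); for the B-spline the basis
  (knots and boundary) is held fixed at the full-data design, so the
  identity is exact and held-out extremes are not extrapolations. LOESS
  is refit explicitly.
* An exactly quadratic probe has $SSE_2 = 0$; its p-value is reported as
  the smallest positive double rather than 0. A constant probe returns
  p = 1. Model-comparison differences at round-off level are treated as
  ties rather than ranked.
* Pearson correlation against a zero-variance trend is defined as 0
  (distance 1), keeping flat trends clusterable.
* Empty clusters during Lloyd iteration are re-seeded at the probe
  farthest from its current centroid; initialization is distance-weighted
  (k-means++ style), which on well-separated families makes most restarts
  converge to the same partition — the convergence-fraction diagnostic in
  `stabilityScan()` depends on this.
* Crossing ties (several equally narrow intersections) resolve to the
  earliest age; cross-k position matching is nearest-age to the k = 2
  reference, and each higher-k candidate is consumed at most once.
* `thinDataset()` keeps the first of each within-decade pair after a
  stable age sort — a deterministic realization of "every other sample,
  maintaining the distribution across decades".
* Redundant gene-set terms (identical member sets after background
  intersection) keep the lexicographically first id; ontology grouping
  connects two significant terms when they share a non-root common
  ancestor (terms themselves included), and groups are the connected
  components of that relation.

## Scale of the validation experiments

The test-suite and acceptance-script experiments run at desk scale,
chosen once as representative: bend recovery on the generator defaults
(2000 probes × 60 samples, 20 seeded runs); filter type-I on 2000
pure-noise probes × 30 samples (20 runs); global-test uniformity on 300
probes × 30 samples over 200 runs with B = 199; model comparison on 60
quadratic-signal probes × 40 samples; permutation summaries with 100
permutations. These sizes give the binomial and rank tests involved
enough resolution without turning a validation run into a compute job.

## Known limitations

* **Center-ward bias of the bend estimate.** A single global parabola
  cannot represent a flat-then-shift trend; its least-squares fit smears
  the transition across the whole age range, and the intersection of
  mirrored fitted trends (the age where the centered parabola crosses
  zero) lands systematically toward the middle of the observed age span.
  On the generator defaults (bends at 45 and 75 inside 25–95) the
  detected positions concentrate near 51 and 69 — about 6 years inward —
  and the acceptance script reports these errors. The bias shrinks when
  the bend sits nearer the center of the sampled range, and the ± range
  across k does not capture it because all k share the same smoother.
  Sharper localization would need a piecewise or change-point smoother,
  which trades away the low-variance global fit this method is built on.
* **Paired model comparison resolves tiny real differences.** The cubic's
  extra parameter inflates its per-probe LOOCV error by a small margin
  with a consistent sign, so the signed-rank comparison flags
  quadratic-vs-cubic as significant at any informative probe count even
  though the mean errors differ by only a few percent. "Similar fit"
  between quadratic and cubic is a statement about magnitudes (see the
  reported error ratios), not about paired non-significance.
* Late age-positions in cross-sectional data may reflect survivor
  enrichment rather than within-individual change; only longitudinal
  designs can separate the two.
* The per-probe sex correction removes additive sex effects only; sex-age
  interactions pass through untouched.
* The permutation global test reports p no smaller than 1/(B+1); datasets
  screened at that floor are simply "significant at the resolution run".
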