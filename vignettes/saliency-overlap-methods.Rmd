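---
title: "Evaluating lesion localization of AI saliency maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating lesion localization of AI saliency maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

When a deep-learning system scores screening mammograms for cancer, does
its attention — as rendered by a saliency map — actually concentrate on
the breast lesion a radiologist would point to? `salovlap` quantifies
this on a matched case–control cohort with two coupled analyses:

1. **Detection**: how well do the per-image prediction scores separate
   cancer cases from healthy controls (ROC AUC with a bootstrap CI)?
2. **Localization**: at its most favorable threshold, how much can the
   saliency map's area of interest overlap the segmented lesion (optimal
   Dice similarity coefficient, summarized as median and IQR)?

Reporting both side by side makes visible the decoupling that motivates
the analysis: a system can detect well while attending to large,
non-lesion image regions.

## The overlap model

Each saliency map is min–max normalized per image,
$v' = (v - \min v)/(\max v - \min v)$, so 1 marks the most salient pixel
of that image. A constant map carries no ordering information; it is
returned as all zeros with a degeneracy flag rather than an arbitrary
rescaling.

For a normalized map $s$ and threshold $\tau$, the **area of interest**
is $A(\tau) = \{p : s(p) \ge \tau\}$. Overlap with the lesion mask $B$
is Dice's similarity coefficient

$$\mathrm{DSC}(A, B) = \frac{2\,|A \cap B|}{|A| + |B|},$$

which is 1 for identical nonempty sets and 0 for disjoint ones. The case
$|A| = |B| = 0$ is mathematically undefined and raises an error instead
of returning a number.

The per-image **optimal threshold** $\tau^*$ maximizes
$\mathrm{DSC}(A(\tau), B)$. Because the area of interest changes only at
distinct saliency values, the exact maximizer can be found by sorting
pixels by descending saliency and evaluating the prefix Dice
$2\,TP(k)/(k + |B|)$ at every boundary between distinct values — an
$O(P \log P)$ sweep whose result provably equals exhaustive search over
all distinct values (the test suite asserts exact agreement against a
brute-force enumerator). The reported optimal DSC is therefore an *upper
bound* on how lesion-localized the map can appear at any threshold,
which makes a low value a strong statement.

Numerical choices, stated for reproducibility:

* Threshold comparison is `>=`, so the maximum-saliency pixel is always
  selectable and the candidate thresholds are exactly the distinct
  values. Pixels with equal saliency enter or leave the area of interest
  together.
* Among DSC-maximizing thresholds the largest is returned — the
  smallest, most specific area of interest — making ties deterministic.
* The search is exact over all distinct values rather than over a fixed
  grid; no step size needs to be chosen and the exact search dominates
  any grid.
* Median and IQR of per-image DSC use linear interpolation between order
  statistics (`stats::quantile` type 7).
* Images without a usable lesion mask (no segmentation, or an empty
  one — e.g. a lesion conspicuous in only one view) are excluded from
  the overlap analysis but retained for detection; exclusions are
  counted and logged, never silently dropped.

## The detection model

The AUC is computed as the Mann–Whitney rank statistic: over all
case–control pairs, the fraction in which the case scores higher,
counting ties as 1/2. Mid-ranks make this identical to trapezoidal
integration of the empirical ROC curve (asserted to `1e-12` in tests),
and invariant under any strictly increasing transform of the scores.

Uncertainty comes from a **stratified percentile bootstrap**: cases and
controls are resampled separately with replacement (the case–control
design fixes the class sizes, and no replicate can lose a class), the
AUC is recomputed per replicate, and the CI is the percentile interval
of the replicate distribution. Percentile rather than BCa is the
simplest defensible interval when only "bootstrapping" is specified, and
it is recorded in the run metadata. Default `n_boot = 2000`; a seed is
mandatory — there is no silent nondeterminism anywhere in the package.

**Significance versus chance** is operationalized as the 95% CI strictly
excluding 0.5 (two-sided at $\alpha = 0.05$). A CI touching 0.5 is not
significant. The test suite checks that this rule reproduces the
published significance calls of four well-known mammography AI systems
from their printed confidence intervals.

The analysis unit is the image. Four images per woman are correlated;
the default bootstrap resamples images independently, and a cluster
bootstrap by woman (`cluster_boot = TRUE`) is available for sensitivity
analysis without any claim that it mirrors the original analysis. A
per-woman aggregation (max score over a woman's images) is likewise
provided but off by default.

## Matching

Controls are matched 1:1 to cases on the exact triple (birth year,
screening year, mammographic system) — years, not age bands, since only
years are available in the cohort tables. When several candidates share
a key, selection follows a seeded random permutation: the data give no
selection rule, and a deterministic, order-invariant choice is required
for reproducibility (records are sorted by `woman_id` before the
permutation is applied, so input row order is irrelevant). Unmatched
cases are reported. Age for summary tables is screening year minus birth
year, banded as `<55`, `55–59`, `60–64`, `>64`.

## What the synthetic data emulate — and what they do not

The generators provide known-truth inputs with the statistical structure
the analysis assumes:

* **Phantoms** (`make_phantom`): a half-ellipse breast region on a dark
  background, textured with Gaussian-smoothed seeded noise, plus an
  additive bright elliptical lesion. The mask marks exactly the discrete
  lesion ellipse, independent of contrast — ground truth does not depend
  on conspicuity. Default size 128×128 pixels, chosen so brute-force
  oracles remain feasible in tests.
* **Saliency fields** (`make_saliency`): a convex mix
  $\lambda K_{\text{lesion}} + (1-\lambda) K_{\text{diffuse}}$ plus
  noise, normalized per image. $K_{\text{lesion}}$ is a Gaussian bump
  (width 8 px) at the lesion centroid; $K_{\text{diffuse}}$ is a broad
  bump (width 32 px) placed uniformly at random, *independently* of the
  lesion — modelling attention to large image regions without building
  in an artificial negative association. $\lambda = 1$ is fully
  lesion-focused, $\lambda = 0$ diffuse and lesion-independent; median
  optimal DSC is monotone in $\lambda$ (property-tested).
* **Detection scores** (`make_scores`): binormal — controls
  $\mathcal N(0,1)$, cases $\mathcal N(\mu,1)$ — giving the closed-form
  true AUC $\Phi(\mu/\sqrt 2)$ used for recovery and bootstrap-coverage
  checks.
* **Cohorts** (`make_cohort`): screening years 2015–2017, ages
  constrained to 50–69 (the biennial invitation band), two mammographic
  systems with a 78/22 mix, cancer types at typical screening-detection
  proportions (DCIS 17%, ductal 64%, lobular 13%, other 6%), and one
  guaranteed key-sharing candidate per case so a full matching always
  exists by construction.
* **Datasets** (`make_dataset`): 191 cases and 191 controls by default,
  four scored images per woman and two lesion images per case (both
  views of the affected breast); only case-side lesion images enter the
  overlap analysis, controls contribute to detection only.

These phantoms are deliberately simplistic. They contain no
mammographic texture, no lesion morphology (spiculation, calcification
clusters), no view geometry, and the scores carry no within-woman
correlation. Passing tests therefore demonstrate the *correctness of
the measurement machinery* — thresholding, Dice, AUC, bootstrap,
matching, accounting — not that any conclusion about real mammograms
would transfer. Saliency maps written through 8-bit PNG are quantized
to 256 levels; the threshold search is exact over whatever distinct
values survive the encoding.

## Problem sizes and runtime choices

The test suite exercises: 200 random 16×16 instances for sweep/oracle
equivalence; 100 random instances for the AUC identities; 2000+2000
scores for binormal recovery; 200 simulated datasets of 100+100 with
1000 bootstrap replicates for CI coverage; 50 phantoms per localization
level for the monotonicity check; and a full 191+191-women dataset (1528
scored images, 382 lesion images) for the decoupling demonstration.
These sizes keep every Monte-Carlo check comfortably stable while the
whole suite runs in about a minute on one CPU.

## Known limitations

* Percentile bootstrap intervals can be narrow at extreme AUCs
  (degenerate at AUC = 1); the CI-excludes-0.5 rule is a decision rule,
  not a p-value.
* Exact-key matching has no caliper; a case with a rare key simply goes
  unmatched (and is reported).
* Normalization is over the full image; if saliency were meaningful
  only within the breast region, cropping before normalization would
  change thresholds. The package normalizes the full matrix.
* The optimal-threshold DSC is intentionally optimistic; comparing
  systems at a common fixed threshold is a different question and out
  of scope.
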