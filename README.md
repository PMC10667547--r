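# salovlap

Does a mammography AI system's attention actually rest on the breast
lesion? `salovlap` answers this for any system that emits per-image
saliency maps and detection scores, by combining two analyses on a
matched case–control screening cohort:

* **Detection performance** — the ROC AUC of the per-image scores,
  computed as the Mann–Whitney rank statistic
  (ties counted 1/2; identical to trapezoidal ROC integration), with a
  stratified percentile-bootstrap 95% CI and significance declared when
  the CI strictly excludes 0.5.
* **Lesion localization** — for each lesion image, the saliency map is
  normalized to [0, 1] and thresholded at the value τ\* that maximizes
  Dice overlap with the radiologist's lesion mask,

  DSC(A, B) = 2 |A ∩ B| / (|A| + |B|),

  where A = {p : s(p) ≥ τ} is the area of interest and B the lesion.
  τ\* is found by an exact sweep over all distinct saliency values, so
  the reported DSC is the *best achievable* overlap at any threshold.
  Per-system results are summarized as median DSC with IQR.

The package also assembles the cohort (exact 1:1 matching on birth
year, screening year and mammographic system, with seeded tie-breaking
and explicit reporting of unmatched cases) and ships a synthetic
phantom generator — elliptical lesions on half-ellipse breast phantoms,
saliency fields with a tunable localization parameter λ, and binormal
detection scores with closed-form true AUC Φ(μ/√2) — so every stage is
testable without any clinical data.

It is aimed at researchers evaluating explainable-AI heatmaps against
ground-truth segmentations, in mammography or any setting where "does
the model look at the finding?" is the question.

## Worked example

Generate a synthetic dataset with two hypothetical systems — one
lesion-focused and strongly detecting (λ = 1, μ = 3), one diffuse and
uninformative (λ = 0, μ = 0), with 10% of lesion images left
unsegmented — then run the full experiment:

```r
library(salovlap)
d <- file.path(tempdir(), "demo")
make_dataset(d, n_cases = 20, n_controls = 20,
             systems = list(good    = list(lambda = 1, mu = 3),
                            diffuse = list(lambda = 0, mu = 0)),
             p_unsegmented = 0.1, seed = 11)

rep <- run_experiment(list(
  manifest = file.path(d, "manifest.csv"),
  systems = c("good", "diffuse"),
  saliency_dir = file.path(d, "saliency"),
  scores_dir = file.path(d, "scores"),
  out_dir = file.path(d, "out"),
  seed = 42, n_boot = 500
))
print(rep)
```

```
Detection performance and saliency-lesion overlap
  System   AUC      95% CI Significant     DSC (IQR)        DSC %   n
    good 0.988 0.973–0.997         yes 0.783 (0.058) 78.3% (5.8%) 160
 diffuse 0.549 0.457–0.639          no 0.007 (0.011)  0.7% (1.1%) 160
(12 lesion image(s) excluded from overlap: no usable mask)
```

Reading the rows: `good` detects nearly perfectly (AUC 0.988 over 160
images, CI excluding 0.5) *and* its best-threshold areas of interest
cover the lesions well (median DSC 0.783). `diffuse` neither detects
(CI straddles 0.5) nor localizes (median DSC 0.007 — even at its most
favorable threshold its attention barely touches the lesion). The 12
excluded images are lesion images without a usable mask; they stay in
the detection analysis and are counted, not dropped. `out/` now holds
`report.csv`, `report.json`, one per-image overlap CSV per system, and
`run_metadata.json` recording the seed, sub-seeds and every analysis
rule used.

A command-line interface with the same stages as subcommands
(`run`, `synth`, `match`, `score-eval`, `overlap`, `report`) is
installed at `system.file("cli", "salovlap.R", package = "salovlap")`.

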