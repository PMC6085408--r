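# bingeLFP

Resting ventral-striatal local field potentials (LFPs) and deep brain
stimulation (DBS) outcomes in a rodent binge-eating model: a tested,
reusable R implementation of the full analysis chain, driven by a
synthetic-data generator so every step runs — and is calibrated — without
any animal data.

The scientific question: DBS of the nucleus accumbens (NAc) core or shell
suppresses binge-like feeding only in subsets of animals, and often in
only one of the two targets. Can features of *resting* LFP activity
recorded at the stimulation sites classify which animals respond, and
which target is the better choice for an individual?

The package is aimed at electrophysiologists and computational
neuroscientists who want the analysis as auditable code: the responder
rule, the spectral features, the penalized classifier with its permutation
null, and a generator with analytically known ground truth for testing.

## The analysis in brief

* **Responder rule.** Session intake is normalized as percent change from
  the animal's average baseline binge size. Pooled baseline variation is
  ≈ normal with SD ≈ 13%, so a *meaningful* change is > 2 SD (26%); an
  animal is a responder at a target iff all three stimulation sessions
  show a reduction beyond the threshold. The optimal target is the
  responder target with the larger mean reduction.
* **Features.** From rest intervals only: Welch power spectral densities
  per channel and magnitude-squared coherence per channel pair (2 s
  Hamming windows, 50% overlap), averaged over six rodent bands
  (Δ 1–4, θ 5–10, α 11–14, β 15–30, lγ 45–65, hγ 70–90 Hz). Four channels
  (`cl`, `cr`, `sl`, `sr`) × 6 bands ⇒ 60 features per session:
  24 power (`Pcr Δ`, …, log10 scale) and 36 coherence (`Cclcr hγ`, …).
* **Classifier.** L1-penalized (lasso) logistic regression under 4-fold
  cross-validation repeated 100 times, with animal-level (group-aware,
  class-paired) folds, training-only standardization and nested penalty
  selection. Chance is established by re-running everything on
  animal-level label permutations; observed vs permuted accuracy
  distributions are compared by Mann–Whitney U, converted to Cohen's d
  via `z = (U − n₁n₂/2)/σ_U`, `r = z/√N`, `d = 2r/√(1−r²)`. Per-feature
  information is measured by univariate logistic models under exhaustive
  leave-one-animal-out CV, and feature tables rank the top 5 by
  univariate % accuracy and by lasso % survival (share of fold-models
  with a nonzero coefficient).
* **Generator.** Channels are linear mixtures of band-limited shared
  sources plus independent noise, so band coherence has a closed form
  `((a_c a_d σ_s²)²) / ((a_c²σ_s² + n_c)(a_d²σ_s² + n_d))` that serves as
  an oracle for the estimators; group effects are planted as
  power-neutral coherence shifts (or coherence-neutral power shifts).

## Worked example

```r
library(bingeLFP)
run_pipeline(demo_config(seed = 7), "run1")
cat(readLines("run1/report.txt"), sep = "\n")
```

prints (exact numbers from this configuration and seed):

```
Resting-LFP / DBS outcome pipeline summary
==========================================
Responder threshold: 22.0% (2 x fitted baseline SD)
Response profile (n = 12): single-target 6, both 0, neither 6

Model core: mean accuracy 100% (SD ± 0%) vs permuted 49% (SD ± 6%), Cohen's d = 2.41
  top features (logistic accuracy | lasso survival):
  ↑ Cclcr hγ 100% | ↑ Cclcr hγ 100%
  ...
Stable discriminative features (within/between ratio < 1): 5
  Cclcr hγ (ratio 0.12)
  ...
```

Reading it: the demo cohort plants a +0.3 coherence shift on the
left-core/right-core high-gamma pair (`Cclcr hγ`) in the responder group
and a strong core stimulation effect in the intake simulator. The
pipeline refits the responder threshold from the table's own baselines
(22% here — with only three baseline sessions per animal the fitted SD
sits slightly below the generative 13%; see the vignette), labels six
core responders, classifies responder status from the LFP features with
100% cross-validated accuracy against a 49% permutation null, and flags
the planted feature as the top-ranked, temporally stable discriminator.

Lower-level functions (`simulate_cohort()`, `extract_feature_vector()`,
`label_outcomes()`, `classify_outcomes()`, `compare_distributions()`, …)
expose each stage separately; `vignettes/` documents the model,
parameters and design choices. A thin CLI wrapper lives at
`inst/scripts/binge-lfp.R`.

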