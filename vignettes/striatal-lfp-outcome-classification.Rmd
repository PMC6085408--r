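---
title: "Classifying DBS outcomes from resting ventral-striatal LFP features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DBS outcomes from resting ventral-striatal LFP features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bingeLFP)
```

## The problem

Deep brain stimulation (DBS) of the nucleus accumbens (NAc) can suppress
binge-like feeding in rodents, but outcomes vary strongly across
individuals and across the two NAc sub-regions (core and shell). The
question this package operationalizes is whether *resting* local field
potential (LFP) activity recorded at the stimulation sites — before any
stimulation is delivered in a session — carries enough information to
classify which animals will respond to stimulation at a given target, and
which of the two targets is the better choice for each animal.

The package implements the full analysis chain as reusable, tested code,
and pairs it with a synthetic-data generator so that the entire chain can
be exercised, calibrated and stress-tested without any animal data.

## The analysis chain

### 1. Binge-size normalization and the responder rule

Each animal's session intake is expressed as percent change from its own
average baseline intake, removing between-animal differences in absolute
binge size. Pooled across animals, session-to-session baseline variation
is approximately normal; its fitted standard deviation (SD, around 13%)
defines a *meaningful change*: a per-session change beyond 2 SD (26%).
An animal is a **responder** at a target only when every one of its three
stimulation sessions shows a *reduction* of strictly more than the
threshold. Sessions that *increase* beyond the threshold are flagged as
paradoxical but never make a responder — the rule is about therapeutic
suppression of feeding. The **optimal target** of an animal is the
responder target with the larger mean reduction; animals with no responder
target are excluded from target-choice modelling.

Two numerical details are deliberately pinned down because the verbal rule
leaves them open: the threshold comparison is strict (`>`), and an exact
tie between targets (impossible in continuous data) is broken toward core,
with a warning. When intake tables are supplied, the threshold is refit as
twice the SD of that table's pooled baseline percent changes; the literal
26% constant is the documented fallback. Note a finite-baseline subtlety:
with only three baseline sessions per animal, deviations from the *sample*
baseline mean have SD about `sqrt(2/3)` times the underlying
session-to-session SD, so a threshold refit from a small table is
systematically a little tighter than 2 of the generative SDs. The
package treats the fitted value as the operational truth, exactly as an
empirical rule derived from pooled real data would be.

### 2. Spectral features

From each resting recording, only manually-annotated rest intervals are
used (merged, clipped, and dropped when shorter than 4 s). Welch
estimation uses 2 s Hamming windows with 50% overlap and per-window linear
detrending: 0.5 Hz resolution — enough to resolve the 1–4 Hz delta band —
with many averaged windows per minute of rest. Power spectral densities
are computed per channel and magnitude-squared coherence per channel pair,
averaging periodograms across windows of all rest segments (segments are
never stitched sample-wise, which would create boundary artifacts).

Band summaries use conventional rodent bands — Δ 1–4, θ 5–10, α 11–14,
β 15–30, lγ 45–65, hγ 70–90 Hz (fully configurable, and recorded in every
output's metadata). Band power is the mean in-band density, log10
transformed for variance stabilization; band coherence is the mean in-band
coherence on its natural 0–1 scale. With 4 channels (`cl`, `cr`, `sl`,
`sr` — left/right core and shell) and 6 bands, each session yields 60
features: 24 power (`"Pcr Δ"`, ...) and 36 coherence (`"Cclcr hγ"`, ...),
with pair labels always written in channel-scheme order.

The coherence estimator applies the standard small-sample bias correction
for averaged magnitude-squared coherence, `C - (1 - C)^2 / n_windows`,
without which band coherence carries a uniform upward offset of roughly
`1/n_windows` that is material at desk-scale recording lengths.

A mains notch is off by default (synthetic data has no mains); real
recordings can exclude the mains frequency by band configuration.

### 3. Outcome classification

Because features (60) far outnumber animals, classification uses the
lasso: L1-penalized logistic regression that drops uninformative or
redundant features. The protocol is 4-fold cross-validation repeated 100
times. Three design decisions deserve emphasis:

* **Group-aware, class-paired folds.** Every animal contributes two
  recording sessions as separate rows, and both rows share the animal's
  label. All sessions of an animal are assigned to the same fold, so no
  animal can appear on both sides of a split — the repeated-measures
  leakage that session-level folding would invite. Animals of the two
  classes are additionally dealt to folds in pairs, so with balanced
  classes every training complement is exactly class-balanced. This
  matters for calibration: with an odd class imbalance in the training
  fold, an uninformative model predicts the training majority while the
  held-out fold is tilted the other way, dragging null-data accuracy well
  below chance — a known artifact of cross-validation on balanced
  designs.
* **No leakage through preprocessing.** Feature standardization uses
  training-fold means and SDs only, and the penalty is chosen by an inner
  group-aware cross-validation on the training fold (minimum held-out
  deviance). Constant features are excluded from selection.
* **Accuracy bookkeeping.** Held-out rows are classified at a probability
  cutoff of 0.5 and pooled over the 4 folds into one accuracy per
  repetition. A predicted probability of exactly 0.5 (an intercept-only
  fit on balanced training data) is undecided and scores half credit —
  the expectation of a random tie-break, kept deterministic. A feature
  *survives* a fold-model when its coefficient is nonzero; % survival
  divides by all `reps × k` fold-models.

Significance is assessed against an empirical null: labels are permuted
at the animal level (sessions move together, marginals preserved) and the
whole repeated-CV procedure is rerun per permutation — 10 permutations by
default, configurable; more are recommended when runtime allows since 10
give a coarse null. Observed and null accuracy distributions are compared
with the Mann–Whitney U test (midrank ties, tie-corrected normal
approximation), and the statistic is converted to a Cohen's d through
`z = (U − n1·n2/2)/σ_U`, `r = z/√N`, `d = 2r/√(1 − r²)`, positive when
observed accuracies dominate the null. The conversion choice is recorded
in every report; the U computation is cross-checked in the test suite
against brute-force pairwise counting and `wilcox.test`.

Per-feature information content is quantified by single-feature logistic
regressions under exhaustive leave-one-animal-out cross-validation (the
mean of the per-split accuracies is reported); training splits with
perfect separation fall back to a lightly ridge-penalized fit. Feature
tables rank the top 5 by univariate % accuracy and by lasso % survival,
with direction arrows (↑ when the class-1 group mean exceeds the class-0
mean); ties break by the other column, then name, so tables are
deterministic.

### 4. Feature stability

Since both recording days of an animal enter the model with the same
label, only features whose group difference is stable across days can
survive. `feature_stability()` reports, per feature, the mean
within-animal |T1 − T2| change, the absolute between-group difference of
animal means, and their ratio — a ratio below 1 marks a stable
discriminative feature.

## The synthetic-data generator

### LFP cohorts

Each channel is a linear mixture of band-limited shared sources plus
independent noise:

\[ x_c(t) = \sum_b a_{cb}\, s_b(t) + e_c(t) \]

Band-limited components are white Gaussian noise passed through a
zero-phase FFT brick-wall band-pass, so the in-band density of a component
with input SD \(s\) is exactly flat at \(s^2/(f_s/2)\) and the expected
band coherence of a pair has the closed form

\[ C_{cd}(b) = \frac{(a_{cb} a_{db} \sigma_s^2)^2}
   {(a_{cb}^2\sigma_s^2 + n_{cb})(a_{db}^2\sigma_s^2 + n_{db})} \]

with \(n_{cb}\) the in-band noise power. The brick-wall choice (rather
than a finite-order filter) is what keeps this formula *exact*: with
Butterworth roll-off, band-averaged coherence would be biased at band
edges by more than the 0.05 oracle tolerance the estimator is tested
against. The analytic table is attached to every simulated recording, so
the Welch estimator can always be checked against its generating truth.
A single band-averaged coherence estimate from 60 s of data has a sampling
SD of up to ~0.035 in the 3 Hz-wide delta band (a time-bandwidth limit,
not an estimator defect), so oracle checks average estimates over
replicate recordings.

Group differences are *planted* as controlled feature shifts. Coherence
shifts are planted power-neutrally: the shared-source gain and in-band
noise of the two channels are re-solved so the pair's coherence moves by
the requested delta while each channel's total in-band power is unchanged
— otherwise a planted coherence effect would leak into power features and
"the planted feature ranks first" would be ill-posed. Power shifts scale
gain and noise together, leaving all coherences fixed. Between-animal
variation and session-to-session drift are multiplicative gain jitters
(both 5% SD by default — small relative to planted effects, so planted
differences are stable across days, emulating the stability property
above). Every recording's seed derives deterministically from the master
seed and animal/session indices: identical specs reproduce identical
cohorts byte for byte.

What the generator does *not* emulate: 1/f background shape, mains
contamination, stimulation artifacts, non-stationarity within a session,
and any biophysics of fields or spikes. Passing tests therefore show that
the *analysis chain* behaves as designed (no leakage, correct calibration,
recovery of planted structure); they do not validate the biological claim
on real recordings.

### Binge cohorts

Baseline intakes are i.i.d. normal around a per-animal mean (20 kcal by
default, a realistic 2 h sweet-fat intake for an adult rat) with a 13%
session-to-session coefficient of variation — the population figure that
defines the 26% rule. Stimulation sessions shift the mean by a per-animal,
per-target percentage; post-stimulation sessions return to baseline
(washout). Negative draws are clipped at zero with a logged count. Under a
null effect, the probability that an animal passes the all-three-sessions
responder rule by chance is \((1-\Phi(2))^3 \approx 1.2\times10^{-5}\),
which the test suite verifies by Monte-Carlo.

## Calibration properties the tests enforce

* **Null calibration.** On a no-effect cohort (12 animals × 2 sessions,
  balanced), repeated-CV mean accuracy lies in [0.45, 0.55] and the effect
  size against its own permutation null is below 0.5 — the analogue of a
  permuted-data accuracy near 49%.
* **Planted-effect recovery.** With one coherence feature shifted by +0.3
  (many within-group SDs) between 12-vs-12 groups, observed-vs-null
  Cohen's d exceeds 0.8 and the planted feature ranks in the top 3 by
  survival, in at least 9 of 10 seeded replicates.
* **Stability.** The planted feature's within-animal day-to-day drift is
  smaller than its between-group separation.

## Problem sizes and runtime choices

Defaults follow the experimental protocol (120 s recordings at 1000 Hz,
100 CV repetitions, 10 permutations). The test and acceptance runs use
deliberately smaller instances chosen for a single-CPU desk run and
documented here as the package's own choices: cohort recordings of 30–60 s
(at 500 Hz for cohorts, 1000 Hz wherever the coherence oracle is checked),
30 CV repetitions inside the 10-replicate recovery study, and 16 replicate
recordings averaged in the coherence-oracle comparison. None of these
sizes change any default.

## Known limitations

* Real preprocessing details of chronic recordings (referencing, artifact
  rejection beyond rest-interval gating, exact band edges) are deployment
  choices; the defaults here are declared, not inferred from any specific
  rig.
* Ten permutations give a coarse null; effect sizes are more trustworthy
  than p-value-like statements at that setting.
* The responder rule is direction-asymmetric by design; cohorts in which
  stimulation *increases* intake are summarized only through the
  paradoxical-increase flags.
* With two sessions per animal and small cohorts, CV accuracy
  distributions are discrete; Mann–Whitney handles the heavy ties, but
  single-repetition accuracies should not be over-interpreted.

## A worked example

```{r example, eval = FALSE}
cfg <- demo_config(seed = 7)
run_pipeline(cfg, "run1")
cat(readLines(file.path("run1", "report.txt")), sep = "\n")
```

The run directory contains the intake table, the 60-column feature table,
outcome labels with the refit threshold, per-model accuracy reports with
permutation nulls and effect sizes, top-5 feature tables with direction
arrows, and the stability table, together with a resolved-config copy and
a structured log for provenance.
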