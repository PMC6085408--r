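Package: bingeLFP
Title: Ventral Striatal LFP Features and Deep Brain Stimulation Outcome
    Classification in a Binge-Eating Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking resting ventral-striatal local field
    potential (LFP) activity to deep brain stimulation (DBS) outcomes in a
    rodent binge-eating paradigm. Provides a synthetic-data generator with
    analytically controlled band power and pairwise coherence, Welch
    spectral feature extraction (band power and magnitude-squared coherence
    for bilateral nucleus accumbens core and shell), responder and
    optimal-target classification from binge-intake tables, penalized
    (lasso) logistic outcome classification with repeated group-aware
    cross-validation, permutation-null effect sizes (Mann-Whitney U
    converted to Cohen's d), per-feature leave-one-animal-out logistic
    accuracies, feature-survival ranking, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
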