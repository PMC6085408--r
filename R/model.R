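#' Classify stimulation outcomes from resting LFP features
#'
#' The package's main fitting function. Builds the design matrix for the
#' requested model (core responder vs non-responder, shell responder vs
#' non-responder, or optimal target core vs shell), runs the repeated
#' group-aware cross-validated lasso, the animal-level permutation null,
#' the Mann-Whitney/Cohen's d comparison of the two accuracy distributions,
#' the per-feature univariate leave-one-animal-out logistic accuracies, and
#' the top-k feature ranking.
#'
#' @param features Feature table (see [build_design_matrix()]).
#' @param labels Outcome labels (see [build_design_matrix()]).
#' @param model `"core"`, `"shell"` or `"core_vs_shell"`.
#' @param k Outer CV folds (default 4).
#' @param reps CV repetitions (default 100).
#' @param n_perms Label permutations for the null (default 10; 0 skips the
#'   null and the effect size).
#' @param seed Integer seed driving all randomness.
#' @param top_k Rows in the feature-ranking tables (default 5).
#' @param univariate Compute per-feature logistic accuracies (default TRUE;
#'   skipping them also skips the feature report).
#' @param ... Passed on to [fit_lasso_repeated_cv()].
#' @return An object of class `dbs_outcome_model` with components
#'   `cv` (`lfp_cv`), `null` (`lfp_permnull` or `NULL`), `effect`
#'   (`effect_size_report` or `NULL`), `features` (`feature_report` or
#'   `NULL`), `univariate`, and the design matrix summary.
#' @seealso [fit_lasso_repeated_cv()], [permutation_null()],
#'   [compare_distributions()], [build_feature_report()]
#' @export
classify_outcomes <- function(features, labels,
                              model = c("core", "shell", "core_vs_shell"),
                              k = 4, reps = 100, n_perms = 10, seed = 1L,
                              top_k = 5, univariate = TRUE, ...) {
  model <- match.arg(model)
  dm <- build_design_matrix(features, labels, model)
  cv <- fit_lasso_repeated_cv(dm, k = k, reps = reps, seed = seed, ...)
  null <- effect <- freport <- uni <- NULL
  if (n_perms > 0) {
    null <- permutation_null(dm, n_perms = n_perms, k = k, reps = reps,
                             seed = seed, ...)
    effect <- compare_distributions(cv, null)
  }
  if (univariate) {
    uni <- lapply(setNames(seq_along(dm$feature_names), dm$feature_names),
                  function(j) univariate_logistic_loocv(dm$x[, j], dm$y,
                                                        dm$groups))
    freport <- build_feature_report(cv, uni, k = top_k)
  }
  structure(list(model = model, cv = cv, null = null, effect = effect,
                 features = freport, univariate = uni,
                 n_rows = nrow(dm$x), n_animals = length(unique(dm$groups)),
                 class_counts = table(dm$y),
                 settings = list(k = k, reps = reps, n_perms = n_perms,
                                 seed = seed, top_k = top_k)),
            class = "dbs_outcome_model")
}

#' @export
print.dbs_outcome_model <- function(x, ...) {
  cat(sprintf("Resting-LFP outcome model '%s' (%d animals, %d sessions)\n",
              x$model, x$n_animals, x$n_rows))
  if (!is.null(x$null)) {
    cat(sprintf("  mean accuracy %.0f%% (SD \u00b1 %.0f%%) vs permuted %.0f%% (SD \u00b1 %.0f%%), Cohen's d = %.2f\n",
                100 * x$cv$mean, 100 * x$cv$sd,
                100 * mean(x$null$accuracy), 100 * stats::sd(x$null$accuracy),
                x$effect$d))
  } else {
    cat(sprintf("  mean accuracy %.0f%% (SD \u00b1 %.0f%%), no permutation null computed\n",
                100 * x$cv$mean, 100 * x$cv$sd))
  }
  invisible(x)
}

#' @export
summary.dbs_outcome_model <- function(object, ...) {
  print(object)
  if (!is.null(object$features)) print(object$features)
  invisible(object)
}

#' Accuracy-distribution plot of a fitted outcome model
#'
#' Overlaid histograms of the observed cross-validated accuracies and (when
#' computed) the permutation-null accuracies, in the style of the usual
#' observed-versus-permuted decoding figures.
#'
#' @param x A `dbs_outcome_model`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.dbs_outcome_model <- function(x, ...) {
  obs <- 100 * x$cv$accuracy
  brk <- seq(0, 100, by = 5)
  if (!is.null(x$null)) {
    nul <- 100 * x$null$accuracy
    hn <- graphics::hist(nul, breaks = brk, plot = FALSE)
    ho <- graphics::hist(obs, breaks = brk, plot = FALSE)
    ylim <- c(0, max(hn$density, ho$density))
    graphics::hist(nul, breaks = brk, freq = FALSE, col = "white",
                   xlim = c(0, 100), ylim = ylim,
                   xlab = "cross-validated accuracy (%)",
                   main = paste("model:", x$model), ...)
    graphics::hist(obs, breaks = brk, freq = FALSE,
                   col = grDevices::adjustcolor("black", 0.6), add = TRUE)
    graphics::legend("topleft", fill = c("grey20", "white"),
                     legend = c("observed", "permuted"), bty = "n")
  } else {
    graphics::hist(obs, breaks = brk, freq = FALSE, col = "grey40",
                   xlim = c(0, 100),
                   xlab = "cross-validated accuracy (%)",
                   main = paste("model:", x$model), ...)
  }
  invisible(x)
}
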