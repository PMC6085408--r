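#' Build a design matrix for outcome classification
#'
#' Turns a feature table and outcome labels into the matrix interface used
#' by the classifier: rows are animal-sessions, columns the canonical LFP
#' features, with a binary outcome per row and an animal grouping vector
#' (both sessions of an animal always share one label).
#'
#' @param features Feature table with columns `animal`, `session` and
#'   feature columns (as from [extract_feature_table()]).
#' @param labels Either an `outcome_labels` data frame from
#'   [label_outcomes()], or a named vector / two-column data frame mapping
#'   animal to a binary label.
#' @param model Which outcome to classify: `"core"` (core
#'   responder = 1 vs non-responder = 0), `"shell"` (likewise for shell), or
#'   `"core_vs_shell"` (optimal target core = 1 vs shell = 0; animals
#'   without a responder target are excluded).
#' @return A list of class `design_matrix` with `x` (numeric matrix), `y`
#'   (0/1 integer), `groups` (animal ids), `feature_names`, `model`.
#' @export
build_design_matrix <- function(features, labels,
                                model = c("core", "shell",
                                          "core_vs_shell")) {
  model <- match.arg(model)
  meta <- intersect(c("animal", "session", "group"), names(features))
  if (!"animal" %in% meta)
    stop("features must carry an 'animal' column", call. = FALSE)
  fcols <- setdiff(names(features), meta)
  if (inherits(labels, "outcome_labels") ||
      (is.data.frame(labels) && any(grepl("_status$", names(labels))))) {
    lab <- switch(model,
      core = ifelse(labels$core_status == "responder", 1L, 0L),
      shell = ifelse(labels$shell_status == "responder", 1L, 0L),
      core_vs_shell = ifelse(labels$optimal_target == "core", 1L,
                             ifelse(labels$optimal_target == "shell", 0L,
                                    NA_integer_)))
    names(lab) <- labels$animal
    lab <- lab[!is.na(lab)]
  } else if (is.data.frame(labels)) {
    lab <- setNames(as.integer(labels[[2]]), labels[[1]])
  } else {
    lab <- setNames(as.integer(labels), names(labels))
  }
  keep <- features$animal %in% names(lab)
  features <- features[keep, , drop = FALSE]
  if (nrow(features) == 0)
    stop("no feature rows match the labelled animals", call. = FALSE)
  x <- as.matrix(features[fcols])
  if (anyNA(x)) stop("design matrix contains missing values", call. = FALSE)
  y <- as.integer(lab[features$animal])
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  structure(list(x = x, y = y, groups = features$animal,
                 feature_names = fcols, model = model),
            class = "design_matrix")
}

# Stratified group-aware fold assignment: animals (not sessions) are
# assigned to folds, so every session of an animal shares a fold. Animals
# of the two classes are paired and each pair is dealt to one fold: with
# balanced classes every fold -- and hence every training complement -- is
# exactly class-balanced, which keeps null-data accuracy at chance instead
# of anti-correlating held-out folds with the training majority. Leftover
# unpaired animals are dealt round-robin. Returns a per-row fold id.
make_group_folds <- function(groups, y, k, paired = TRUE) {
  anim <- unique(groups)
  alab <- y[match(anim, groups)]
  a1 <- sample(anim[alab == 1L])
  a0 <- sample(anim[alab == 0L])
  fold_of <- setNames(integer(length(anim)), anim)
  nxt <- sample.int(k, 1)
  if (paired) {
    npair <- min(length(a1), length(a0))
    for (i in seq_len(npair)) {
      f <- (nxt - 1L) %% k + 1L
      fold_of[a1[i]] <- f
      fold_of[a0[i]] <- f
      nxt <- nxt + 1L
    }
    rest <- c(tail(a1, length(a1) - npair), tail(a0, length(a0) - npair))
  } else {
    rest <- c(a1, a0)
  }
  for (a in rest) {
    fold_of[a] <- (nxt - 1L) %% k + 1L
    nxt <- nxt + 1L
  }
  fold_of[groups]
}

# TRUE when every training complement of the fold assignment contains both
# classes (required to fit a logistic model).
folds_trainable <- function(fold, y, k) {
  all(vapply(seq_len(k), function(f)
    length(unique(y[fold != f])) == 2L, logical(1)))
}

#' Lasso outcome classification with repeated group-aware cross-validation
#'
#' Fits L1-penalized logistic regressions under a k-fold cross-validation
#' scheme repeated `reps` times. Folds are stratified and group-aware: all
#' sessions of an animal share a fold, so no animal contributes to both the
#' training and held-out side of a split. Within every training fold,
#' features are standardized using training rows only and the penalty is
#' chosen by an inner cross-validation on the training fold
#' (minimum held-out deviance); held-out rows are classified at a 0.5
#' probability cutoff and pooled over the k folds into one accuracy per
#' repetition. A feature "survives" a fold-model when its lasso coefficient
#' is nonzero; % survival is the share of all `reps * k` fold-models in
#' which the feature survives.
#'
#' @param dm A `design_matrix` from [build_design_matrix()], or a numeric
#'   matrix (then `y` and `groups` are required).
#' @param y,groups Outcome (0/1) and animal id per row when `dm` is a bare
#'   matrix.
#' @param k Number of outer folds (default 4).
#' @param reps Number of repetitions (default 100).
#' @param seed Integer seed; each repetition uses a derived stream.
#' @param nlambda,lambda_min_ratio Penalty-path resolution passed to
#'   \pkg{glmnet}.
#' @return An object of class `lfp_cv`: list with `accuracy` (one value per
#'   repetition), `mean`, `sd`, `survival` (named percentages), selection
#'   counts, the number of fold-models, and the settings used.
#' @export
fit_lasso_repeated_cv <- function(dm, y = NULL, groups = NULL, k = 4,
                                  reps = 100, seed = 1L, nlambda = 40,
                                  lambda_min_ratio = 0.05) {
  if (inherits(dm, "design_matrix")) {
    x <- dm$x; y <- dm$y; groups <- dm$groups
  } else {
    x <- as.matrix(dm)
    if (is.null(y) || is.null(groups))
      stop("y and groups are required with a bare matrix", call. = FALSE)
    groups <- as.character(groups)
  }
  n_anim_by_class <- table(y[match(unique(groups), groups)])
  if (length(n_anim_by_class) != 2L || any(n_anim_by_class < 2L))
    stop("need at least 2 animals per class", call. = FALSE)
  if (k > length(unique(groups)))
    stop("k must not exceed the number of animals", call. = FALSE)
  p <- ncol(x)
  fnames <- colnames(x) %||% paste0("f", seq_len(p))
  selections <- setNames(numeric(p), fnames)
  acc <- numeric(reps)
  n_reshuffles <- 0L
  for (r in seq_len(reps)) {
    res <- with_seed(derive_seed(seed, r), {
      fold <- make_group_folds(groups, y, k)
      tries <- 0L
      while (!folds_trainable(fold, y, k) && tries < 50L) {
        fold <- make_group_folds(groups, y, k)
        tries <- tries + 1L
      }
      if (!folds_trainable(fold, y, k))
        stop("could not build folds with both classes in every training set",
             call. = FALSE)
      correct <- 0L
      sel <- numeric(p)
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- fit_lasso_fold(x[tr, , drop = FALSE], y[tr], groups[tr],
                              x[!tr, , drop = FALSE], nlambda,
                              lambda_min_ratio)
        # exact-tie probabilities (e.g. an intercept-only fit on balanced
        # training data) are undecided: half credit, the expectation of a
        # random tie-break, kept deterministic
        tie <- abs(fit$prob - 0.5) < 1e-9
        correct <- correct + sum((fit$prob > 0.5) == (y[!tr] == 1L) & !tie) +
          0.5 * sum(tie)
        sel[fit$selected] <- sel[fit$selected] + 1
      }
      list(acc = correct / length(y), sel = sel, tries = tries)
    })
    acc[r] <- res$acc
    selections <- selections + res$sel
    n_reshuffles <- n_reshuffles + res$tries
  }
  n_models <- reps * k
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 survival = 100 * selections / n_models,
                 selections = selections, n_models = n_models,
                 n_reshuffles = n_reshuffles,
                 settings = list(k = k, reps = reps, seed = seed,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)),
            class = "lfp_cv")
}

# One outer fold: training-only standardization, inner CV for lambda,
# held-out probabilities and surviving feature indices.
fit_lasso_fold <- function(xtr, ytr, gtr, xte, nlambda, lambda_min_ratio) {
  mu <- colMeans(xtr)
  sig <- apply(xtr, 2, stats::sd)
  usable <- which(sig > 0)  # constant features can never be selected
  xs <- sweep(sweep(xtr[, usable, drop = FALSE], 2, mu[usable]), 2,
              sig[usable], "/")
  # inner folds: plain stratified round-robin (every fold non-empty when
  # the training set has >= inner_k animals); penalty selection by deviance
  # does not need the paired balance the outer accuracy folds use
  inner_k <- min(4L, length(unique(gtr)))
  foldid <- make_group_folds(gtr, ytr, inner_k, paired = FALSE)
  tries <- 0L
  while (!folds_trainable(foldid, ytr, inner_k) && tries < 50L) {
    foldid <- make_group_folds(gtr, ytr, inner_k, paired = FALSE)
    tries <- tries + 1L
  }
  foldid <- match(foldid, sort(unique(foldid)))  # consecutive fold ids
  # glmnet's small-class advisory is expected at cohort-sized n; muffle it
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(xs, ytr, family = "binomial", foldid = foldid,
                      nlambda = nlambda,
                      lambda.min.ratio = lambda_min_ratio,
                      standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations|grouped=FALSE",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  xts <- sweep(sweep(xte[, usable, drop = FALSE], 2, mu[usable]), 2,
               sig[usable], "/")
  prob <- as.numeric(predict(cvfit, xts, s = "lambda.min",
                             type = "response"))
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  list(prob = prob, selected = usable[beta != 0])
}

#' @export
print.lfp_cv <- function(x, ...) {
  cat(sprintf("<lfp_cv> mean accuracy %.1f%% (SD \u00b1 %.1f%%) over %d repetitions of %d-fold CV\n",
              100 * x$mean, 100 * x$sd, x$settings$reps, x$settings$k))
  top <- sort(x$survival, decreasing = TRUE)[1:min(5, length(x$survival))]
  cat("  top survival:",
      paste(sprintf("%s %.0f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation-null accuracy distribution
#'
#' Re-runs the full repeated-CV lasso after randomly permuting the outcome
#' labels at the animal level (all sessions of an animal receive the
#' permuted label together, so label marginals and the repeated-measures
#' structure are preserved while the label-feature relationship is
#' destroyed). The pooled accuracy distribution across permutations is the
#' empirical null against which the observed accuracies are compared.
#'
#' @inheritParams fit_lasso_repeated_cv
#' @param n_perms Number of permutations (default 10; larger values give a
#'   smoother null and are recommended when runtime allows).
#' @return An object of class `lfp_permnull`: list with `accuracy` (pooled
#'   over permutations), `per_perm` (one `lfp_cv` summary per permutation),
#'   `n_perms`.
#' @export
permutation_null <- function(dm, y = NULL, groups = NULL, n_perms = 10,
                             k = 4, reps = 100, seed = 1L, nlambda = 40,
                             lambda_min_ratio = 0.05) {
  if (inherits(dm, "design_matrix")) {
    x <- dm$x; y <- dm$y; groups <- dm$groups
  } else {
    x <- as.matrix(dm)
    groups <- as.character(groups)
  }
  if (n_perms < 1) stop("n_perms must be >= 1", call. = FALSE)
  anim <- unique(groups)
  alab <- y[match(anim, groups)]
  per_perm <- vector("list", n_perms)
  pooled <- numeric(0)
  for (pm in seq_len(n_perms)) {
    yperm <- with_seed(derive_seed(seed, 1000L, pm), {
      setNames(sample(alab), anim)[groups]
    })
    cv <- fit_lasso_repeated_cv(x, y = as.integer(yperm), groups = groups,
                                k = k, reps = reps,
                                seed = derive_seed(seed, 2000L, pm),
                                nlambda = nlambda,
                                lambda_min_ratio = lambda_min_ratio)
    per_perm[[pm]] <- list(mean = cv$mean, sd = cv$sd)
    pooled <- c(pooled, cv$accuracy)
  }
  structure(list(accuracy = pooled, per_perm = per_perm,
                 n_perms = n_perms),
            class = "lfp_permnull")
}

#' @export
print.lfp_permnull <- function(x, ...) {
  cat(sprintf("<lfp_permnull> %d permutations, pooled null accuracy %.1f%% (SD \u00b1 %.1f%%)\n",
              x$n_perms, 100 * mean(x$accuracy), 100 * stats::sd(x$accuracy)))
  invisible(x)
}

# Mann-Whitney U with midrank tie handling, tie-corrected normal
# approximation, and rank-biserial ingredients. U counts pairs where a
# value of sample 1 exceeds one of sample 2 (ties count 1/2).
mann_whitney_u <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  r <- rank(c(x1, x2))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x1, x2))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  list(U = U, n1 = n1, n2 = n2, sigma = sqrt(sigma2))
}

#' Effect size of observed versus permutation-null accuracies
#'
#' Compares the observed cross-validated accuracy distribution with the
#' permutation-null distribution by the Mann-Whitney U test and converts
#' the statistic into a Cohen's d: the tie-corrected normal approximation
#' gives `z = (U - n1*n2/2) / sigma_U`, the correlation effect size is
#' `r = z / sqrt(n1 + n2)`, and `d = 2r / sqrt(1 - r^2)`. The sign is
#' positive when the observed distribution stochastically dominates the
#' null.
#'
#' @param observed Accuracies from [fit_lasso_repeated_cv()] (or the
#'   `lfp_cv` object itself).
#' @param null Accuracies from [permutation_null()] (or the `lfp_permnull`
#'   object itself).
#' @return An object of class `effect_size_report`: list with `U`, `n1`,
#'   `n2`, `z`, `r`, `d`, `direction` and a `degenerate` flag (all values
#'   identical in both samples).
#' @export
compare_distributions <- function(observed, null) {
  if (inherits(observed, "lfp_cv")) observed <- observed$accuracy
  if (inherits(null, "lfp_permnull")) null <- null$accuracy
  if (length(observed) == 0 || length(null) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  mw <- mann_whitney_u(observed, null)
  degenerate <- mw$sigma == 0
  z <- if (degenerate) 0 else (mw$U - mw$n1 * mw$n2 / 2) / mw$sigma
  r <- z / sqrt(mw$n1 + mw$n2)
  r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
  d <- 2 * r / sqrt(1 - r^2)
  structure(list(U = mw$U, n1 = mw$n1, n2 = mw$n2, z = z, r = r, d = d,
                 direction = if (d > 0) "observed > null"
                             else if (d < 0) "observed < null" else "none",
                 degenerate = degenerate),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("<effect_size_report> U = %.1f (n1 = %d, n2 = %d), z = %.2f, Cohen's d = %.2f%s\n",
              x$U, x$n1, x$n2, x$z, x$d,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Univariate logistic accuracy by exhaustive leave-one-animal-out CV
#'
#' For one feature, fits a single-predictor logistic regression on all but
#' one animal, predicts the held-out animal's sessions, and repeats for
#' every animal; the mean of the per-split accuracies is reported. The
#' direction arrow is up when the class-1 group mean of the feature exceeds
#' the class-0 mean. Training splits with perfect separation (a glm
#' warning) are refit with a lightly ridge-penalized logistic model.
#'
#' @param feature Numeric feature column (one value per row/session).
#' @param y Binary outcome per row.
#' @param groups Animal id per row; all sessions of an animal are held out
#'   together.
#' @return List with `accuracy` (mean over splits), `accuracies` (per
#'   split), `direction` (`"up"`/`"down"`), `n_separation` (splits that
#'   needed the penalized fallback).
#' @export
univariate_logistic_loocv <- function(feature, y, groups) {
  groups <- as.character(groups)
  anim <- unique(groups)
  alab <- y[match(anim, groups)]
  if (any(table(factor(alab, levels = c(0L, 1L))) < 3L))
    stop("need at least 3 animals per class", call. = FALSE)
  n_sep <- 0L
  accs <- vapply(anim, function(a) {
    tr <- groups != a
    d <- data.frame(y = y[tr], f = feature[tr])
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ f, family = stats::binomial(), data = d),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    newd <- data.frame(f = feature[!tr])
    if (sep) {
      n_sep <<- n_sep + 1L
      # ridge fallback: glmnet needs >= 2 columns, so duplicate the predictor
      xtr <- cbind(f = d$f, f2 = d$f)
      rf <- withCallingHandlers(
        glmnet::glmnet(xtr, d$y, family = "binomial", alpha = 0,
                       lambda = 1e-2),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      prob <- as.numeric(predict(rf, cbind(newd$f, newd$f),
                                 type = "response"))
    } else {
      prob <- as.numeric(predict(fit, newd, type = "response"))
    }
    mean((prob > 0.5) == (y[!tr] == 1L))
  }, numeric(1))
  dir <- if (mean(feature[y == 1L]) >= mean(feature[y == 0L])) "up" else "down"
  list(accuracy = mean(accs), accuracies = unname(accs), direction = dir,
       n_separation = n_sep)
}

#' Rank features by univariate accuracy and lasso survival
#'
#' Builds the two per-model feature rankings: by univariate
#' leave-one-animal-out % accuracy (logistic models) and by lasso %
#' survival, each with direction arrows, truncated to the top `k`. Ties in
#' the primary column are broken by the other column, then by feature name,
#' so the tables are deterministic.
#'
#' @param cv An `lfp_cv` from [fit_lasso_repeated_cv()].
#' @param univariate Named list of [univariate_logistic_loocv()] results
#'   (one per feature, names matching the design-matrix columns).
#' @param k Rows per table (default 5).
#' @return An object of class `feature_report`: list with data frames
#'   `logistic` (`direction`, `feature`, `accuracy_pct`) and `lasso`
#'   (`direction`, `feature`, `survival_pct`).
#' @export
build_feature_report <- function(cv, univariate, k = 5) {
  stopifnot(inherits(cv, "lfp_cv"))
  fnames <- names(cv$survival)
  if (!setequal(fnames, names(univariate)))
    stop("univariate results must cover exactly the fitted features",
         call. = FALSE)
  if (k > length(fnames)) {
    warning("k exceeds the number of features; truncating", call. = FALSE)
    k <- length(fnames)
  }
  arrow <- vapply(fnames, function(f)
    if (univariate[[f]]$direction == "up") "\u2191" else "\u2193", "")
  acc <- vapply(fnames, function(f) 100 * univariate[[f]]$accuracy,
                numeric(1))
  surv <- cv$survival[fnames]
  ord_l <- order(-acc, -surv, fnames)[seq_len(k)]
  ord_s <- order(-surv, -acc, fnames)[seq_len(k)]
  logistic <- data.frame(direction = arrow[ord_l], feature = fnames[ord_l],
                         accuracy_pct = round(acc[ord_l], 1),
                         stringsAsFactors = FALSE, row.names = NULL)
  lasso <- data.frame(direction = arrow[ord_s], feature = fnames[ord_s],
                      survival_pct = round(surv[ord_s], 1),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(logistic = logistic, lasso = lasso, k = k),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("Top", x$k, "features by univariate % accuracy (logistic):\n")
  print(x$logistic, row.names = FALSE)
  cat("Top", x$k, "features by % survival (lasso):\n")
  print(x$lasso, row.names = FALSE)
  invisible(x)
}
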