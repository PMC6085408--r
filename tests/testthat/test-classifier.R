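# Small direct design matrices: n animals per class, s sessions each, one
# informative feature (class separation `sep` in SD units) plus noise.
toy_design <- function(n1 = 12, n0 = 12, s = 1, p_noise = 9, sep = 6,
                       seed = 1) {
  set.seed(seed)
  anim <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n0)))
  alab <- rep(c(1L, 0L), c(n1, n0))
  groups <- rep(anim, each = s)
  y <- rep(alab, each = s)
  x <- cbind(sep * y + rnorm(length(y)),
             matrix(rnorm(length(y) * p_noise), ncol = p_noise))
  colnames(x) <- paste0("f", seq_len(p_noise + 1))
  list(x = x, y = y, groups = groups)
}

test_that("Mann-Whitney U agrees with brute-force pairwise counting", {
  set.seed(20)
  for (i in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x1 <- sample(1:5, n1, replace = TRUE)  # heavy ties on purpose
    x2 <- sample(1:5, n2, replace = TRUE)
    mw <- bingeLFP:::mann_whitney_u(x1, x2)
    expect_equal(mw$U, brute_force_u(x1, x2))
    expect_equal(mw$U, unname(suppressWarnings(
      stats::wilcox.test(x1, x2)$statistic)))
  }
})

test_that("the U-to-d conversion has the documented fixed points and symmetry", {
  # central U: identical samples give d = 0
  ctr <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ctr$d, 0)
  # swapping samples flips the sign, magnitude unchanged
  a <- rnorm(20); b <- rnorm(25, 1)
  e1 <- compare_distributions(a, b)
  e2 <- compare_distributions(b, a)
  expect_equal(e1$d, -e2$d, tolerance = 1e-12)
  # complete separation: U = n1 * n2, large positive d
  sep <- compare_distributions(101:120, 1:20)
  expect_equal(sep$U, 400)
  expect_gt(sep$d, 2)
  # all-identical degenerate case
  dg <- compare_distributions(rep(0.5, 5), rep(0.5, 7))
  expect_true(dg$degenerate)
  expect_equal(dg$d, 0)
  expect_error(compare_distributions(numeric(0), 1), "nonempty")
})

test_that("repeated-CV lasso separates a strong planted feature", {
  td <- toy_design(sep = 6, seed = 2)
  cv <- fit_lasso_repeated_cv(td$x, td$y, td$groups, reps = 15, seed = 3)
  expect_gt(cv$mean, 0.95)
  expect_gt(cv$survival["f1"], 90)
  expect_length(cv$accuracy, 15)
  expect_equal(cv$mean, mean(cv$accuracy))
  expect_equal(cv$sd, sd(cv$accuracy))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_true(all(cv$survival >= 0 & cv$survival <= 100))
})

test_that("constant features are never selected", {
  td <- toy_design(n1 = 6, n0 = 6, sep = 4, p_noise = 3, seed = 4)
  td$x[, 3] <- 7  # zero variance
  cv <- fit_lasso_repeated_cv(td$x, td$y, td$groups, reps = 5, seed = 5)
  expect_identical(unname(cv$survival["f3"]), 0)
})

test_that("fold assignment is group-aware and stratified", {
  td <- toy_design(n1 = 6, n0 = 6, s = 2, seed = 6)
  set.seed(1)
  fold <- bingeLFP:::make_group_folds(td$groups, td$y, 4)
  # all sessions of an animal share a fold
  expect_true(all(tapply(fold, td$groups, function(f)
    length(unique(f))) == 1))
  # stratification: every fold holds animals of both classes (6+6 over 4)
  af <- tapply(fold, td$groups, unique)
  al <- td$y[match(names(af), td$groups)]
  expect_true(all(table(af, al) >= 1))
})

test_that("animal-level label permutation preserves marginals and structure", {
  td <- toy_design(n1 = 5, n0 = 7, s = 2, seed = 7)
  anim <- unique(td$groups)
  alab <- td$y[match(anim, td$groups)]
  for (i in 1:20) {
    yp <- setNames(sample(alab), anim)[td$groups]
    expect_identical(as.vector(sort(table(yp))),
                     as.vector(sort(table(td$y))))
    expect_true(all(tapply(yp, td$groups, function(v)
      length(unique(v))) == 1))
  }
})

test_that("permutation null of an informative design sits at chance", {
  td <- toy_design(n1 = 6, n0 = 6, sep = 6, seed = 8)
  cv <- fit_lasso_repeated_cv(td$x, td$y, td$groups, reps = 10, seed = 9)
  nul <- permutation_null(td$x, td$y, td$groups, n_perms = 4, reps = 10,
                          seed = 9)
  expect_length(nul$accuracy, 40)
  expect_lt(mean(nul$accuracy), 0.72)
  expect_gt(mean(nul$accuracy), 0.28)
  expect_gt(cv$mean - mean(nul$accuracy), 0.25)
  expect_gt(compare_distributions(cv, nul)$d, 0.8)
  expect_error(permutation_null(td$x, td$y, td$groups, n_perms = 0),
               ">= 1")
})

test_that("a redundant near-copy of a feature splits lasso selections", {
  td <- toy_design(n1 = 8, n0 = 8, sep = 5, p_noise = 5, seed = 10)
  cv1 <- fit_lasso_repeated_cv(td$x, td$y, td$groups, reps = 10, seed = 11)
  set.seed(12)
  xdup <- cbind(td$x, f1_copy = td$x[, "f1"] + rnorm(nrow(td$x), 0, 0.2))
  cv2 <- fit_lasso_repeated_cv(xdup, td$y, td$groups, reps = 10, seed = 11)
  # the redundant copy carries no extra information: selections are shared
  # between the pair, and neither member out-survives the original alone
  expect_lt(min(cv2$survival[c("f1", "f1_copy")]), cv1$survival["f1"])
  expect_lte(max(cv2$survival[c("f1", "f1_copy")]),
             cv1$survival["f1"] + 10)
})

test_that("univariate leave-one-animal-out logistic accuracy behaves at the extremes", {
  set.seed(21)
  groups <- rep(paste0("a", 1:12), each = 2)
  y <- rep(rep(c(1L, 0L), each = 6), each = 2)
  # feature = label + tiny noise: near-perfect accuracy, direction up
  f <- y + rnorm(24, 0, 0.05)
  r <- univariate_logistic_loocv(f, y, groups)
  expect_gt(r$accuracy, 0.95)
  expect_identical(r$direction, "up")
  # constant feature: falls back to the majority class rate
  y2 <- rep(rep(c(1L, 0L), c(8, 4)), each = 2)
  r2 <- univariate_logistic_loocv(rep(1.3, 24), y2, groups)
  expect_equal(r2$accuracy, 8 / 12, tolerance = 1e-9)
  expect_error(univariate_logistic_loocv(f[1:8], y[1:8], groups[1:8]),
               "3 animals")
})

test_that("feature report ranks by accuracy and survival with fixed tie-breaks", {
  td <- toy_design(n1 = 6, n0 = 6, sep = 6, p_noise = 4, seed = 12)
  cv <- fit_lasso_repeated_cv(td$x, td$y, td$groups, reps = 8, seed = 13)
  uni <- lapply(setNames(seq_len(ncol(td$x)), colnames(td$x)), function(j)
    univariate_logistic_loocv(td$x[, j], td$y, td$groups))
  rep5 <- build_feature_report(cv, uni, k = 3)
  expect_named(rep5$logistic, c("direction", "feature", "accuracy_pct"))
  expect_named(rep5$lasso, c("direction", "feature", "survival_pct"))
  expect_identical(rep5$logistic$feature[1], "f1")
  expect_identical(rep5$lasso$feature[1], "f1")
  expect_true(all(rep5$logistic$direction %in% c("\u2191", "\u2193")))
  expect_warning(big <- build_feature_report(cv, uni, k = 99), "truncat")
  expect_identical(nrow(big$lasso), ncol(td$x))
  # deterministic under rerun
  rep5b <- build_feature_report(cv, uni, k = 3)
  expect_identical(rep5, rep5b)
})

test_that("design matrices validate class structure", {
  feats <- null_cohort_features()
  lab <- group_label_table(feats, one = "A")
  dm <- build_design_matrix(feats[setdiff(names(feats), "group")], lab)
  expect_identical(dim(dm$x), c(24L, 60L))
  expect_identical(length(dm$y), 24L)
  one_class <- lab; one_class$label <- 1L
  expect_error(build_design_matrix(feats[setdiff(names(feats), "group")],
                                   one_class), "both outcome classes")
})
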