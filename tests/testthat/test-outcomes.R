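test_that("percent change from baseline is plain normalized arithmetic", {
  expect_equal(percent_change_from_baseline(7.4, 10), -26)
  expect_equal(percent_change_from_baseline(10, 10), 0)
  expect_equal(percent_change_from_baseline(15, 10), 50)
  expect_error(percent_change_from_baseline(5, 0), "positive")
})

test_that("the pooled baseline fit recovers a known normal distribution", {
  set.seed(10)
  f <- fit_baseline_distribution(rnorm(1e5, 0, 13))
  expect_equal(f$sd, 13, tolerance = 0.02)
  expect_equal(f$mean, 0, tolerance = 0.5)
  expect_gt(f$r_squared, 0.95)
  # symmetric two-point data: SD is the point value (up to the n-1 factor),
  # but a normal fits the bimodal histogram poorly
  two <- rep(c(-13, 13), 100)
  f2 <- fit_baseline_distribution(two)
  expect_equal(f2$sd, 13 * sqrt(200 / 199), tolerance = 1e-10)
  expect_lt(f2$r_squared, 0.5)
  expect_error(fit_baseline_distribution(rep(3, 10)), "constant")
  expect_error(fit_baseline_distribution(1), "at least 2")
})

test_that("a 36-rat, 3-session pooled baseline recreates the 13% SD", {
  # percent changes of sessions around the known per-animal baseline mean
  set.seed(11)
  pc <- rnorm(36 * 3, 0, 13)
  f <- fit_baseline_distribution(pc)
  expect_identical(f$n, 108L)
  expect_lt(abs(f$sd - 13), 3 * 13 / sqrt(2 * 107))  # 3 x SE of the SD
})

test_that("the responder rule requires all sessions beyond the strict threshold", {
  expect_identical(as.character(classify_response(c(-30, -28, -35))),
                   "responder")
  expect_identical(as.character(classify_response(c(-30, -20, -35))),
                   "non-responder")
  # boundary: exactly -26 is not 'greater than 2 SD'
  expect_identical(as.character(classify_response(c(-26, -27, -28))),
                   "non-responder")
  expect_error(classify_response(c(-30, -30)), "3 stimulation sessions")
  # an all-sessions increase is flagged, never a responder
  up <- classify_response(c(40, 35, 28))
  expect_identical(as.character(up), "non-responder")
  expect_true(attr(up, "paradoxical"))
})

test_that("the responder rule is monotone in the size of the reduction", {
  set.seed(12)
  for (i in 1:200) {
    pct <- rnorm(3, -20, 20)
    extra <- abs(rnorm(3, 0, 15))
    a <- as.character(classify_response(pct))
    b <- as.character(classify_response(pct - extra))
    expect_false(a == "responder" && b == "non-responder")
  }
})

test_that("optimal target picks the largest responder reduction", {
  expect_identical(assign_optimal_target(
    c(core = -40, shell = -30),
    c(core = "responder", shell = "responder")), "core")
  expect_identical(assign_optimal_target(
    c(core = -10, shell = -30),
    c(core = "non-responder", shell = "responder")), "shell")
  expect_identical(assign_optimal_target(
    c(core = -10, shell = -20),
    c(core = "non-responder", shell = "non-responder")), "excluded")
  expect_warning(tie <- assign_optimal_target(
    c(core = -30, shell = -30),
    c(core = "responder", shell = "responder")), "tie")
  expect_identical(tie, "core")
})

test_that("response profiles reproduce the printed cohort aggregations", {
  # second-experiment profile: 3 shell-only, 2 core-only, 2 both, 2 neither
  exp2 <- summarize_response_profiles(profile_labels(2, 3, 2, 2))
  expect_identical(exp2$single_target, 5L)
  expect_identical(exp2$n, 9L)
  # first-experiment cohort: 5/8 single-target
  exp1 <- summarize_response_profiles(profile_labels(2, 3, 2, 1))
  expect_identical(exp1$single_target, 5L)
  # pooled cohorts: 10/17 single-target, categories sum to cohort size
  pooled <- summarize_response_profiles(profile_labels(4, 6, 4, 3))
  expect_identical(pooled$single_target, 10L)
  expect_identical(pooled$core_only + pooled$shell_only + pooled$both +
                     pooled$neither, pooled$n)
  # all-both cohort: no single-target animals
  expect_identical(summarize_response_profiles(
    profile_labels(0, 0, 5, 0))$single_target, 0L)
  # missing labels are an error naming the animal
  bad <- profile_labels(1, 1, 1, 1)
  bad$shell_status[2] <- NA
  expect_error(summarize_response_profiles(bad), "rat02")
})

test_that("label_outcomes applies the whole rule chain to an intake table", {
  sp <- binge_gen_spec(effect_pct = c(core = -55, shell = -5), seed = 31)
  b <- simulate_binge_cohort(sp, 6)
  lab <- label_outcomes(b, threshold = 26)
  expect_identical(nrow(lab), 6L)
  expect_true(all(lab$core_status == "responder"))
  expect_true(all(lab$shell_status == "non-responder"))
  expect_true(all(lab$optimal_target == "core"))
  expect_identical(attr(lab, "threshold"), 26)
  # with no fixed threshold the rule refits 2 x SD from this table's baselines
  lab2 <- label_outcomes(b)
  expect_gt(attr(lab2, "threshold"), 10)
  expect_lt(attr(lab2, "threshold"), 35)
  expect_s3_class(attr(lab2, "baseline_fit"), "normal_fit")
})

test_that("the null responder probability matches the closed-form tail", {
  # (1 - Phi(2))^3 per target under no stimulation effect
  set.seed(13)
  pc <- matrix(rnorm(3 * 2e5, 0, 13), ncol = 3)
  hits <- mean(rowSums(pc < -26) == 3)
  p0 <- (1 - pnorm(2))^3
  expect_lt(abs(hits - p0), 3 * sqrt(p0 * (1 - p0) / 2e5) + p0)
})
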