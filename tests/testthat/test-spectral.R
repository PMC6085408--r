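make_rec <- function(x_list, fs, intervals = NULL) {
  lfp_recording(do.call(rbind, x_list), fs,
                channel_scheme(paste0("c", seq_along(x_list))),
                rest_intervals = intervals)
}

test_that("rest intervals are merged, clipped and length-filtered", {
  fs <- 100
  x <- list(rnorm(120 * fs), rnorm(120 * fs))
  rec <- make_rec(x, fs, cbind(0, 120))
  seg <- segment_rest_intervals(rec, 4)
  expect_identical(seg, cbind(start = 0L, stop = 12000L))
  # overlapping intervals merge before the length filter
  rec2 <- make_rec(x, fs, rbind(c(0, 2), c(1, 5)))
  expect_identical(segment_rest_intervals(rec2, 4),
                   cbind(start = 0L, stop = 500L))
  # all intervals too short -> explicit no-rest-data error
  rec3 <- make_rec(x, fs, rbind(c(0, 3), c(10, 12)))
  expect_error(segment_rest_intervals(rec3, 4), "no rest data")
})

test_that("Welch PSD recovers closed-form power of known signals", {
  fs <- 256
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  # sinusoid: total integrated power = A^2 / 2
  A <- 2
  x <- A * sin(2 * pi * 8 * t)
  psd <- compute_psd(x, fs)
  df <- diff(psd$freq[1:2])
  expect_equal(sum(psd$value) * df, A^2 / 2, tolerance = 0.05)
  # the power concentrates at 8 Hz (theta band of the default scheme)
  bs <- band_summarize(psd)
  expect_gt(bs["\u03b8"], max(bs[c("\u03b2", "l\u03b3", "h\u03b3")]) + 2)  # > 2 decades
  # white noise: flat density sigma^2 / (fs/2), averaged over draws
  set.seed(1)
  dens <- replicate(100, {
    p <- compute_psd(rnorm(10 * fs, sd = 1.5), fs)
    mean(p$value[p$freq > 5 & p$freq < 100])
  })
  expect_equal(mean(dens), 1.5^2 / (fs / 2), tolerance = 0.02)
  # zero signal: zero density
  expect_true(all(compute_psd(numeric(5 * fs), fs)$value == 0))
})

test_that("coherence is exact for copied channels and degenerate for one window", {
  fs <- 200
  set.seed(2)
  x <- rnorm(20 * fs)
  coh <- compute_coherence(x, x, fs)
  expect_true(all(coh$value > 1 - 1e-10))
  expect_true(all(coh$value <= 1))
  expect_error(compute_coherence(x[1:(2 * fs)], x[1:(2 * fs)], fs,
                                 welch_params(window_s = 2, overlap = 0)),
               "at least two")
})

test_that("independent channels lose coherence as windows accumulate", {
  fs <- 200
  set.seed(3)
  coh_short <- compute_coherence(rnorm(10 * fs), rnorm(10 * fs), fs)
  coh_long <- compute_coherence(rnorm(200 * fs), rnorm(200 * fs), fs)
  expect_lt(mean(coh_long$value), mean(coh_short$value))
  expect_lt(mean(coh_long$value), 0.02)
})

test_that("coherence is symmetric and invariant to channel rescaling", {
  fs <- 250
  rec <- simulate_lfp_recording(mixing_spec(fs = fs, duration = 10, seed = 8))
  x <- rec$samples[1, ]; y <- rec$samples[2, ]
  cxy <- compute_coherence(x, y, fs)
  cyx <- compute_coherence(y, x, fs)
  expect_equal(cxy$value, cyx$value, tolerance = 1e-12)
  csc <- compute_coherence(3.7 * x, 0.2 * y, fs)
  expect_equal(csc$value, cxy$value, tolerance = 1e-9)
  # PSD is invariant to a DC shift thanks to per-window detrending
  p0 <- compute_psd(x, fs)
  p1 <- compute_psd(x + 100, fs)
  expect_equal(p1$value[-1], p0$value[-1], tolerance = 1e-6)
})

test_that("band summaries transform power and coherence as documented", {
  sp <- structure(data.frame(freq = seq(0, 100, 0.5),
                             value = rep(0.02, 201)),
                  type = "psd", n_windows = 10,
                  class = c("lfp_spectrum", "data.frame"))
  expect_equal(unname(band_summarize(sp)), rep(log10(0.02), 6))
  attr(sp, "type") <- "coherence"
  sp$value <- rep(1, 201)
  expect_equal(unname(band_summarize(sp)), rep(1, 6))
  expect_error(band_summarize(sp, band_scheme("far", 99.6, 99.9)),
               "no frequency bins")
})

test_that("feature vectors have the canonical layout and counts", {
  rec <- simulate_lfp_recording(mixing_spec(fs = 500, duration = 10, seed = 3))
  fv <- extract_feature_vector(rec)
  expect_length(fv, 60)
  expect_identical(names(fv), as.character(feature_names()))
  expect_identical(sum(attr(fv, "kind") == "power"), 24L)
  expect_identical(sum(attr(fv, "kind") == "coherence"), 36L)
  expect_true(all(fv[attr(fv, "kind") == "coherence"] >= 0 &
                    fv[attr(fv, "kind") == "coherence"] <= 1))
})

test_that("Welch band coherence agrees with the analytic mixing oracle", {
  # single 60 s recording: wide bands within the 0.05 oracle tolerance
  sp <- mixing_spec(duration = 60, seed = 1)
  an <- analytic_coherence(sp)
  fv <- extract_feature_vector(simulate_lfp_recording(sp))
  est <- fv[paste0("C", an$pair, " ", an$band)]
  wide <- an$band %in% c("\u03b2", "l\u03b3", "h\u03b3")
  expect_lt(max(abs(est[wide] - an$coherence[wide])), 0.05)
  # averaging replicate recordings brings every band within tolerance
  for (s in 2:6)
    est <- est + extract_feature_vector(
      simulate_lfp_recording(mixing_spec(duration = 60, seed = s))
    )[names(est)]
  est <- est / 6
  expect_lt(max(abs(est - an$coherence)), 0.05)
})

test_that("a single-band source drives only its own band", {
  g <- matrix(0, 4, 6); g[, 6] <- 1  # high-gamma only
  sp <- mixing_spec(gains = g, sigma_noise = 0.05, fs = 500, duration = 20,
                    seed = 12)
  fv <- extract_feature_vector(simulate_lfp_recording(sp))
  expect_gt(fv["Pcl h\u03b3"], fv["Pcl \u0394"] + 1)       # > 1 decade of power
  expect_gt(fv["Cclcr h\u03b3"], 0.9)
  expect_lt(max(fv[c("Cclcr \u0394", "Cclcr \u03b8", "Cclcr \u03b2")]), 0.2)
})

test_that("feature stability contrasts session drift with group separation", {
  feats <- planted_cohort_features()
  # identical sessions: zero within-animal difference
  dup <- feats[feats$session == 1, ]
  dup2 <- dup; dup2$session <- 2
  st0 <- feature_stability(rbind(dup, dup2))
  expect_true(all(st0$within == 0))
  # planted feature: day-to-day drift smaller than the group difference
  st <- feature_stability(feats)
  expect_lt(st$ratio[st$feature == planted_feature_name], 1)
  expect_error(feature_stability(feats[feats$group == "R", ]),
               "two groups")
})
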