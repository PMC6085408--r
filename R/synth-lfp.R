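#' Mixing specification for synthetic multichannel LFP
#'
#' The generator builds each channel as a linear mixture of band-limited
#' shared sources plus independent noise:
#' \deqn{x_c(t) = \sum_b a_{cb}\, s_b(t) + e_c(t)}
#' where `s_b` is Gaussian noise confined to band `b` (shared across
#' channels) and `e_c` is independent noise composed of per-band band-limited
#' components (SD `sigma_noise[c, b]`) plus an optional broadband white floor
#' (`sigma_floor`). All band-limited components are produced by zero-phase
#' FFT band-pass filtering of white noise, so the in-band power spectral
#' density of a component with input SD `s` is exactly flat at
#' `s^2 / (fs/2)`. This makes the expected magnitude-squared coherence of a
#' channel pair in a band available in closed form (see
#' [analytic_coherence()]), which is the oracle the spectral estimators are
#' tested against.
#'
#' @param gains Shared-source gains: scalar, or a channels-by-bands matrix
#'   `a[c, b]` (dimensionless).
#' @param sigma_source Source SD per band (scalar or length-B vector);
#'   must be `>= 0`.
#' @param sigma_noise Independent in-band noise SD: scalar, per-channel
#'   vector, or channels-by-bands matrix; the total noise for every
#'   channel/band (including `sigma_floor`) must be positive.
#' @param sigma_floor Broadband white-noise floor SD (default 0).
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration Recording length in seconds (default 120).
#' @param seed Integer seed for the recording's random draws.
#' @param channels,bands Channel and band schemes (canonical defaults).
#' @return An object of class `mixing_spec`.
#' @seealso [simulate_lfp_recording()], [analytic_coherence()]
#' @export
mixing_spec <- function(gains = 1, sigma_source = 1, sigma_noise = 1,
                        sigma_floor = 0, fs = 1000, duration = 120,
                        seed = 1L, channels = channel_scheme(),
                        bands = band_scheme()) {
  C <- length(channels)
  B <- nrow(bands)
  expand_cb <- function(x, name) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(C, B)))
        stop(name, " matrix must be channels x bands", call. = FALSE)
    } else if (length(x) == 1L) {
      x <- matrix(x, C, B)
    } else if (length(x) == C) {
      x <- matrix(x, C, B)
    } else stop(name, " must be scalar, per-channel, or channels x bands",
                call. = FALSE)
    dimnames(x) <- list(as.character(channels), bands$name)
    x
  }
  gains <- expand_cb(gains, "gains")
  sigma_noise <- expand_cb(sigma_noise, "sigma_noise")
  if (length(sigma_source) == 1L) sigma_source <- rep(sigma_source, B)
  if (length(sigma_source) != B)
    stop("sigma_source must be scalar or one value per band", call. = FALSE)
  names(sigma_source) <- bands$name
  if (any(!is.finite(gains)))
    stop("gains must be finite", call. = FALSE)
  if (any(sigma_source < 0))
    stop("sigma_source must be >= 0", call. = FALSE)
  if (any(sigma_noise < 0) || sigma_floor < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (any(sigma_noise^2 + sigma_floor^2 <= 0))
    stop("total noise SD must be positive for every channel/band",
         call. = FALSE)
  stop_if_not_scalar_num(fs, "fs", positive = TRUE)
  stop_if_not_scalar_num(duration, "duration", positive = TRUE)
  if (any(bands$high > fs / 2))
    stop("band edges must lie below the Nyquist frequency fs/2",
         call. = FALSE)
  structure(list(gains = gains, sigma_source = sigma_source,
                 sigma_noise = sigma_noise, sigma_floor = sigma_floor,
                 fs = fs, duration = duration, seed = as.integer(seed),
                 channels = channels, bands = bands),
            class = "mixing_spec")
}

#' Closed-form band coherence of the mixing model
#'
#' For channels `c`, `d` sharing the band-`b` source with gains `a_c`,
#' `a_d`, source variance `s2 = sigma_source[b]^2` and in-band noise power
#' `n_c = sigma_noise[c,b]^2 + sigma_floor^2`, the expected
#' magnitude-squared coherence is
#' \deqn{C_{cd}(b) = \frac{(a_c a_d s^2)^2}{(a_c^2 s^2 + n_c)(a_d^2 s^2 + n_d)}}
#' which always lies in `[0, 1]`.
#'
#' @param spec A [mixing_spec()].
#' @return Data frame with columns `pair` (e.g. `"clcr"`), `chan1`, `chan2`,
#'   `band`, `coherence`.
#' @export
analytic_coherence <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  ch <- as.character(spec$channels)
  pairs <- utils::combn(ch, 2, simplify = FALSE)
  s2 <- spec$sigma_source^2
  noise2 <- spec$sigma_noise^2 + spec$sigma_floor^2
  rows <- lapply(pairs, function(p) {
    num <- (spec$gains[p[1], ] * spec$gains[p[2], ] * s2)^2
    den <- (spec$gains[p[1], ]^2 * s2 + noise2[p[1], ]) *
           (spec$gains[p[2], ]^2 * s2 + noise2[p[2], ])
    data.frame(pair = paste0(p[1], p[2]), chan1 = p[1], chan2 = p[2],
               band = spec$bands$name, coherence = as.numeric(num / den),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Zero-phase FFT band-pass: keep only Fourier components with
# low <= f <= high. Input white noise keeps its flat in-band density.
bandlimited_noise <- function(n, fs, low, high, sd) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n, sd = sd)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  X[f < low | f > high] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate one multichannel resting LFP recording
#'
#' Draws band-limited shared sources and independent noise according to a
#' [mixing_spec()] and mixes them into a channels-by-time recording. The
#' returned recording carries a single full-length rest interval, the seed,
#' and the closed-form coherence table from [analytic_coherence()] in its
#' `meta` field for oracle testing.
#'
#' @param spec A [mixing_spec()].
#' @return An [lfp_recording()].
#' @examples
#' rec <- simulate_lfp_recording(mixing_spec(duration = 12, seed = 7))
#' rec$meta$analytic_coherence[1:3, ]
#' @export
simulate_lfp_recording <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  n <- round(spec$duration * spec$fs)
  # enough data for >= 8 Welch windows of 2 s at 50% overlap
  if (n < 4.5 * 2 * spec$fs)
    stop("duration too short: need at least 9 s for stable Welch averaging",
         call. = FALSE)
  ch <- as.character(spec$channels)
  bd <- spec$bands
  with_seed(spec$seed, {
    sources <- lapply(seq_len(nrow(bd)), function(b)
      bandlimited_noise(n, spec$fs, bd$low[b], bd$high[b],
                        spec$sigma_source[b]))
    samples <- matrix(0, length(ch), n)
    for (ci in seq_along(ch)) {
      x <- numeric(n)
      for (b in seq_len(nrow(bd))) {
        if (spec$gains[ci, b] != 0 && spec$sigma_source[b] > 0)
          x <- x + spec$gains[ci, b] * sources[[b]]
        if (spec$sigma_noise[ci, b] > 0)
          x <- x + bandlimited_noise(n, spec$fs, bd$low[b], bd$high[b],
                                     spec$sigma_noise[ci, b])
      }
      if (spec$sigma_floor > 0)
        x <- x + stats::rnorm(n, sd = spec$sigma_floor)
      samples[ci, ] <- x
    }
    lfp_recording(samples, spec$fs, spec$channels,
                  meta = list(seed = spec$seed,
                              analytic_coherence = analytic_coherence(spec),
                              mixing_spec = spec))
  })
}

#' Cohort specification for the synthetic two-group LFP study
#'
#' Describes a cohort of animals in two (or more) groups, each recorded in
#' `sessions` resting sessions separated in time. Group differences are
#' planted as controlled shifts of specific features; animal-level and
#' session-level multiplicative jitter on the mixing gains provides
#' biological and day-to-day nuisance variation, so planted between-group
#' differences are stable across sessions while nothing else separates the
#' groups.
#'
#' Planted effects are lists with fields `kind` (`"coherence"` or
#' `"power"`), `channels` (two labels for coherence, one for power), `band`,
#' `delta` (coherence shift on the raw 0-1 scale, or power shift in log10
#' units), and optionally `group` (which group receives the shift; default
#' the first group label). Coherence shifts are planted power-neutrally: the
#' shared-source gain and the in-band noise of the two channels are re-solved
#' so that the pair's closed-form coherence moves by `delta` while each
#' channel's total in-band power is unchanged.
#'
#' @param n_per_group Animals per group (scalar or per-group vector).
#' @param groups Character vector of group labels (default `c("R", "NR")`).
#' @param planted List of planted effect descriptors (default none: a null
#'   cohort).
#' @param sessions Recording sessions per animal (default 2).
#' @param session_jitter_sd SD of the multiplicative session-to-session gain
#'   jitter (default 0.05).
#' @param animal_sd SD of the multiplicative between-animal gain variation
#'   (default 0.05).
#' @param base Baseline [mixing_spec()] shared by all animals; its seed
#'   field is ignored in favour of derived per-recording seeds.
#' @param seed Master seed; every animal/session recording seed is derived
#'   deterministically from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12, groups = c("R", "NR"),
                        planted = list(), sessions = 2,
                        session_jitter_sd = 0.05, animal_sd = 0.05,
                        base = mixing_spec(), seed = 1L) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, length(groups))
  if (length(n_per_group) != length(groups) || any(n_per_group < 1))
    stop("need at least one animal per group", call. = FALSE)
  if (sessions < 1) stop("sessions must be >= 1", call. = FALSE)
  stopifnot(inherits(base, "mixing_spec"))
  if (length(planted) > 0 && !is.null(planted$kind))
    planted <- list(planted)  # single effect given unwrapped
  for (ef in planted) validate_planted(ef, base, groups)
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 planted = planted, sessions = as.integer(sessions),
                 session_jitter_sd = session_jitter_sd,
                 animal_sd = animal_sd, base = base,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

validate_planted <- function(ef, base, groups) {
  if (!is.list(ef) || is.null(ef$kind) || is.null(ef$channels) ||
      is.null(ef$band) || is.null(ef$delta))
    stop("a planted effect needs fields kind, channels, band, delta",
         call. = FALSE)
  if (!ef$kind %in% c("coherence", "power"))
    stop("planted kind must be 'coherence' or 'power'", call. = FALSE)
  nloc <- if (ef$kind == "coherence") 2L else 1L
  if (length(ef$channels) != nloc ||
      !all(ef$channels %in% as.character(base$channels)))
    stop("planted channels invalid for kind ", ef$kind, call. = FALSE)
  if (!ef$band %in% base$bands$name)
    stop("planted band not in band scheme", call. = FALSE)
  if (!is.null(ef$group) && !ef$group %in% groups)
    stop("planted group not among cohort groups", call. = FALSE)
  invisible(ef)
}

# Apply planted effects to a baseline mixing spec, returning the modified
# spec for the affected group. Coherence shifts hold per-channel in-band
# total power fixed; power shifts hold coherence fixed.
plant_effects <- function(base, effects) {
  spec <- base
  for (ef in effects) {
    b <- match(ef$band, spec$bands$name)
    s2 <- spec$sigma_source[b]^2
    if (ef$kind == "coherence") {
      if (s2 <= 0)
        stop("cannot plant coherence in a band with zero source power",
             call. = FALSE)
      c1 <- ef$channels[1]; c2 <- ef$channels[2]
      n1 <- spec$sigma_noise[c1, b]^2 + spec$sigma_floor^2
      n2 <- spec$sigma_noise[c2, b]^2 + spec$sigma_floor^2
      T1 <- spec$gains[c1, b]^2 * s2 + n1
      T2 <- spec$gains[c2, b]^2 * s2 + n2
      C0 <- (spec$gains[c1, b] * spec$gains[c2, b] * s2)^2 / (T1 * T2)
      Ct <- C0 + ef$delta
      if (Ct < 0 || Ct >= 1)
        stop("planted coherence target out of [0, 1): ", signif(Ct, 3),
             call. = FALSE)
      r <- sqrt(Ct)
      for (cc in c(c1, c2)) {
        Tc <- spec$gains[cc, b]^2 * s2 + spec$sigma_noise[cc, b]^2 +
          spec$sigma_floor^2
        a2 <- r * Tc / s2
        nn2 <- Tc - a2 * s2 - spec$sigma_floor^2
        if (nn2 < 0)
          stop("planted coherence not reachable with the broadband floor",
               call. = FALSE)
        spec$gains[cc, b] <- sqrt(a2)
        spec$sigma_noise[cc, b] <- sqrt(nn2)
      }
    } else {  # power: scale gain and in-band noise together
      g <- sqrt(10^ef$delta)
      cc <- ef$channels[1]
      spec$gains[cc, b] <- spec$gains[cc, b] * g
      spec$sigma_noise[cc, b] <- spec$sigma_noise[cc, b] * g
    }
  }
  spec
}

#' Simulate a synthetic LFP cohort
#'
#' Generates every animal-session recording of a [cohort_spec()]. Per-animal
#' gain multipliers are drawn once and reused across that animal's sessions
#' (with small session jitter), so planted between-group differences are
#' stable across recording days. Recording seeds are derived
#' deterministically from the master seed and the animal/session indices:
#' the same spec always yields identical recordings.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `lfp_cohort`: a list with `records` (one
#'   element per animal-session holding `animal`, `session`, `group` and the
#'   [lfp_recording()]) and `group_specs` (the planted [mixing_spec()] per
#'   group, with analytic coherence tables).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  group_specs <- lapply(spec$groups, function(g) {
    efs <- Filter(function(ef) (ef$group %||% spec$groups[1]) == g,
                  spec$planted)
    plant_effects(spec$base, efs)
  })
  names(group_specs) <- spec$groups
  C <- length(spec$base$channels)
  B <- nrow(spec$base$bands)
  animals <- data.frame(
    animal = character(0), group = character(0), stringsAsFactors = FALSE)
  for (gi in seq_along(spec$groups))
    animals <- rbind(animals, data.frame(
      animal = sprintf("%s_%02d", spec$groups[gi],
                       seq_len(spec$n_per_group[gi])),
      group = spec$groups[gi], stringsAsFactors = FALSE))
  # nuisance multipliers drawn up-front for determinism
  mult <- with_seed(spec$seed, {
    lapply(seq_len(nrow(animals)), function(ai) {
      A <- matrix(stats::rnorm(C * B, 1, spec$animal_sd), C, B)
      S <- lapply(seq_len(spec$sessions), function(si)
        matrix(stats::rnorm(C * B, 1, spec$session_jitter_sd), C, B))
      list(animal = A, sessions = S)
    })
  })
  records <- list()
  for (ai in seq_len(nrow(animals))) {
    gspec <- group_specs[[animals$group[ai]]]
    for (si in seq_len(spec$sessions)) {
      mspec <- gspec
      mspec$gains <- gspec$gains * mult[[ai]]$animal * mult[[ai]]$sessions[[si]]
      mspec$seed <- derive_seed(spec$seed, ai, si)
      rec <- simulate_lfp_recording(mspec)
      records[[length(records) + 1L]] <-
        list(animal = animals$animal[ai], session = si,
             group = animals$group[ai], recording = rec)
    }
  }
  structure(list(records = records, group_specs = group_specs, spec = spec),
            class = "lfp_cohort")
}

#' @export
print.lfp_cohort <- function(x, ...) {
  gr <- table(vapply(x$records, `[[`, "", "group"))
  cat(sprintf("<lfp_cohort> %d recordings (%s), %d session(s)/animal\n",
              length(x$records),
              paste(names(gr), gr, sep = ": ", collapse = ", "),
              x$spec$sessions))
  invisible(x)
}
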