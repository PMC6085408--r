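#' Welch estimation parameters
#'
#' Defaults: 2 s Hamming windows with 50% overlap and per-window linear
#' detrending. A 2 s window gives 0.5 Hz resolution, enough to resolve the
#' 1-4 Hz delta band while leaving many averages in a one- or two-minute
#' rest recording.
#'
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`.
#' @param detrend `"linear"` (remove per-window linear trend), `"mean"`, or
#'   `"none"`.
#' @return An object of class `welch_params`.
#' @export
welch_params <- function(window_s = 2, overlap = 0.5, detrend = "linear") {
  stop_if_not_scalar_num(window_s, "window_s", positive = TRUE)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  detrend <- match.arg(detrend, c("linear", "mean", "none"))
  structure(list(window_s = window_s, overlap = overlap, detrend = detrend),
            class = "welch_params")
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

detrend_window <- function(x, mode, tc, tc2) {
  if (mode == "none") return(x)
  x <- x - mean(x)
  if (mode == "linear") x <- x - (sum(x * tc) / tc2) * tc
  x
}

# Windowed FFTs of one channel over a list of rest segments.
# Returns the complex window x frequency matrix plus scaling constants.
# Window placement depends only on segment lengths, so two channels of the
# same recording always get identical windows.
welch_windows <- function(segments, fs, wp = welch_params()) {
  if (!is.list(segments)) segments <- list(segments)
  nfft <- round(wp$window_s * fs)
  hop <- max(1L, round(nfft * (1 - wp$overlap)))
  w <- hamming_window(nfft)
  tc <- seq_len(nfft) - (nfft + 1) / 2
  tc2 <- sum(tc^2)
  skipped <- 0L
  rows <- list()
  for (seg in segments) {
    if (length(seg) < nfft) { skipped <- skipped + 1L; next }
    starts <- seq(1L, length(seg) - nfft + 1L, by = hop)
    for (s in starts) {
      x <- detrend_window(seg[s:(s + nfft - 1L)], wp$detrend, tc, tc2)
      rows[[length(rows) + 1L]] <- stats::fft(x * w)
    }
  }
  if (skipped > 0)
    warning(skipped, " rest segment(s) shorter than the Welch window skipped",
            call. = FALSE)
  if (length(rows) == 0)
    stop("no rest segment is long enough for the Welch window", call. = FALSE)
  nf <- nfft %/% 2 + 1L
  F <- t(vapply(rows, function(z) z[seq_len(nf)], complex(nf)))
  list(F = F, freq = (seq_len(nf) - 1L) * fs / nfft, nfft = nfft,
       U = sum(w^2), n_windows = nrow(F), fs = fs)
}

one_sided_scale <- function(ww) {
  sc <- rep(2 / (ww$fs * ww$U), length(ww$freq))
  sc[1] <- sc[1] / 2
  if (ww$nfft %% 2 == 0) sc[length(sc)] <- sc[length(sc)] / 2
  sc
}

spectrum_df <- function(freq, value, type, n_windows) {
  structure(data.frame(freq = freq, value = value),
            type = type, n_windows = n_windows,
            class = c("lfp_spectrum", "data.frame"))
}

#' Welch power spectral density
#'
#' One-sided Welch-averaged PSD (units signal^2/Hz) over one or more rest
#' segments. Per-window periodograms are averaged across all windows of all
#' segments; segments are never concatenated, so no spurious power is
#' introduced at segment boundaries.
#'
#' @param segments Numeric vector, or list of numeric vectors (one per rest
#'   segment).
#' @param fs Sampling rate in Hz.
#' @param wp A [welch_params()].
#' @return An `lfp_spectrum` data frame with columns `freq`, `value` and
#'   attributes `type = "psd"`, `n_windows`.
#' @export
compute_psd <- function(segments, fs, wp = welch_params()) {
  ww <- welch_windows(segments, fs, wp)
  pxx <- colMeans(Mod(ww$F)^2) * one_sided_scale(ww)
  spectrum_df(ww$freq, pxx, "psd", ww$n_windows)
}

#' Welch magnitude-squared coherence
#'
#' Magnitude-squared coherence between two channels on the Welch grid:
#' `|mean(Sxy)|^2 / (mean(Sxx) * mean(Syy))`, averaged over identical
#' windows for both channels. By the Cauchy-Schwarz inequality the estimate
#' lies in `[0, 1]`; with a single window it degenerates to exactly 1, so at
#' least two windows are required.
#'
#' @param segments_x,segments_y Rest-segment samples of the two channels
#'   (same segment lengths, as produced by one recording).
#' @inheritParams compute_psd
#' @return An `lfp_spectrum` with `type = "coherence"`.
#' @export
compute_coherence <- function(segments_x, segments_y, fs,
                              wp = welch_params()) {
  wx <- welch_windows(segments_x, fs, wp)
  wy <- welch_windows(segments_y, fs, wp)
  if (wx$n_windows != wy$n_windows)
    stop("the two channels must supply identical windows", call. = FALSE)
  coherence_from_windows(wx, wy)
}

coherence_from_windows <- function(wx, wy) {
  if (wx$n_windows < 2)
    stop("coherence needs at least two Welch windows (it is degenerate at 1 for a single window)",
         call. = FALSE)
  sxx <- colMeans(Mod(wx$F)^2)
  syy <- colMeans(Mod(wy$F)^2)
  sxy <- colMeans(wx$F * Conj(wy$F))
  coh <- Mod(sxy)^2 / (sxx * syy)
  coh[!is.finite(coh)] <- 0  # zero-power bins carry no coherence
  # standard small-sample bias correction for averaged MSC,
  # E[Chat] ~ C + (1 - C)^2 / n_windows
  coh <- pmin(pmax(coh - (1 - coh)^2 / wx$n_windows, 0), 1)
  spectrum_df(wx$freq, coh, "coherence", wx$n_windows)
}

#' Average a spectrum into frequency-band summaries
#'
#' Power spectra are averaged over the in-band frequency bins and then
#' log10-transformed (variance stabilization for downstream regression);
#' coherence is averaged untransformed on its natural 0-1 scale. Band edges
#' are inclusive on both sides of the bin grid.
#'
#' @param spectrum An `lfp_spectrum` from [compute_psd()] or
#'   [compute_coherence()].
#' @param bands A [band_scheme()].
#' @return Named numeric vector, one value per band.
#' @export
band_summarize <- function(spectrum, bands = band_scheme()) {
  stopifnot(inherits(spectrum, "lfp_spectrum"))
  type <- attr(spectrum, "type")
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- spectrum$freq >= bands$low[b] & spectrum$freq <= bands$high[b]
    if (!any(sel))
      stop("band '", bands$name[b], "' contains no frequency bins",
           call. = FALSE)
    m <- mean(spectrum$value[sel])
    if (type == "psd") log10(m) else m
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' Extract the canonical LFP feature vector of one recording session
#'
#' Computes, from the rest intervals of a multichannel recording, the band
#' power of every channel and the band coherence of every channel pair, and
#' returns them as a named feature vector in canonical order (power
#' features first). For C channels and B bands this yields
#' `B*C + B*C*(C-1)/2` features; with the canonical 4-channel, 6-band
#' schemes, 60 features (24 power + 36 coherence).
#'
#' @param recording An [lfp_recording()].
#' @param bands A [band_scheme()].
#' @param wp A [welch_params()].
#' @param min_rest_s Minimum rest-interval length in seconds.
#' @return Named numeric vector of features with attribute `"kind"`
#'   (`"power"`/`"coherence"` per element).
#' @export
extract_feature_vector <- function(recording, bands = band_scheme(),
                                   wp = welch_params(), min_rest_s = 4) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (any(bands$high > recording$fs / 2))
    stop("band edges exceed the Nyquist frequency", call. = FALSE)
  segs <- segment_rest_intervals(recording, min_rest_s)
  ch <- as.character(recording$channels)
  ww <- lapply(ch, function(cc)
    welch_windows(segment_samples(recording, segs, cc), recording$fs, wp))
  names(ww) <- ch
  vals <- numeric(0)
  for (cc in ch) {
    psd <- spectrum_df(ww[[cc]]$freq,
                       colMeans(Mod(ww[[cc]]$F)^2) * one_sided_scale(ww[[cc]]),
                       "psd", ww[[cc]]$n_windows)
    v <- band_summarize(psd, bands)
    names(v) <- paste0("P", cc, " ", bands$name)
    vals <- c(vals, v)
  }
  pairs <- utils::combn(ch, 2, simplify = FALSE)
  for (p in pairs) {
    coh <- coherence_from_windows(ww[[p[1]]], ww[[p[2]]])
    v <- band_summarize(coh, bands)
    names(v) <- paste0("C", p[1], p[2], " ", bands$name)
    vals <- c(vals, v)
  }
  nB <- nrow(bands); nC <- length(ch)
  structure(vals, kind = rep(c("power", "coherence"),
                             c(nB * nC, nB * nC * (nC - 1) / 2)))
}

#' Feature table for a whole synthetic cohort
#'
#' Runs [extract_feature_vector()] on every recording of an `lfp_cohort`
#' and assembles one row per animal-session.
#'
#' @param cohort An `lfp_cohort` from [simulate_cohort()].
#' @inheritParams extract_feature_vector
#' @return Data frame with metadata columns `animal`, `session`, `group`
#'   followed by the canonical feature columns.
#' @export
extract_feature_table <- function(cohort, bands = band_scheme(),
                                  wp = welch_params(), min_rest_s = 4) {
  stopifnot(inherits(cohort, "lfp_cohort"))
  rows <- lapply(cohort$records, function(r) {
    fv <- extract_feature_vector(r$recording, bands, wp, min_rest_s)
    cbind(data.frame(animal = r$animal, session = r$session,
                     group = r$group, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE, optional = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-animal stability versus between-group separation of features
#'
#' For each feature, compares the mean absolute within-animal change between
#' the two recording sessions (T1 to T2) with the absolute between-group
#' difference of animal means. A ratio below 1 marks a feature whose
#' between-group separation exceeds its day-to-day drift - the property that
#' makes a resting-state feature usable for outcome classification.
#'
#' @param features A feature table with columns `animal`, `session`, `group`
#'   and feature columns (as from [extract_feature_table()]).
#' @return Data frame with columns `feature`, `within` (mean |T1-T2|),
#'   `between` (|group-mean difference|), `ratio` (= within/between).
#' @export
feature_stability <- function(features) {
  meta <- c("animal", "session", "group")
  if (!all(meta %in% names(features)))
    stop("features must have animal, session and group columns",
         call. = FALSE)
  groups <- unique(features$group)
  if (length(groups) != 2L)
    stop("between-group difference needs exactly two groups, got ",
         length(groups), call. = FALSE)
  fcols <- setdiff(names(features), meta)
  counts <- table(features$animal)
  bad <- names(counts)[counts != 2L]
  if (length(bad) > 0) {
    warning("excluding animal(s) without exactly two sessions: ",
            paste(bad, collapse = ", "), call. = FALSE)
    features <- features[!features$animal %in% bad, , drop = FALSE]
    if (nrow(features) == 0) stop("no animals left", call. = FALSE)
  }
  f1 <- features[features$session == 1, , drop = FALSE]
  f2 <- features[features$session == 2, , drop = FALSE]
  f2 <- f2[match(f1$animal, f2$animal), , drop = FALSE]
  within <- colMeans(abs(as.matrix(f1[fcols]) - as.matrix(f2[fcols])))
  amean <- (as.matrix(f1[fcols]) + as.matrix(f2[fcols])) / 2
  g <- f1$group
  between <- abs(colMeans(amean[g == groups[1], , drop = FALSE]) -
                 colMeans(amean[g == groups[2], , drop = FALSE]))
  data.frame(feature = fcols, within = as.numeric(within),
             between = as.numeric(between),
             ratio = as.numeric(within / between),
             stringsAsFactors = FALSE, row.names = NULL)
}
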