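#' Multichannel LFP recording
#'
#' Container for a resting multichannel local field potential recording:
#' a channels-by-time sample matrix, its sampling rate, the channel scheme,
#' and the rest intervals (periods of behavioural inactivity) from which
#' spectral features may be computed. Times are seconds, 0-based, and
#' intervals are half-open `[start, stop)`.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channels A [channel_scheme()] whose length matches `nrow(samples)`.
#' @param rest_intervals Two-column matrix (or data frame) of interval start
#'   and stop times in seconds. Default: one interval covering the whole
#'   recording.
#' @param meta Optional list of metadata (seed, analytic coherence, ...).
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, channels = channel_scheme(),
                          rest_intervals = NULL, meta = list()) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (channels x time)", call. = FALSE)
  if (nrow(samples) < 2L)
    stop("a recording needs at least 2 channels", call. = FALSE)
  stop_if_not_scalar_num(fs, "fs", positive = TRUE)
  if (length(channels) != nrow(samples))
    stop("channel scheme length must match nrow(samples)", call. = FALSE)
  rownames(samples) <- as.character(channels)
  duration <- ncol(samples) / fs
  if (is.null(rest_intervals))
    rest_intervals <- cbind(start = 0, stop = duration)
  rest_intervals <- as.matrix(rest_intervals)
  if (ncol(rest_intervals) != 2L || !is.numeric(rest_intervals))
    stop("rest_intervals must have two numeric columns (start, stop)",
         call. = FALSE)
  colnames(rest_intervals) <- c("start", "stop")
  if (any(rest_intervals[, 1] >= rest_intervals[, 2]))
    stop("rest intervals must have start < stop", call. = FALSE)
  structure(list(samples = samples, fs = fs, channels = channels,
                 rest_intervals = rest_intervals, duration = duration,
                 meta = meta),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels (%s), %.1f s at %g Hz, %d rest interval(s)\n",
              nrow(x$samples), paste(x$channels, collapse = ","),
              x$duration, x$fs, nrow(x$rest_intervals)))
  invisible(x)
}

#' Select rest-interval sample segments
#'
#' Merges overlapping or touching rest intervals, clips them to the
#' recording, drops intervals shorter than `min_len_s`, and converts the
#' survivors to half-open 0-based sample ranges (start rounded up, stop
#' rounded down).
#'
#' @param recording An [lfp_recording()].
#' @param min_len_s Minimum interval length in seconds to keep (default 4).
#' @return Integer matrix with columns `start`, `stop`: half-open 0-based
#'   sample ranges, so segment `i` is samples `start[i]+1 .. stop[i]` in R's
#'   1-based indexing.
#' @export
segment_rest_intervals <- function(recording, min_len_s = 4) {
  stopifnot(inherits(recording, "lfp_recording"))
  iv <- recording$rest_intervals
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmin(iv[, 2], recording$duration)
  iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
  if (nrow(iv) > 0) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      last <- nrow(merged)
      if (iv[i, 1] <= merged[last, 2])
        merged[last, 2] <- max(merged[last, 2], iv[i, 2])
      else merged <- rbind(merged, iv[i, ])
    }
    iv <- merged
  }
  iv <- iv[(iv[, 2] - iv[, 1]) >= min_len_s, , drop = FALSE]
  if (nrow(iv) == 0)
    stop("no rest data: no rest interval of at least ", min_len_s,
         " s survives merging and clipping", call. = FALSE)
  fs <- recording$fs
  out <- cbind(start = as.integer(ceiling(iv[, 1] * fs)),
               stop = as.integer(floor(iv[, 2] * fs)))
  out
}

# Extract the sample vectors of one channel over the given segments.
segment_samples <- function(recording, segments, channel) {
  x <- recording$samples[channel, ]
  lapply(seq_len(nrow(segments)), function(i)
    x[(segments[i, 1] + 1):segments[i, 2]])
}
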