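#' Channel scheme for multichannel LFP recordings
#'
#' The canonical recording montage is bilateral nucleus accumbens core and
#' shell: left core `"cl"`, right core `"cr"`, left shell `"sl"`, right
#' shell `"sr"`. The order of the labels is fixed and determines how channel
#' pairs are enumerated when coherence features are named and ordered.
#'
#' @param labels Character vector of unique channel labels, in montage order.
#' @return An object of class `channel_scheme` (a character vector).
#' @examples
#' channel_scheme()
#' channel_scheme(c("a", "b"))
#' @export
channel_scheme <- function(labels = c("cl", "cr", "sl", "sr")) {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyNA(labels) || any(!nzchar(labels)))
    stop("channel labels must be non-empty strings", call. = FALSE)
  if (anyDuplicated(labels))
    stop("channel labels must be unique", call. = FALSE)
  structure(labels, class = "channel_scheme")
}

#' Frequency-band scheme
#'
#' Defines the ordered set of frequency bands over which spectra are averaged
#' into scalar features. The default is the conventional rodent scheme of six
#' bands: delta 1-4 Hz, theta 5-10 Hz, alpha 11-14 Hz, beta 15-30 Hz, low
#' gamma 45-65 Hz and high gamma 70-90 Hz, labelled with their conventional
#' symbols.
#'
#' @param name Character vector of band names.
#' @param low,high Numeric vectors of band edges in Hz (`low < high`,
#'   bands must not overlap).
#' @return A `band_scheme`: a data frame with columns `name`, `low`, `high`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(name = c("\u0394", "\u03b8", "\u03b1", "\u03b2",
                                 "l\u03b3", "h\u03b3"),
                        low = c(1, 5, 11, 15, 45, 70),
                        high = c(4, 10, 14, 30, 65, 90)) {
  name <- as.character(name)
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (length(name) != length(low) || length(low) != length(high))
    stop("name, low and high must have equal length", call. = FALSE)
  if (anyDuplicated(name)) stop("band names must be unique", call. = FALSE)
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low <= 0) ||
      any(low >= high))
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  ord <- order(low)
  if (any(head(high[ord], -1) > low[ord][-1]))
    stop("bands must not overlap", call. = FALSE)
  structure(data.frame(name = name, low = low, high = high,
                       stringsAsFactors = FALSE),
            class = c("band_scheme", "data.frame"))
}

#' Canonical feature label
#'
#' Power features are labelled `"P<channel> <band>"` (e.g. `"Pcr \u0394"`)
#' and coherence features `"C<chanA><chanB> <band>"` (e.g.
#' `"Cclcr h\u03b3"`), with the two channels of a pair always written in
#' channel-scheme order so the label is symmetric in its arguments.
#'
#' @param kind `"power"` or `"coherence"`.
#' @param locations One channel label (power) or two (coherence).
#' @param band Band name from the band scheme.
#' @param channels A [channel_scheme()] used to validate and order labels.
#' @param bands A [band_scheme()] used to validate the band name.
#' @return The canonical feature name (length-one character).
#' @examples
#' feature_label("power", "cr", "\u0394")
#' feature_label("coherence", c("cr", "cl"), "h\u03b3")  # order normalized
#' @export
feature_label <- function(kind = c("power", "coherence"), locations, band,
                          channels = channel_scheme(), bands = band_scheme()) {
  kind <- match.arg(kind)
  locations <- as.character(locations)
  if (!all(locations %in% channels))
    stop("unknown channel label(s): ",
         paste(setdiff(locations, channels), collapse = ", "), call. = FALSE)
  if (!band %in% bands$name)
    stop("unknown band name: ", band, call. = FALSE)
  if (kind == "power") {
    if (length(locations) != 1L)
      stop("power features take exactly one channel", call. = FALSE)
    paste0("P", locations, " ", band)
  } else {
    if (length(locations) != 2L || locations[1] == locations[2])
      stop("coherence features take two distinct channels", call. = FALSE)
    locations <- locations[order(match(locations, channels))]
    paste0("C", locations[1], locations[2], " ", band)
  }
}

#' All canonical feature names for a channel/band scheme
#'
#' Enumerates power features first (channels in scheme order, bands in scheme
#' order within each channel), then coherence features (pairs in scheme
#' order, bands within each pair). For C channels and B bands this yields
#' `B*C` power and `B*C*(C-1)/2` coherence names.
#'
#' @inheritParams feature_label
#' @return Character vector of feature names; attribute `"kind"` marks each
#'   as `"power"` or `"coherence"`.
#' @examples
#' length(feature_names())  # 60 for the canonical 4-channel, 6-band scheme
#' @export
feature_names <- function(channels = channel_scheme(), bands = band_scheme()) {
  pw <- unlist(lapply(channels, function(ch)
    paste0("P", ch, " ", bands$name)))
  pairs <- utils::combn(as.character(channels), 2, simplify = FALSE)
  co <- unlist(lapply(pairs, function(p)
    paste0("C", p[1], p[2], " ", bands$name)))
  structure(c(pw, co),
            kind = rep(c("power", "coherence"), c(length(pw), length(co))))
}
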