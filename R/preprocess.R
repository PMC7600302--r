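# Preprocessing: zero-phase band-pass filtering, surface Laplacian,
# interval segmentation and resting-record trimming.

#' Canonical frequency bands
#'
#' The sensorimotor rhythm bands used throughout: mu 8--13 Hz, beta
#' 14--30 Hz, and the broad 4--40 Hz analysis band.
#'
#' @param band \code{"mu"}, \code{"beta"} or \code{"broad"}.
#' @return numeric length-2 band edges in Hz.
#' @export
rhythmBand <- function(band = c("mu", "beta", "broad")) {
  band <- match.arg(band)
  switch(band, mu = c(8, 13), beta = c(14, 30), broad = c(4, 40))
}

# forward-backward filtering with odd-reflection padding at both ends,
# so the filter transient decays in the padding instead of the data
.filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(bf$b), length(bf$a)) * 10L)
  if (pad < 1) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

# zero-phase band-pass of a channels x samples matrix
.bandpass_matrix <- function(m, fs, low, high) {
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / (fs / 2), "pass")
  t(apply(m, 1, function(x) .filtfilt_padded(bf, x)))
}

#' Zero-phase band-pass filter
#'
#' Forward-backward 4th-order Butterworth band-pass, applied channel-wise
#' (and trial-wise for a \linkS4class{TrialSet}). The zero-phase scheme
#' preserves ERD/ERS latencies. Defaults to the 4--40 Hz analysis band;
#' pass \code{rhythmBand("mu")} or \code{rhythmBand("beta")} for the
#' sub-band filters.
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{TrialSet}.
#' @param low,high band edges in Hz, \code{0 < low < high < fs/2}.
#' @return object of the same class, filtered.
#' @export
setGeneric("bandpassFilter",
           function(x, low = 4, high = 40) standardGeneric("bandpassFilter"))

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "EEGRecording", function(x, low = 4, high = 40) {
  x@samples <- .bandpass_matrix(x@samples, x@fs, low, high)
  x
})

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "TrialSet", function(x, low = 4, high = 40) {
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= x@fs / 2) stop("high band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / (x@fs / 2), "pass")
  d <- dim(x@trials)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      x@trials[i, j, ] <- .filtfilt_padded(bf, x@trials[i, j, ])
  x
})

# subtract the neighbor mean from each requested channel
.laplacian_matrix <- function(m, channels, montage) {
  idx <- match(channels, montage@channels)
  if (anyNA(idx))
    stop("montage is missing channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  out <- m
  for (r in seq_along(channels)) {
    nbs <- montage@adjacency[[channels[r]]]
    nb_rows <- match(nbs, channels)
    nb_rows <- nb_rows[!is.na(nb_rows)]
    if (length(montage@adjacency[[channels[r]]]) < 2) {
      warning("channel ", channels[r],
              " has fewer than 2 neighbors; passed through unfiltered")
      next
    }
    if (length(nb_rows) == 0) next      # neighbors exist but not in data
    out[r, ] <- m[r, , drop = FALSE] -
      colMeans(m[nb_rows, , drop = FALSE])
  }
  out
}

#' Surface Laplacian spatial filter
#'
#' Small-Laplacian re-referencing: each channel's neighbor average (from
#' the montage adjacency) is subtracted from the channel, sharpening
#' focal sensorimotor activity and reducing volume conduction. Channels
#' with fewer than two montage neighbors are passed through with a
#' warning; neighbors present in the montage but absent from the data are
#' ignored.
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{TrialSet}.
#' @param montage a \linkS4class{Montage}; defaults to the trial set's
#'   own montage.
#' @return object of the same class, spatially filtered.
#' @export
setGeneric("laplacianFilter",
           function(x, montage) standardGeneric("laplacianFilter"))

#' @rdname laplacianFilter
#' @export
setMethod("laplacianFilter", "EEGRecording", function(x, montage) {
  x@samples <- .laplacian_matrix(x@samples, x@channels, montage)
  x
})

#' @rdname laplacianFilter
#' @export
setMethod("laplacianFilter", "TrialSet", function(x, montage) {
  if (missing(montage)) montage <- x@montage
  ch <- channelNames(x)
  for (i in seq_len(dim(x@trials)[1]))
    x@trials[i, , ] <- .laplacian_matrix(x@trials[i, , , drop = TRUE],
                                         ch, montage)
  x
})

#' Select channels of a trial set
#'
#' @param x a \linkS4class{TrialSet}.
#' @param channels channel labels to keep (order preserved as given).
#' @return a \linkS4class{TrialSet} restricted to those channels.
#' @export
selectChannels <- function(x, channels) {
  ch <- channelNames(x)
  if (!all(channels %in% ch))
    stop("trial set is missing channel(s): ",
         paste(setdiff(channels, ch), collapse = ", "))
  x@trials <- x@trials[, channels, , drop = FALSE]
  x
}

# sample index range for half-open [t0, t1) with 0-based time
.interval_samples <- function(t0, t1, fs) {
  start <- round(t0 * fs) + 1L
  count <- round((t1 - t0) * fs)
  if (count <= 0) stop("empty interval")
  seq.int(start, start + count - 1L)
}

#' Segment trials to a time interval
#'
#' Crops every trial to the half-open interval \code{[t0, t1)} (seconds
#' from trial start; sample count \code{round((t1 - t0) * fs)}). Named
#' intervals \code{"baseline"} and \code{"mi"} resolve through the trial
#' timing (defaults 0--2 s and 2.6--4.6 s).
#'
#' @param x a \linkS4class{TrialSet}.
#' @param interval \code{"baseline"}, \code{"mi"}, or a numeric
#'   \code{c(t0, t1)} within the trial.
#' @return a \linkS4class{TrialSet} with cropped trials. The stored
#'   timing keeps the original field values; segmented sets are treated
#'   as plain sample blocks downstream.
#' @export
segmentTrials <- function(x, interval) {
  if (is.character(interval)) {
    interval <- switch(match.arg(interval, c("baseline", "mi")),
                       baseline = x@timing@baseline,
                       mi = x@timing@mi)
  }
  if (length(interval) != 2 || interval[1] >= interval[2])
    stop("interval must be an increasing length-2 numeric")
  n <- dim(x@trials)[3]
  if (interval[1] < 0 || round(interval[2] * x@fs) > n)
    stop("interval outside the trial")
  idx <- .interval_samples(interval[1], interval[2], x@fs)
  x@trials <- x@trials[, , idx, drop = FALSE]
  x
}

#' Trim the start of a resting record
#'
#' Removes the first \code{drop_s} seconds (default 5 s), discarding the
#' initial measurement transient; a 60 s record becomes 55 s.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param drop_s seconds to drop from the start.
#' @return trimmed \linkS4class{EEGRecording}.
#' @export
trimResting <- function(rec, drop_s = 5) {
  n <- ncol(rec@samples)
  drop_n <- round(drop_s * rec@fs)
  if (drop_n >= n) stop("record shorter than the requested trim")
  if (drop_n > 0) rec@samples <- rec@samples[, -seq_len(drop_n), drop = FALSE]
  rec
}
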