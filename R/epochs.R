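#' Trial-structured multi-channel epoch container
#'
#' Wraps a 4-dimensional voltage array (subject x trial x channel x sample,
#' in uV) together with its timing and montage metadata and an ordered log
#' of applied preprocessing steps.
#'
#' @param data Numeric array, dimensions subject x trial x channel x sample.
#' @param sfreq Sampling rate, samples/s.
#' @param t0 Epoch start time in s relative to stimulus onset (negative for
#'   prestimulus samples).
#' @param channel_names Ordered channel labels, one per channel dimension.
#' @param log Character vector of applied processing steps.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, sfreq, t0, channel_names, log = character()) {
  stopifnot(length(dim(data)) == 4)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique", call. = FALSE)
  if (dim(data)[3] != length(channel_names))
    stop("channel dimension does not match channel_names", call. = FALSE)
  rng <- suppressWarnings(range(data))   # O(1) memory finiteness check
  if (anyNA(rng) || any(!is.finite(rng)))
    stop("epoch data must be finite", call. = FALSE)
  # stimulus onset must fall on the sample grid
  if (abs(t0 * sfreq - round(t0 * sfreq)) > 1e-6)
    stop("t0 is not on the sample grid", call. = FALSE)
  structure(list(data = data, sfreq = sfreq, t0 = t0,
                 channel_names = as.character(channel_names),
                 log = as.character(log)),
            class = "epoch_array")
}

#' Sample times of an epoch array
#'
#' @param epochs An `epoch_array` (or any object with `sfreq`, `t0` and a
#'   sample dimension `n`).
#' @param n Number of samples; defaults to the epoch's sample dimension.
#' @return Numeric vector of sample times in s relative to stimulus onset.
#' @export
epoch_times <- function(epochs, n = dim(epochs$data)[4]) {
  epochs$t0 + (seq_len(n) - 1L) / epochs$sfreq
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch array: %d subjects x %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  %g Hz, t = [%g, %g] s; channels: %s\n", x$sfreq, x$t0,
              x$t0 + (d[4] - 1) / x$sfreq,
              paste(x$channel_names, collapse = ", ")))
  if (length(x$log))
    cat("  log:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' Keep or exclude channels of an epoch array
#'
#' Channel selection (e.g. excluding EOG channels from analysis, or
#' restricting a large montage to the channels a feature set needs).
#'
#' @param epochs An [epoch_array()].
#' @param keep Channel labels to keep (in this order); or `NULL` to use
#'   `exclude`.
#' @param exclude Channel labels to drop.
#' @return The reduced `epoch_array`.
#' @export
select_channels <- function(epochs, keep = NULL, exclude = NULL) {
  if (is.null(keep)) keep <- setdiff(epochs$channel_names, exclude)
  idx <- vapply(keep, function(ch) channel_index(epochs, ch), integer(1))
  epoch_array(epochs$data[, , idx, , drop = FALSE], epochs$sfreq,
              epochs$t0, epochs$channel_names[idx],
              log = c(epochs$log,
                      sprintf("channels(%s)", paste(keep, collapse = ","))))
}

channel_index <- function(epochs, channel) {
  i <- match(channel, epochs$channel_names)
  if (is.na(i))
    stop(sprintf("unknown channel label '%s'", channel), call. = FALSE)
  i
}

#' Extract one channel as a subject x trial x sample array
#'
#' @param epochs An `epoch_array`.
#' @param channel Channel label.
#' @return A `channel_signal`: 3-d array (subject x trial x sample) with
#'   `sfreq`, `t0` and `label` attributes.
#' @export
channel_signal <- function(epochs, channel) {
  i <- channel_index(epochs, channel)
  x <- epochs$data[, , i, , drop = FALSE]
  dim(x) <- dim(epochs$data)[c(1, 2, 4)]
  structure(x, sfreq = epochs$sfreq, t0 = epochs$t0, label = channel,
            class = "channel_signal")
}
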