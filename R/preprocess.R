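#' Zero-phase band-pass filter epochs
#'
#' Filters every subject/trial/channel trace with a 4th-order Butterworth
#' band-pass applied zero-phase: the filter's squared magnitude response
#' (the exact forward-backward response, which cancels the phase) is
#' applied in the frequency domain. Epoch edges are protected by
#' odd-symmetric reflection padding of three filter time constants
#' (`3 * sfreq / low_hz` samples, capped at the trace length).
#'
#' @param epochs An [epoch_array()].
#' @param low_hz,high_hz Band edges in Hz; default (1, 100).
#' @return The filtered `epoch_array` with its log updated.
#' @export
bandpass_filter <- function(epochs, low_hz = 1, high_hz = 100) {
  fs <- epochs$sfreq
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low < high < sfreq/2", call. = FALSE)
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  d <- epochs$data
  dm <- dim(d)
  n <- dm[4]
  pad <- min(n - 1L, as.integer(round(3 * fs / low_hz)))
  x <- matrix(aperm(d, c(4, 1, 2, 3)), nrow = n)   # samples x traces
  x <- .zero_phase_filter(x, bf, pad)
  d <- aperm(array(x, dim = dm[c(4, 1, 2, 3)]), c(2, 3, 4, 1))
  epoch_array(d, fs, epochs$t0, epochs$channel_names,
              log = c(epochs$log,
                      sprintf("bandpass(%g,%g)", low_hz, high_hz)))
}

# zero-phase (squared-magnitude) IIR filtering of a samples x traces
# matrix with odd-reflection padding; exact forward-backward response
.zero_phase_filter <- function(x, filt, pad) {
  n <- nrow(x)
  pad <- min(n - 1L, pad)
  np <- n + 2L * pad
  w <- 2 * pi * (0:(np - 1)) / np
  ek <- exp(-1i * outer(w, 0:(length(filt$b) - 1)))
  h2 <- as.vector(Mod((ek %*% filt$b) / (ek %*% filt$a))^2)
  head_refl <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2, , drop = FALSE]
  tail_refl <- 2 * x[rep(n, pad), , drop = FALSE] - x[n - (1:pad), , drop = FALSE]
  xp <- rbind(head_refl, x, tail_refl)
  # pack two real traces per complex FFT (h2 is real and conjugate-
  # symmetric, so filtering each part stays exact); chunk the workspace
  ntr <- ncol(xp)
  pairs <- seq(1L, ntr, by = 2L)
  chunk <- max(1L, floor(4e6 / np))
  for (j0 in seq(1L, length(pairs), by = chunk)) {
    jj <- pairs[j0:min(j0 + chunk - 1L, length(pairs))]
    j2 <- pmin(jj + 1L, ntr)
    xc <- xp[, jj, drop = FALSE] + 1i * xp[, j2, drop = FALSE]
    xc <- stats::mvfft(stats::mvfft(xc) * h2, inverse = TRUE) / np
    xp[, jj] <- Re(xc)
    xp[, j2] <- Im(xc)
  }
  xp[pad + seq_len(n), , drop = FALSE]
}

#' Zero-phase low-pass smoothing of a single-channel signal set
#'
#' 4th-order Butterworth low-pass applied zero-phase (squared magnitude
#' response), used to smooth waveforms before peak measurement so that
#' high-frequency activity (gamma-band oscillations, residual noise) does
#' not bias the extremum search.
#'
#' @param sig A `channel_signal` (subject x trial x sample).
#' @param high_hz Low-pass corner frequency in Hz (default 30).
#' @return The smoothed `channel_signal`.
#' @export
lowpass_signal <- function(sig, high_hz = 30) {
  fs <- attr(sig, "sfreq")
  if (!(high_hz > 0 && high_hz < fs / 2))
    stop("invalid corner: need 0 < high < sfreq/2", call. = FALSE)
  bf <- signal::butter(4, high_hz / (fs / 2), type = "low")
  dm <- dim(sig)
  x <- matrix(aperm(unclass(sig), c(3, 1, 2)), nrow = dm[3])
  x <- .zero_phase_filter(x, bf, as.integer(round(3 * fs / high_hz)))
  out <- aperm(array(x, dim = dm[c(3, 1, 2)]), c(2, 3, 1))
  attributes(out)[c("sfreq", "t0", "label")] <-
    attributes(sig)[c("sfreq", "t0", "label")]
  class(out) <- "channel_signal"
  out
}

#' Baseline-correct epochs in the time domain
#'
#' Subtracts, per trial and channel, the mean voltage over the prestimulus
#' window.
#'
#' @param epochs An [epoch_array()].
#' @param window_s Baseline window (start, end) in s; default (-0.5, 0).
#' @return Baseline-corrected `epoch_array`.
#' @export
baseline_correct_time <- function(epochs, window_s = c(-0.5, 0)) {
  tt <- epoch_times(epochs)
  sel <- tt >= window_s[1] & tt <= window_s[2]
  if (!any(sel) || window_s[1] < tt[1] - 1e-9 ||
      window_s[2] > tt[length(tt)] + 1e-9)
    stop("baseline window outside epoch or empty", call. = FALSE)
  d <- epochs$data
  bl <- apply(d[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  d <- d - as.vector(bl)   # recycles over the sample dimension (last)
  epoch_array(d, epochs$sfreq, epochs$t0, epochs$channel_names,
              log = c(epochs$log,
                      sprintf("baseline(%g,%g)", window_s[1], window_s[2])))
}

#' Re-referenced single-channel derivation
#'
#' Returns `channel - reference_channel` per trial (e.g. the C4-Fz
#' derivation used for the N1 wave). With `reference_channel = NULL` the
#' plain channel is returned (for recordings already referenced, e.g.
#' nose-referenced Cz).
#'
#' @param epochs An [epoch_array()].
#' @param channel Channel label.
#' @param reference_channel Reference channel label, or `NULL`.
#' @return A `channel_signal` (subject x trial x sample array).
#' @export
rereference <- function(epochs, channel, reference_channel = NULL) {
  x <- channel_signal(epochs, channel)
  if (!is.null(reference_channel)) {
    r <- channel_signal(epochs, reference_channel)
    out <- unclass(x) - unclass(r)
    attributes(out) <- attributes(x)
    attr(out, "label") <- paste0(channel, "-", reference_channel)
    x <- out
  }
  x
}
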