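#' Single-trial time-frequency decomposition by windowed Fourier transform
#'
#' Computes, for every trial, the power `|sum_n x(n) h(n) exp(-i 2 pi f n / fs)|^2`
#' of the Hanning-windowed segment of length `window_s` centred at each
#' analysis time, for each analysis frequency. Time points whose window
#' would exceed the epoch edges are dropped. Power is the squared
#' magnitude of the (two-sided) windowed DFT coefficient; since all
#' downstream measures are percent change relative to baseline, no
#' one-sided or window-gain normalisation is applied (recorded in the
#' object's `convention` field).
#'
#' @param x An [epoch_array()] (then `channel` is required) or a
#'   `channel_signal` from [rereference()]/[channel_signal()].
#' @param channel Channel label when `x` is an `epoch_array`.
#' @param window_s Analysis window length in s (default 0.25).
#' @param step_s Time step of the analysis grid in s (default 0.01).
#' @param freqs Analysis frequencies in Hz (default 1-100 in 1 Hz steps).
#' @param times Analysis times in s; default: all epoch times on the
#'   `step_s` grid whose window fits inside the epoch.
#' @return A `tfd` object: `power` (subject x trial x frequency x time),
#'   `freqs_hz`, `times_s`, `window_s`, `baseline_state = "raw"`,
#'   `kind = "total"`.
#' @export
wft_tfd <- function(x, channel = NULL, window_s = 0.25, step_s = 0.01,
                    freqs = 1:100, times = NULL) {
  if (inherits(x, "epoch_array")) {
    if (is.null(channel)) stop("channel is required", call. = FALSE)
    sig <- channel_signal(x, channel)
  } else sig <- x
  fs <- attr(sig, "sfreq")
  t0 <- attr(sig, "t0")
  dm <- dim(sig)
  n <- dm[3]
  half <- round(window_s * fs / 2)
  L <- 2L * half + 1L
  if (L > n) stop("window longer than epoch", call. = FALSE)
  tt <- t0 + (seq_len(n) - 1L) / fs
  if (is.null(times)) {
    step <- max(1L, round(step_s * fs))
    centers <- seq(1L + half, n - half, by = step)
  } else {
    centers <- round((times - t0) * fs) + 1L
    if (any(centers - half < 1L | centers + half > n))
      stop("analysis times exceed epoch minus half-window margins",
           call. = FALSE)
  }
  times_s <- tt[centers]
  han <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  # windowed complex exponential basis, real and imaginary stacked so the
  # segment projection is a single real matrix product
  ang <- -2 * pi * outer(0:(L - 1), freqs) / fs
  basis <- cbind(cos(ang), sin(ang)) * han           # L x 2F
  nf <- length(freqs)
  ntp <- length(centers)
  seg_idx <- outer(seq_len(ntp), -half:half,
                   function(j, o) centers[j] + o)    # ntp x L
  ns <- dm[1]; ntr <- dm[2]
  power <- array(NA_real_, dim = c(ns, ntr, nf, ntp))
  for (s in seq_len(ns)) {
    d <- matrix(sig[s, , ], nrow = ntr)              # trials x samples
    big <- array(0, dim = c(ntr, ntp, L))            # segment stack
    for (j in seq_len(ntp)) big[, j, ] <- d[, seg_idx[j, ]]
    dim(big) <- c(ntr * ntp, L)
    proj <- big %*% basis                            # (trials*ntp) x 2F
    pw <- proj[, seq_len(nf), drop = FALSE]^2 +
      proj[, nf + seq_len(nf), drop = FALSE]^2
    dim(pw) <- c(ntr, ntp, nf)
    power[s, , , ] <- aperm(pw, c(1, 3, 2))
  }
  structure(list(power = power, freqs_hz = as.numeric(freqs),
                 times_s = times_s, window_s = window_s, sfreq = fs,
                 channel = attr(sig, "label"), baseline_state = "raw",
                 kind = "total",
                 convention = "two-sided squared windowed-DFT magnitude"),
            class = "tfd")
}

#' @export
print.tfd <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("TFD (%s, %s): %d subjects x %d trials x %d freqs x %d times\n",
              x$kind, x$baseline_state, d[1], d[2], d[3], d[4]))
  cat(sprintf("  channel %s, %g-%g Hz, t = [%g, %g] s, window %g s\n",
              x$channel, min(x$freqs_hz), max(x$freqs_hz),
              min(x$times_s), max(x$times_s), x$window_s))
  invisible(x)
}

#' Percent-change baseline correction of a TFD
#'
#' For each subject, channel and frequency, the raw power is expressed as
#' percent change relative to the mean prestimulus power:
#' `100 * (P(t, f) - B(f)) / B(f)`, where `B(f)` is the mean of the
#' trial-averaged power over the baseline window. The default window
#' (-0.4 to -0.1 s) leaves a half-window margin to both the epoch start
#' and stimulus onset so no post-stimulus energy leaks into the baseline.
#'
#' @param tfd A raw `tfd` (kind total or evoked).
#' @param baseline_s Baseline window (start, end) in s.
#' @return The baseline-corrected `tfd` (`baseline_state = "percent"`).
#' @export
tfd_baseline_correct <- function(tfd, baseline_s = c(-0.4, -0.1)) {
  if (tfd$baseline_state != "raw")
    stop("TFD is already baseline-corrected", call. = FALSE)
  if (!tfd$kind %in% c("total", "evoked"))
    stop("baseline correction applies to total or evoked power", call. = FALSE)
  sel <- tfd$times_s >= baseline_s[1] & tfd$times_s <= baseline_s[2]
  if (!any(sel)) stop("baseline window outside time grid", call. = FALSE)
  p <- tfd$power
  d <- dim(p)
  # B: subject x freq, averaged over trials and baseline times
  b <- apply(p[, , , sel, drop = FALSE], c(1, 3), mean)
  if (any(b == 0)) stop("degenerate baseline: zero power", call. = FALSE)
  barr <- array(rep(b, times = d[2] * d[4]), dim = c(d[1], d[3], d[2], d[4]))
  barr <- aperm(barr, c(1, 3, 2, 4))
  tfd$power <- 100 * (p - barr) / barr
  tfd$baseline_state <- "percent"
  tfd$baseline_window_s <- baseline_s
  tfd
}

#' Separate phase-locked from non-phase-locked power
#'
#' Computes three TFDs: `evoked` (WFT of the across-trial average
#' waveform, the phase-locked part), `total` (across-trial mean of
#' single-trial WFTs), and `induced = total - evoked` (non-phase-locked;
#' may be slightly negative at points where the estimator overshoots,
#' reported as-is).
#'
#' @inheritParams wft_tfd
#' @return List of three `tfd` objects (`evoked`, `total`, `induced`),
#'   each with a singleton trial dimension.
#' @export
split_phase_locked <- function(x, channel = NULL, window_s = 0.25,
                               step_s = 0.01, freqs = 1:100, times = NULL) {
  if (inherits(x, "epoch_array")) {
    if (is.null(channel)) stop("channel is required", call. = FALSE)
    sig <- channel_signal(x, channel)
  } else sig <- x
  if (dim(sig)[2] < 2)
    stop("at least 2 trials are required to split phase-locked power",
         call. = FALSE)
  avg <- apply(sig, c(1, 3), mean)
  dim(avg) <- c(dim(sig)[1], 1L, dim(sig)[3])
  attributes(avg)[c("sfreq", "t0", "label")] <-
    attributes(sig)[c("sfreq", "t0", "label")]
  class(avg) <- "channel_signal"
  evoked <- wft_tfd(avg, window_s = window_s, step_s = step_s,
                    freqs = freqs, times = times)
  evoked$kind <- "evoked"
  tot <- wft_tfd(sig, window_s = window_s, step_s = step_s,
                 freqs = freqs, times = times)
  d <- dim(tot$power)
  m <- apply(tot$power, c(1, 3, 4), mean)
  dim(m) <- c(d[1], 1L, d[3], d[4])
  total <- tot
  total$power <- m
  total$kind <- "total"
  induced <- total
  induced$power <- total$power - evoked$power
  induced$kind <- "induced"
  list(evoked = evoked, total = total, induced = induced)
}
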