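#' Region-of-interest definition for a response feature
#'
#' @param name Feature name.
#' @param domain "time" (peak features) or "tf" (time-frequency features).
#' @param channel Channel label the feature is measured at.
#' @param reference Optional reference channel (e.g. Fz for the C4-Fz N1
#'   derivation); `NULL` for already-referenced channels.
#' @param time_window (start, end) in s.
#' @param freq_window (low, high) in Hz, time-frequency domain only.
#' @param direction "positive" or "negative" deflection/power change.
#' @param fraction Proportion of most-extreme ROI points averaged for
#'   time-frequency magnitudes (default 0.2).
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(name, domain = c("time", "tf"), channel,
                           reference = NULL, time_window,
                           freq_window = NULL,
                           direction = c("positive", "negative"),
                           fraction = 0.2) {
  domain <- match.arg(domain)
  direction <- match.arg(direction)
  if (diff(time_window) <= 0) stop("empty time window", call. = FALSE)
  if (domain == "tf" && (is.null(freq_window) || diff(freq_window) <= 0))
    stop("tf ROI requires a nonempty frequency window", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  structure(list(name = name, domain = domain, channel = channel,
                 reference = reference, time_window = time_window,
                 freq_window = freq_window, direction = direction,
                 fraction = fraction),
            class = "roi_definition")
}

#' Canonical laser-evoked response ROIs
#'
#' The six standard regions of interest: N1 (C4-Fz, 120-200 ms, negative),
#' N2 (Cz, 180-300 ms, negative), P2 (Cz, 250-500 ms, positive), LEP
#' (Cz, 100-400 ms, 1-10 Hz), alpha-ERD (Cz, 600-900 ms, 7-13 Hz,
#' negative) and gamma-ERS (Cz, 180-260 ms, 60-85 Hz).
#'
#' @return Named list of [roi_definition()] objects.
#' @export
default_rois <- function() {
  list(
    N1 = roi_definition("N1", "time", "C4", "Fz", c(0.120, 0.200),
                        direction = "negative"),
    N2 = roi_definition("N2", "time", "Cz", NULL, c(0.180, 0.300),
                        direction = "negative"),
    P2 = roi_definition("P2", "time", "Cz", NULL, c(0.250, 0.500),
                        direction = "positive"),
    LEP = roi_definition("LEP", "tf", "Cz", NULL, c(0.100, 0.400),
                         c(1, 10), "positive"),
    aERD = roi_definition("aERD", "tf", "Cz", NULL, c(0.600, 0.900),
                          c(7, 13), "negative"),
    gERS = roi_definition("gERS", "tf", "Cz", NULL, c(0.180, 0.260),
                          c(60, 85), "positive")
  )
}

#' Write / read an ROI set as YAML
#' @param rois Named list of [roi_definition()] objects.
#' @param path File path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the ROI list.
#' @export
write_rois <- function(rois, path) {
  yaml::write_yaml(lapply(rois, unclass), path)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  lst <- yaml::read_yaml(path)
  lapply(lst, function(r)
    roi_definition(r$name, r$domain, r$channel, r$reference,
                   as.numeric(unlist(r$time_window)),
                   if (!is.null(r$freq_window)) as.numeric(unlist(r$freq_window)),
                   r$direction, r$fraction))
}

#' Baseline-to-peak amplitude within a latency window
#'
#' Returns the extremum of the stated polarity within the window and its
#' latency. The amplitude is signed (negative for N1/N2). Ties are broken
#' by the earliest window sample.
#'
#' @param waveform Numeric voltage trace (baseline-corrected).
#' @param times Sample times in s, same length as `waveform`.
#' @param window_s (start, end) search window in s.
#' @param direction "positive" or "negative".
#' @return List with `amplitude` (uV) and `latency` (s).
#' @export
peak_amplitude <- function(waveform, times, window_s,
                           direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sel <- which(times >= window_s[1] & times <= window_s[2])
  if (!length(sel)) stop("empty peak window", call. = FALSE)
  w <- waveform[sel]
  i <- if (direction == "negative") which.min(w) else which.max(w)
  list(amplitude = w[i], latency = times[sel[i]])
}

#' Top-fraction time-frequency ROI magnitude
#'
#' Collects all baseline-corrected power values inside the ROI rectangle
#' and averages the `fraction` most extreme points in the ROI's direction
#' (largest values for positive features; most negative for the alpha-ERD,
#' whose defining signature is a power decrease). The number of points
#' used is `ceiling(fraction * ROI size)`. Boundary ties are broken by
#' earlier time, then lower frequency.
#'
#' @param tfd A baseline-corrected `tfd`.
#' @param roi A time-frequency [roi_definition()].
#' @return Matrix of magnitudes, subjects x trials (percent power change).
#' @export
tfroi_magnitude <- function(tfd, roi) {
  if (tfd$baseline_state != "percent")
    stop("TFD must be baseline-corrected before ROI extraction",
         call. = FALSE)
  fsel <- which(tfd$freqs_hz >= roi$freq_window[1] &
                tfd$freqs_hz <= roi$freq_window[2])
  tsel <- which(tfd$times_s >= roi$time_window[1] - 1e-9 &
                tfd$times_s <= roi$time_window[2] + 1e-9)
  if (!length(fsel) || !length(tsel))
    stop(sprintf("ROI '%s' is empty on the TFD grid", roi$name),
         call. = FALSE)
  npts <- length(fsel) * length(tsel)
  k <- ceiling(roi$fraction * npts)
  grid_f <- rep(seq_along(fsel), times = length(tsel))
  grid_t <- rep(seq_along(tsel), each = length(fsel))
  d <- dim(tfd$power)
  out <- matrix(NA_real_, d[1], d[2])
  sgn <- if (roi$direction == "negative") 1 else -1
  for (s in seq_len(d[1])) for (tr in seq_len(d[2])) {
    v <- as.vector(tfd$power[s, tr, fsel, tsel])
    ord <- order(sgn * v, grid_t, grid_f)   # extreme first, ties t then f
    out[s, tr] <- mean(v[ord[seq_len(k)]])
  }
  out
}

#' Extract the per-trial feature table
#'
#' Measures the six scalar response magnitudes for every trial: peak
#' amplitudes (N1 on the C4-Fz derivation; N2 and P2 on Cz) from the
#' baseline-corrected waveforms, and time-frequency magnitudes (LEP,
#' alpha-ERD, gamma-ERS on Cz) from single-trial percent-change TFDs
#' whose baseline spectrum is the trial average.
#'
#' @param epochs A preprocessed [epoch_array()] (band-passed and
#'   time-domain baseline corrected).
#' @param trials The matching `trial_table`.
#' @param rois ROI set (default [default_rois()]).
#' @param tfd Optional precomputed baseline-corrected `tfd` at the TF
#'   ROIs' channel; computed internally when `NULL`.
#' @param window_s,step_s WFT parameters used when computing internally.
#' @param baseline_s Spectral baseline window in s.
#' @param peak_lowpass_hz Corner of the zero-phase low-pass applied to
#'   waveforms before peak measurement (default 30 Hz; `NULL` disables),
#'   so gamma-band activity and residual noise do not bias the extremum
#'   search.
#' @return A `feature_table` data frame aligned with `trials`: subject,
#'   trial, energy, rating, the six magnitudes, and N1/N2/P2 latencies.
#' @export
extract_feature_table <- function(epochs, trials, rois = default_rois(),
                                  tfd = NULL, window_s = 0.25,
                                  step_s = 0.01,
                                  baseline_s = c(-0.4, -0.1),
                                  peak_lowpass_hz = 30) {
  d <- dim(epochs$data)
  if (nrow(trials) != d[1] * d[2])
    stop("trial table does not match epoch dimensions", call. = FALSE)
  tt <- epoch_times(epochs)
  out <- data.frame(subject = trials$subject, trial = trials$trial,
                    energy = trials$energy_level, rating = trials$rating)
  time_rois <- Filter(function(r) r$domain == "time", rois)
  tf_rois <- Filter(function(r) r$domain == "tf", rois)

  for (roi in time_rois) {
    sig <- rereference(epochs, roi$channel, roi$reference)
    if (!is.null(peak_lowpass_hz)) sig <- lowpass_signal(sig, peak_lowpass_hz)
    sel <- which(tt >= roi$time_window[1] & tt <= roi$time_window[2])
    amp <- matrix(NA_real_, d[1], d[2])
    lat <- matrix(NA_real_, d[1], d[2])
    for (s in seq_len(d[1])) {
      w <- matrix(sig[s, , sel], nrow = d[2])
      i <- if (roi$direction == "negative") max.col(-w, "first")
           else max.col(w, "first")
      amp[s, ] <- w[cbind(seq_len(d[2]), i)]
      lat[s, ] <- tt[sel][i]
    }
    out[[roi$name]] <- as.vector(t(amp))       # subject-major row order
    out[[paste0("lat_", roi$name)]] <- as.vector(t(lat))
  }

  if (length(tf_rois)) {
    if (is.null(tfd)) {
      ch <- unique(vapply(tf_rois, function(r) r$channel, character(1)))
      if (length(ch) != 1)
        stop("all tf ROIs must share one channel for internal TFD",
             call. = FALSE)
      freqs <- sort(unique(unlist(lapply(tf_rois, function(r)
        seq(ceiling(r$freq_window[1]), floor(r$freq_window[2]))))))
      tlo <- min(vapply(tf_rois, function(r) r$time_window[1], numeric(1)))
      thi <- max(vapply(tf_rois, function(r) r$time_window[2], numeric(1)))
      grid <- seq(ceiling(min(baseline_s[1], tlo) / step_s),
                  floor(max(baseline_s[2], thi) / step_s)) * step_s
      # keep only centres whose analysis window fits inside the epoch
      half_s <- round(window_s * epochs$sfreq / 2) / epochs$sfreq
      grid <- grid[grid >= tt[1] + half_s - 1e-9 &
                   grid <= tt[length(tt)] - half_s + 1e-9]
      tfd <- wft_tfd(epochs, ch, window_s = window_s, step_s = step_s,
                     freqs = freqs, times = grid)
      tfd <- tfd_baseline_correct(tfd, baseline_s)
    }
    for (roi in tf_rois) {
      m <- tfroi_magnitude(tfd, roi)
      out[[roi$name]] <- as.vector(t(m))
    }
  }
  # order columns: ids, magnitudes, latencies
  mags <- names(rois)
  lats <- paste0("lat_", names(time_rois))
  out <- out[, c("subject", "trial", "energy", "rating",
                 intersect(mags, names(out)), intersect(lats, names(out)))]
  class(out) <- c("feature_table", "data.frame")
  out
}
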