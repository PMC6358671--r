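# Reduced cohorts for unit tests: fewer subjects/trials and a 250 Hz
# sampling rate (all analysis windows and ROIs stay valid; the gamma
# burst at 72 Hz is far below the 125 Hz Nyquist).
small_config <- function(n_subjects = 6, n_trials_per_energy = 5,
                         sfreq = 250, seed = 1, scenario = "dissociation", ...) {
  args <- list(...)
  if (is.null(args$feature_specs))
    args$feature_specs <- default_feature_specs(scenario)
  do.call(synth_config,
          c(list(n_subjects = n_subjects,
                 n_trials_per_energy = n_trials_per_energy,
                 sfreq = sfreq, seed = seed), args))
}

# noiseless rating model: rating == energy level exactly
det_rating_model <- function() {
  list(intercept_mean = 0, intercept_sd = 0,
       slope_mean = 1, slope_sd = 0, noise_sd = 0)
}

# build a tfd object directly from a power array (unit-test fixture)
make_tfd <- function(power, freqs, times, state = "percent",
                     kind = "total") {
  structure(list(power = power, freqs_hz = as.numeric(freqs),
                 times_s = as.numeric(times), window_s = 0.25,
                 sfreq = 1000, channel = "Cz", baseline_state = state,
                 kind = kind, convention = "test"),
            class = "tfd")
}

# single-trial epoch_array from a plain vector/matrix of traces
make_epochs <- function(traces, sfreq = 1000, t0 = -0.5,
                        channels = "Cz") {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  n <- ncol(traces)
  a <- array(NA_real_, dim = c(1, nrow(traces), length(channels), n))
  for (ch in seq_along(channels)) a[1, , ch, ] <- traces
  epoch_array(a, sfreq, t0, channels)
}
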