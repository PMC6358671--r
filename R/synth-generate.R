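#' Generate single-trial intensity ratings for a synthetic cohort
#'
#' Draws per-subject rating intercepts and slopes, pseudorandomises the
#' stimulus-energy order within each subject, and produces single-trial
#' ratings `clip(b_i + s_i * level + eps, bounds)` where `level` is the
#' stimulus energy rank (1-4).
#'
#' @param config A [synth_config()].
#' @return A `trial_table` data frame with columns subject, trial,
#'   energy_level, energy_j, rating.
#' @export
generate_ratings <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  draw_ratings(config)
}

# Draws from the current RNG stream (no reseeding); shared by
# generate_ratings() and generate_cohort() so both emit identical tables
# for the same seed.
draw_ratings <- function(config) {
  ns <- config$n_subjects
  npe <- config$n_trials_per_energy
  ne <- length(config$energy_joules)
  nt <- npe * ne
  rm <- config$rating_model
  b <- stats::rnorm(ns, rm$intercept_mean, rm$intercept_sd)
  s <- stats::rnorm(ns, rm$slope_mean, rm$slope_sd)
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    levels_i <- sample(rep(seq_len(ne), npe))   # pseudorandom energy order
    eps <- stats::rnorm(nt, 0, rm$noise_sd)
    rating <- pmin(pmax(b[i] + s[i] * levels_i + eps, rm$bounds[1]),
                   rm$bounds[2])
    if (!is.null(rm$round_step))
      rating <- round(rating / rm$round_step) * rm$round_step
    rows[[i]] <- data.frame(subject = i, trial = seq_len(nt),
                            energy_level = levels_i,
                            energy_j = config$energy_joules[levels_i],
                            rating = rating)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("trial_table", "data.frame")
  attr(tab, "subject_params") <- data.frame(subject = seq_len(ns),
                                            intercept = b, slope = s)
  tab
}

#' Single-channel waveform of one response component
#'
#' Transient components are Gaussian-enveloped. Non-oscillatory peaks
#' (N1/N2/P2) are `amplitude * polarity * exp(-(t - latency)^2 / (2 width^2))`;
#' oscillatory components (low-frequency LEP, gamma burst) additionally
#' carry a cosine at the component frequency,
#' `amplitude * envelope * cos(2 pi f (t - latency) + phase)`. The waveform
#' is identically zero outside +/- 4 envelope widths of the latency. For
#' the multiplicative alpha-suppression component ("erd" kind) the return
#' value is the gate `1 - depth * envelope` to be multiplied into the
#' ongoing alpha process (1 outside the envelope support).
#'
#' @param spec A `feature_spec` (see [default_feature_specs()]).
#' @param times Numeric vector of sample times in s.
#' @param amplitude Component amplitude (uV), or suppression depth in
#'   `[0, 1]` for "erd".
#' @param phase Oscillation phase in radians (0 for phase-locked features).
#' @return Numeric waveform, same length as `times`.
#' @export
component_waveform <- function(spec, times, amplitude, phase = 0) {
  if (spec$width <= 0)
    stop(sprintf("invalid feature_spec '%s': width must be > 0", spec$name),
         call. = FALSE)
  dt <- times - spec$latency
  env <- exp(-dt^2 / (2 * spec$width^2))
  env[abs(dt) > 4 * spec$width] <- 0
  switch(spec$kind,
    peak = amplitude * spec$polarity * env,
    oscillation = amplitude * env * cos(2 * pi * spec$freq * dt + phase),
    erd = 1 - pmin(pmax(amplitude, 0), 1) * env,
    stop(sprintf("unknown component kind '%s'", spec$kind), call. = FALSE))
}

# 1/f ("pink") noise by spectral amplitude shaping of white Gaussian
# noise; independent per call. Returns a matrix n x m (m traces).
pink_noise <- function(n, m, sd) {
  if (sd == 0) return(matrix(0, n, m))
  white <- matrix(stats::rnorm(n * m), n, m)
  spec <- stats::mvfft(white)
  f <- c(1, seq_len(n - 1))                   # DC unscaled, else 1/sqrt(f)
  f <- pmin(f, n - f + 1)                     # symmetric (two-sided grid)
  spec <- spec / sqrt(f)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/") * sd
  x
}

#' Generate a full synthetic cohort of epochs, ratings and ground truth
#'
#' For every trial, each response feature receives a latent amplitude
#' `baseline + u_i + kappa_w * (rating - mean_i(rating)) +
#' kappa_b * mean_i(rating) + noise`, where `u_i` is a per-subject trait
#' offset (sd `subject_sd`). Channel signals are the topography-weighted
#' sum of the component waveforms plus 1/f background noise and an ongoing
#' 10 Hz alpha oscillation; the alpha-ERD feature acts multiplicatively on
#' the alpha process. EOG channels receive no gamma component. The whole
#' cohort is bit-reproducible from (config, seed).
#'
#' @param config A [synth_config()].
#' @return List with elements `epochs` ([epoch_array()]), `trials`
#'   (`trial_table`) and `manifest` (ground-truth subject parameters,
#'   latent per-trial feature amplitudes and the couplings used).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  trials <- draw_ratings(config)
  ns <- config$n_subjects
  nt <- config$n_trials_per_energy * length(config$energy_joules)
  chs <- config$channel_names
  nc <- length(chs)
  n <- round((config$epoch_window[2] - config$epoch_window[1]) * config$sfreq)
  times <- config$epoch_window[1] + (seq_len(n) - 1L) / config$sfreq
  specs <- config$feature_specs
  nf <- length(specs)
  eog <- grepl("^EOG", chs)

  data <- array(0, dim = c(ns, nt, nc, n))
  amp_store <- array(NA_real_, dim = c(ns, nt, nf),
                     dimnames = list(NULL, NULL, names(specs)))
  subj_offsets <- matrix(stats::rnorm(ns * nf, 0, 1), ns, nf,
                         dimnames = list(NULL, names(specs)))
  for (k in seq_len(nf)) subj_offsets[, k] <- subj_offsets[, k] * specs[[k]]$subject_sd

  # precompute topography weight per feature x channel (0 where unnamed)
  topo <- matrix(0, nf, nc, dimnames = list(names(specs), chs))
  for (k in seq_len(nf)) {
    w <- specs[[k]]$topography
    keep <- intersect(names(w), chs)
    topo[k, keep] <- w[keep]
    if (specs[[k]]$name == "gERS") topo[k, eog] <- 0  # no ocular gamma
  }

  # fixed per-feature basis waveforms (amplitude/phase enter linearly):
  # peak: shape; oscillation: cos/sin pair under the envelope; erd: envelope
  basis <- lapply(specs, function(sp) {
    dt <- times - sp$latency
    env <- exp(-dt^2 / (2 * sp$width^2))
    env[abs(dt) > 4 * sp$width] <- 0
    switch(sp$kind,
      peak = list(w = sp$polarity * env),
      oscillation = list(w = env * cos(2 * pi * sp$freq * dt),
                         v = env * sin(2 * pi * sp$freq * dt)),
      erd = list(env = env))
  })
  c10 <- cos(2 * pi * 10 * times)
  s10 <- sin(2 * pi * 10 * times)
  alpha_amp <- config$noise_model$alpha_amplitude
  erd_k <- which(vapply(specs, function(sp) sp$kind == "erd", logical(1)))

  for (i in seq_len(ns)) {
    ri <- trials$rating[trials$subject == i]
    rbar <- mean(ri)
    # latent amplitudes and phases, all trials at once (nf x nt)
    amps <- matrix(NA_real_, nf, nt)
    phases <- matrix(0, nf, nt)
    for (k in seq_len(nf)) {
      sp <- specs[[k]]
      a <- sp$baseline + subj_offsets[i, k] +
        sp$kappa_w * (ri - rbar) + sp$kappa_b * rbar +
        stats::rnorm(nt, 0, sp$noise_sd)
      a <- pmax(a, 0)
      if (sp$kind == "erd") a <- pmin(a, 1)
      amps[k, ] <- a
      if (!sp$phase_locked) phases[k, ] <- stats::runif(nt, 0, 2 * pi)
    }
    amp_store[i, , ] <- t(amps)
    # additive feature contributions, n x nt, shared across channels
    contrib <- vector("list", nf)
    for (k in seq_len(nf)) {
      sp <- specs[[k]]
      if (sp$kind == "erd") next
      if (sp$kind == "peak") {
        contrib[[k]] <- basis[[k]]$w %o% amps[k, ]
      } else {
        contrib[[k]] <- basis[[k]]$w %o% (amps[k, ] * cos(phases[k, ])) -
          basis[[k]]$v %o% (amps[k, ] * sin(phases[k, ]))
      }
    }
    pink <- pink_noise(n, nt * nc, config$noise_model$pink_sd)
    alpha_phase <- matrix(stats::runif(nt * nc, 0, 2 * pi), nt, nc)
    for (c in seq_len(nc)) {
      sig <- matrix(0, n, nt)
      for (k in seq_len(nf)) {
        if (specs[[k]]$kind == "erd" || topo[k, c] == 0) next
        sig <- sig + topo[k, c] * contrib[[k]]
      }
      # ongoing alpha with per-trial phase, gated by the ERD envelope
      alpha <- c10 %o% (alpha_amp * cos(alpha_phase[, c])) -
        s10 %o% (alpha_amp * sin(alpha_phase[, c]))
      if (length(erd_k)) {
        w_erd <- topo[erd_k[1], c]
        if (w_erd != 0)
          alpha <- alpha * (1 - (w_erd * basis[[erd_k[1]]]$env) %o%
                              amps[erd_k[1], ])
      }
      j <- (seq_len(nt) - 1) * nc + c
      data[i, , c, ] <- t(sig + alpha + pink[, j, drop = FALSE])
    }
  }

  epochs <- epoch_array(data, config$sfreq, config$epoch_window[1], chs,
                        log = "simulate")
  manifest <- list(
    subject_params = cbind(attr(trials, "subject_params"),
                           mean_rating = tapply(trials$rating, trials$subject, mean)),
    latent_amplitudes = amp_store,
    subject_offsets = subj_offsets,
    kappa_w = vapply(specs, function(f) f$kappa_w, numeric(1)),
    kappa_b = vapply(specs, function(f) f$kappa_b, numeric(1)),
    seed = config$seed
  )
  list(epochs = epochs, trials = trials, manifest = manifest)
}
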