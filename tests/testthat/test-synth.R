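test_that("configuration invariants are enforced with named errors", {
  expect_error(synth_config(energy_joules = c(4, 3.5, 3, 2.5)),
               "energy_joules")
  expect_error(synth_config(rating_model = list(noise_sd = -1)),
               "noise_sd")
  expect_error(synth_config(channel_names = c("Fz", "Cz", "EOG1", "EOG2")),
               "C4")
  expect_error(synth_config(channel_names = c("Fz", "Cz", "C4", "EOG1")),
               "EOG")
  expect_error(synth_config(epoch_window = c(-0.2, 1)), "epoch_window")
  fs <- default_feature_specs()
  fs$N1$width <- -1
  expect_error(synth_config(feature_specs = fs), "width")
})

test_that("configuration round-trips through YAML", {
  cfg <- small_config(seed = 42)
  path <- tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back, cfg)
  # and the round-tripped config generates identical data
  expect_identical(generate_ratings(back), generate_ratings(cfg))
})

test_that("noise-free linear rating model gives exact ratings", {
  cfg <- small_config(n_subjects = 3, rating_model = det_rating_model())
  tab <- generate_ratings(cfg)
  expect_equal(tab$rating[tab$energy_level == 1], rep(1, 15))
  expect_equal(tab$rating[tab$energy_level == 4], rep(4, 15))
  # energies balanced per subject
  expect_true(all(table(tab$subject, tab$energy_level) == 5))
})

test_that("generation is deterministic given the seed", {
  cfg <- small_config(n_subjects = 3, seed = 9)
  expect_identical(generate_ratings(cfg), generate_ratings(cfg))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$trials, b$trials)
  expect_identical(a$manifest, b$manifest)
  # the trial table inside the cohort equals the standalone one
  expect_identical(a$trials, generate_ratings(cfg))
  # a different seed changes the data
  cfg2 <- small_config(n_subjects = 3, seed = 10)
  expect_false(identical(generate_cohort(cfg2)$epochs$data, a$epochs$data))
})

test_that("default rating model couples ratings to energy in nearly all subjects", {
  frac <- sapply(1:20, function(seed) {
    tab <- generate_ratings(synth_config(seed = seed))
    r <- sapply(split(tab, tab$subject),
                function(d) cor(d$rating, d$energy_level))
    mean(r > 0)
  })
  expect_gte(mean(frac), 0.95)
})

test_that("ratings always stay inside the scale bounds", {
  for (seed in 1:5) {
    tab <- generate_ratings(synth_config(seed = seed))
    expect_true(all(tab$rating >= 0 & tab$rating <= 10))
  }
})

test_that("component waveforms follow their construction", {
  tt <- seq(-0.5, 1, by = 1e-3)
  g <- default_feature_specs()$gERS
  g$freq <- 75; g$latency <- 0.22; g$width <- 0.03
  expect_equal(component_waveform(g, tt, amplitude = 0), rep(0, length(tt)))
  w <- component_waveform(g, tt, amplitude = 1, phase = 0)
  expect_equal(tt[which.max(abs(w))], 0.22, tolerance = 1e-9)
  # zero crossings spaced 1/150 s near the centre (75 Hz oscillation)
  zc <- tt[which(diff(sign(w[tt > 0.19 & tt < 0.25])) != 0)]
  expect_equal(mean(diff(zc)), 1 / 150, tolerance = 0.05)
  # zero outside +/- 4 widths
  expect_true(all(w[abs(tt - 0.22) > 4 * g$width] == 0))
  # peaks: polarity and envelope shape
  n2 <- default_feature_specs()$N2
  w2 <- component_waveform(n2, tt, amplitude = 3)
  expect_equal(min(w2), -3, tolerance = 1e-6)
  n2bad <- n2; n2bad$width <- 0
  expect_error(component_waveform(n2bad, tt, 1), "width")
})

test_that("oscillation energy matches the closed-form Gaussian-envelope integral", {
  # for width >> 1/f: integral of a^2 env^2 cos^2 = a^2 sigma sqrt(pi) / 2
  tt <- seq(-2, 2, by = 1e-4)
  sp <- default_feature_specs()$gERS
  sp$latency <- 0; sp$width <- 0.1; sp$freq <- 40
  w <- component_waveform(sp, tt, amplitude = 1.7, phase = 0)
  num <- sum(w^2) * 1e-4
  closed <- 1.7^2 * sp$width * sqrt(pi) / 2
  expect_equal(num, closed, tolerance = 0.01)
})

test_that("the ERD component is a multiplicative gate in [0, 1]", {
  tt <- seq(-0.5, 1, by = 5e-3)   # grid contains the 0.75 s latency
  sp <- default_feature_specs()$aERD
  g <- component_waveform(sp, tt, amplitude = 0.7)
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(min(g), 0.3, tolerance = 1e-6)
  expect_true(all(g[abs(tt - sp$latency) > 4 * sp$width] == 1))
  # depth is clipped into [0, 1]
  expect_true(all(component_waveform(sp, tt, amplitude = 5) >= 0))
})

test_that("cohorts have consistent shapes and ground truth", {
  cfg <- small_config(n_subjects = 4, seed = 2)
  out <- generate_cohort(cfg)
  expect_identical(dim(out$epochs$data), c(4L, 20L, 5L, 375L))
  expect_equal(nrow(out$trials), 4 * 20)
  expect_identical(dim(out$manifest$latent_amplitudes), c(4L, 20L, 6L))
  expect_equal(nrow(out$manifest$subject_params), 4)
  # dissociation scenario: exactly one trait-coupled feature, gamma
  kb <- out$manifest$kappa_b
  expect_identical(names(kb)[kb != 0], "gERS")
})

test_that("a 64-channel montage generates the full-rate epoch shape", {
  chans <- c("Fz", "Cz", "C4", sprintf("X%02d", 1:59), "EOG1", "EOG2")
  cfg <- synth_config(n_subjects = 2, channel_names = chans, seed = 5)
  out <- generate_cohort(cfg)
  expect_identical(dim(out$epochs$data), c(2L, 40L, 64L, 1500L))
})

test_that("EOG channels carry no gamma component", {
  fs <- default_feature_specs()
  for (nm in names(fs)) {
    fs[[nm]]$baseline <- 0; fs[[nm]]$noise_sd <- 0
    fs[[nm]]$subject_sd <- 0; fs[[nm]]$kappa_w <- 0; fs[[nm]]$kappa_b <- 0
  }
  fs$gERS$baseline <- 2
  fs$gERS$topography <- c(Fz = 0.5, Cz = 1, C4 = 0.7, EOG1 = 0.9, EOG2 = 0.9)
  cfg <- small_config(n_subjects = 1, n_trials_per_energy = 1,
                      feature_specs = fs,
                      noise_model = list(pink_sd = 0, alpha_amplitude = 0))
  out <- generate_cohort(cfg)
  eog <- grepl("^EOG", out$epochs$channel_names)
  expect_true(all(out$epochs$data[, , eog, ] == 0))
  expect_gt(max(abs(out$epochs$data[, , !eog, ])), 0)
})
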