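test_that("median splits halve the sample with the documented tie rules", {
  set.seed(24)
  lab96 <- median_split(rnorm(96))
  expect_equal(as.vector(table(lab96)), c(48, 48))
  lab40 <- median_split(rnorm(40))
  expect_equal(as.vector(table(lab40)), c(20, 20))
  lab5 <- median_split(c(3, 1, 4, 1, 5))
  expect_equal(as.vector(table(lab5)), c(2, 3))
  # invariance to strictly increasing transforms
  x <- rnorm(30)
  expect_identical(median_split(x), median_split(exp(x)))
  expect_identical(median_split(x), median_split(rank(x)))
  # degenerate input still splits, deterministically, with a warning
  expect_warning(labc <- median_split(rep(2, 6)), "identical")
  expect_equal(as.vector(table(labc)), c(3, 3))
  expect_identical(labc, suppressWarnings(median_split(rep(2, 6))))
  expect_error(median_split(1), "at least 2")
})

test_that("split assignments are balanced at both levels", {
  trials <- generate_ratings(synth_config(seed = 31))
  sp <- split_assignment(trials)
  expect_equal(as.vector(sp$n_subjects), c(48, 48))
  expect_equal(as.vector(sp$n_trials), c(20, 20))
  # labels derive only from ratings: every low-trial rating within a
  # subject is <= every high-trial rating
  for (s in sample(unique(trials$subject), 5)) {
    i <- trials$subject == s
    expect_lte(max(trials$rating[i & sp$trial_label == "low"]),
               min(trials$rating[i & sp$trial_label == "high"]))
  }
})

test_that("2x2 mixed ANOVA matches the sums-of-squares oracle", {
  set.seed(25)
  for (rep in 1:25) {
    n <- sample(c(8, 12, 20), 1)
    y <- matrix(rnorm(2 * n), n, 2)
    if (rep %% 3 == 0) y[, 2] <- y[, 2] + 1          # trial effect
    if (rep %% 4 == 0) y[1:(n / 2), ] <- y[1:(n / 2), ] + 1  # group effect
    group <- rep(c("low", "high"), each = n / 2)
    ft <- data.frame(subject = rep(seq_len(n), each = 2),
                     rating = NA,
                     m = as.vector(t(y)))
    sp <- list(subject_label = factor(setNames(group, seq_len(n)),
                                      levels = c("low", "high")),
               trial_label = factor(rep(c("low", "high"), n),
                                    levels = c("low", "high")))
    class(sp) <- "split_assignment"
    got <- mixed_anova_2way(ft, sp, "m")
    want <- mixed2_ss_oracle(y, group)
    expect_equal(got$F[got$effect == "subject_category"], want$group$F)
    expect_equal(got$F[got$effect == "trial_category"], want$trial$F)
    expect_equal(got$F[got$effect == "interaction"], want$interaction$F)
    # partial eta^2 equals SS_effect / (SS_effect + SS_error), recomputed
    expect_equal(got$peta2[got$effect == "trial_category"],
                 want$trial$ss / (want$trial$ss + want$trial$ss_err))
    expect_true(all(got$peta2 >= 0 & got$peta2 <= 1))
  }
})

test_that("degenerate and single-effect designs behave as specified", {
  n <- 10
  ft <- data.frame(subject = rep(1:n, each = 2), rating = NA, m = 5)
  sp <- list(subject_label = factor(setNames(rep(c("low", "high"), each = n / 2),
                                             1:n), levels = c("low", "high")),
             trial_label = factor(rep(c("low", "high"), n),
                                  levels = c("low", "high")))
  class(sp) <- "split_assignment"
  got <- mixed_anova_2way(ft, sp, "m")
  expect_true(all(got$F == 0))
  expect_true(all(got$p == 1))
  # pure trial effect: subject F ~ 0, trial F large
  set.seed(26)
  y <- matrix(rnorm(2 * n, sd = 0.1), n, 2)
  y[, 2] <- y[, 2] + 3
  ft$m <- as.vector(t(y))
  got2 <- mixed_anova_2way(ft, sp, "m")
  expect_gt(got2$F[got2$effect == "trial_category"], 100)
  expect_lt(got2$F[got2$effect == "subject_category"], 5)
  # identity: the within-factor F equals the squared paired t when the
  # between factor is absorbed (single-group design)
  sp1 <- sp; sp1$subject_label[] <- "low"
  fit <- stats::aov(y ~ trialcat + Error(subject / trialcat),
                    data = painvar:::.cell_means(ft, sp1, "m"))
  f_trial <- summary(fit)[[2]][[1]]["trialcat", "F value"]
  tt <- t.test(y[, 2] - y[, 1])$statistic
  expect_equal(f_trial, unname(tt)^2, tolerance = 1e-10)
})

test_that("z-scoring standardises cell means and is affine invariant", {
  cf <- cohort_features(small_config(n_subjects = 8, seed = 27),
                        filter = FALSE)
  sp <- split_assignment(cf$trials)
  z <- zscore_features(cf$features, sp)
  for (f in levels(z$feature)) {
    expect_equal(mean(z$y[z$feature == f]), 0, tolerance = 1e-10)
    expect_equal(sd(z$y[z$feature == f]), 1, tolerance = 1e-10)
  }
  # affine transform of a feature leaves its z-scores unchanged
  ft2 <- cf$features
  ft2$LEP <- 3 * ft2$LEP + 100
  z2 <- zscore_features(ft2, sp)
  expect_equal(z2$y[z2$feature == "LEP"], z$y[z$feature == "LEP"])
  # small worked example
  ftc <- data.frame(subject = rep(1:2, each = 2), rating = NA,
                    m = c(1, 2, 3, 6))
  spc <- list(subject_label = factor(setNames(c("low", "high"), 1:2),
                                     levels = c("low", "high")),
              trial_label = factor(rep(c("low", "high"), 2),
                                   levels = c("low", "high")))
  class(spc) <- "split_assignment"
  zc <- zscore_features(ftc, spc, "m")
  expect_equal(zc$y, (c(1, 2, 3, 6) - 3) / sd(c(1, 2, 3, 6)))
  ftc$m <- 1
  expect_error(zscore_features(ftc, spc, "m"), "degenerate")
})

test_that("3-way mixed ANOVA matches a first-principles SS decomposition", {
  # balanced toy design with known structure
  set.seed(28)
  n <- 12
  group <- rep(c("low", "high"), each = n / 2)
  cells <- expand.grid(trialcat = c("low", "high"),
                       feature = c("LEP", "aERD", "gERS"))
  rows <- list()
  for (s in seq_len(n)) for (j in seq_len(nrow(cells))) {
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, group = group[s], trialcat = cells$trialcat[j],
      feature = cells$feature[j],
      y = rnorm(1) + (cells$trialcat[j] == "high") * 0.8 +
        (group[s] == "high") * (cells$feature[j] == "gERS") * 2.5)
  }
  zf <- do.call(rbind, rows)
  zf$group <- factor(zf$group, levels = c("low", "high"))
  zf$trialcat <- factor(zf$trialcat, levels = c("low", "high"))
  zf$feature <- factor(zf$feature, levels = c("LEP", "aERD", "gERS"))
  got <- mixed_anova_3way(zf)

  # independent oracle: stratum-wise sums of squares from cell means
  Y <- tapply(zf$y, list(zf$subject, interaction(zf$trialcat, zf$feature)),
              mean)
  gm <- mean(Y)
  subj_mean <- rowMeans(Y)
  ss_group <- 6 * sum(sapply(split(subj_mean, group), function(v)
    length(v) * (mean(v) - gm)^2))
  ss_subj <- 6 * sum((subj_mean - gm)^2)
  f_group <- (ss_group / 1) / ((ss_subj - ss_group) / (n - 2))
  expect_equal(got$F[got$effect == "subject_category"], f_group,
               tolerance = 1e-8)

  # trial-category stratum
  tc_mean <- tapply(zf$y, list(zf$subject, zf$trialcat), mean)
  d <- tc_mean[, "high"] - tc_mean[, "low"]   # per-subject within diff
  ss_trial <- 3 * sum(2 * (tapply(zf$y, zf$trialcat, mean) - gm)^2) * n / 2
  gd <- sapply(split(d, group), mean)
  ss_gt <- 3 * sum(sapply(split(d, group), length) * (gd - mean(d))^2) / 2
  ss_err_t <- 3 * (sum((d - ave(d, group))^2)) / 2
  f_trial <- ss_trial / (ss_err_t / (n - 2))
  f_gt <- ss_gt / (ss_err_t / (n - 2))
  expect_equal(got$F[got$effect == "trial_category"], f_trial,
               tolerance = 1e-8)
  expect_equal(got$F[got$effect == "subject_x_trial"], f_gt,
               tolerance = 1e-8)

  # effect sizes and GG corrections are well-formed
  expect_true(all(got$peta2 >= 0 & got$peta2 <= 1))
  expect_true(all(got$gg_epsilon >= 0.5 - 1e-9 & got$gg_epsilon <= 1 + 1e-9))
  # two-level within effects are exact: no correction applied
  two_level <- got$effect %in% c("subject_category", "trial_category",
                                 "subject_x_trial")
  expect_equal(got$p_gg[two_level], got$p[two_level])
  expect_true(all(got$gg_epsilon[!two_level] < 1 + 1e-9))
  # the planted subject x feature interaction is detected
  expect_lt(got$p[got$effect == "subject_x_feature"], 0.01)
  ph <- attr(got, "posthoc")
  expect_equal(as.character(ph$feature), c("LEP", "aERD", "gERS"))
  expect_lt(ph$p[ph$feature == "gERS"], 0.05)
  expect_true(all(ph$peta2 >= 0 & ph$peta2 <= 1))
})

test_that("null feature tables give uniform ANOVA p values", {
  set.seed(29)
  ps <- replicate(120, {
    n <- 16
    ft <- data.frame(subject = rep(1:n, each = 4),
                     rating = rnorm(4 * n), m = rnorm(4 * n))
    sp <- split_assignment(cbind(ft, trial = rep(1:4, n),
                                 energy_level = 1)[, c("subject", "trial",
                                                       "energy_level",
                                                       "rating")])
    got <- mixed_anova_2way(ft, sp, "m")
    got$p[got$effect == "subject_category"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
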