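# minimal trial table for map-level tests
fake_trials <- function(ns, nt, ratings) {
  data.frame(subject = rep(seq_len(ns), each = nt),
             trial = rep(seq_len(nt), ns), rating = ratings)
}

test_that("per-subject correlations match the textbook formula", {
  set.seed(13)
  ft <- data.frame(subject = rep(1:4, each = 40),
                   rating = rnorm(160), m = rnorm(160))
  r <- within_subject_correlation(ft, "m")
  for (s in 1:4) {
    d <- ft[ft$subject == s, ]
    num <- sum((d$m - mean(d$m)) * (d$rating - mean(d$rating)))
    den <- sqrt(sum((d$m - mean(d$m))^2) * sum((d$rating - mean(d$rating))^2))
    expect_equal(unname(r[s]), num / den)
  }
  # magnitudes equal to ratings give r = 1 everywhere
  ft$m <- ft$rating
  expect_equal(unname(within_subject_correlation(ft, "m")), rep(1, 4))
  # degenerate subjects are excluded with a warning
  ft$m[ft$subject == 2] <- 5
  expect_warning(r2 <- within_subject_correlation(ft, "m"), "degenerate")
  expect_true(is.na(r2[2]) && !anyNA(r2[-2]))
})

test_that("Fisher transform is atanh with a clipping policy", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  expect_equal(tanh(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_error(fisher_z(1), "clip")
  expect_lt(abs(clip_r(1) - 1), 2e-12)
  expect_true(is.finite(fisher_z(clip_r(1))))
})

test_that("group-level z test is a one-sample t against zero", {
  g <- group_level_test(c(-0.3, 0.3, -0.1, 0.1))
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)
  z <- c(0.1, 0.2, 0.3, 0.4)
  g2 <- group_level_test(z)
  expect_equal(g2$t, mean(z) / (sd(z) / 2))
  expect_equal(g2$df, 3)
  expect_equal(g2$p, 2 * pt(-abs(g2$t), 3))
  expect_error(group_level_test(rep(0.2, 5)), "degenerate")
  expect_error(group_level_test(0.5), "at least 2")
})

test_that("group-level p values are uniform under the null", {
  set.seed(14)
  ps <- replicate(500, group_level_test(rnorm(96, 0, 0.2))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("between-subject correlation uses subject means", {
  set.seed(15)
  ft <- data.frame(subject = rep(1:20, each = 10),
                   rating = rnorm(200), m = rnorm(200))
  my <- tapply(ft$rating, ft$subject, mean)
  ft$m <- rep(my, each = 10)   # subject-mean magnitude equals mean rating
  b <- between_subject_correlation(ft, "m")
  expect_equal(b$r, 1)
  expect_equal(b$n, 20)
  ft$m <- 3
  expect_error(between_subject_correlation(ft, "m"), "degenerate")
})

test_that("BH adjustment equals step-up enumeration", {
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.031), 0.031)
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(fdr_adjust(p), bh_stepup_oracle(p))
  set.seed(16)
  for (i in 1:1000) {
    p <- runif(sample(2:12, 1))
    expect_equal(fdr_adjust(p), bh_stepup_oracle(p))
  }
  p <- runif(30)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.2, 1.7)), "p values")
})

test_that("pointwise maps recover injected state and trait coupling", {
  set.seed(17)
  ns <- 14; nt <- 24; nf <- 6; nti <- 8
  ratings <- rnorm(ns * nt, 5, 1.5)
  tr <- fake_trials(ns, nt, ratings)
  p <- array(rnorm(ns * nt * nf * nti), dim = c(ns, nt, nf, nti))
  # state coupling at (3, 4); trait coupling at (5, 2)
  rc <- ratings - ave(ratings, tr$subject)
  p[, , 3, 4] <- p[, , 3, 4] + matrix(0.9 * rc, ns, nt, byrow = TRUE)
  my <- tapply(ratings, tr$subject, mean)
  p[, , 5, 2] <- p[, , 5, 2] + matrix(rep(2 * my, nt), ns, nt)
  tf <- make_tfd(p, freqs = 1:nf, times = seq(0.1, 0.8, length.out = nti))
  maps <- pointwise_tf_maps(tf, tr)
  expect_identical(dim(maps$t_map), as.integer(c(nf, nti)))
  expect_identical(dim(maps$r_map), as.integer(c(nf, nti)))
  expect_equal(which(maps$t_map == max(maps$t_map), arr.ind = TRUE)[1, ],
               c(row = 3L, col = 4L))
  expect_equal(which(maps$r_map == max(maps$r_map), arr.ind = TRUE)[1, ],
               c(row = 5L, col = 2L))
})

test_that("cluster permutation test finds injected clusters and is calibrated in form", {
  set.seed(18)
  ns <- 10; nt <- 20; nf <- 8; nti <- 10
  ratings <- rnorm(ns * nt, 5, 1.5)
  tr <- fake_trials(ns, nt, ratings)
  p <- array(rnorm(ns * nt * nf * nti), dim = c(ns, nt, nf, nti))
  rc <- ratings - ave(ratings, tr$subject)
  for (f in 3:5) for (ti in 4:6)
    p[, , f, ti] <- p[, , f, ti] + matrix(1.2 * rc, ns, nt, byrow = TRUE)
  tf <- make_tfd(p, freqs = 1:nf, times = seq(0, 0.9, length.out = nti))
  maps <- pointwise_tf_maps(tf, tr)
  cl <- cluster_permutation_test(maps, tf, tr, "within", n_perm = 999,
                                 seed = 1)
  expect_gt(nrow(cl$clusters), 0)
  top <- cl$clusters[1, ]
  # the dominant cluster covers the injected block and beats every draw
  expect_equal(top$p, 1 / 1000)
  expect_true(top$f_lo <= 3 && top$f_hi >= 5)
  expect_gte(top$n_points, 9)
  # determinism under the seed
  cl2 <- cluster_permutation_test(maps, tf, tr, "within", n_perm = 999,
                                  seed = 1)
  expect_identical(cl$clusters, cl2$clusters)
  # p values never zero and never below 1/(B+1)
  expect_true(all(cl$clusters$p >= 1 / 1000))
  # a stricter cluster-forming threshold never enlarges clusters
  cl01 <- cluster_permutation_test(maps, tf, tr, "within", n_perm = 199,
                                   alpha = 0.01, seed = 2)
  expect_lte(sum(cl01$labels > 0), sum(cl$labels > 0))
  expect_true(all(which(cl01$labels > 0) %in% which(cl$labels > 0)))
  expect_error(cluster_permutation_test(maps, tf, tr, "within",
                                        n_perm = 50), "100")
  expect_identical(eval(formals(cluster_permutation_test)$n_perm), 5000)
})

test_that("between-mode permutations shuffle subject means", {
  set.seed(19)
  ns <- 16; nt <- 10; nf <- 5; nti <- 6
  ratings <- rnorm(ns * nt, 5, 1)
  tr <- fake_trials(ns, nt, ratings)
  p <- array(rnorm(ns * nt * nf * nti), dim = c(ns, nt, nf, nti))
  my <- tapply(ratings, tr$subject, mean)
  for (f in 2:3) for (ti in 2:3)
    p[, , f, ti] <- p[, , f, ti] + matrix(rep(3 * my, nt), ns, nt)
  tf <- make_tfd(p, freqs = 1:nf, times = seq(0, 0.5, length.out = nti))
  maps <- pointwise_tf_maps(tf, tr)
  cl <- cluster_permutation_test(maps, tf, tr, "between", n_perm = 499,
                                 seed = 3)
  expect_gt(nrow(cl$clusters), 0)
  expect_lt(cl$clusters$p[1], 0.05)
  # no suprathreshold points: empty cluster table, not an error
  pz <- array(0.1 * rnorm(ns * nt * nf * nti) + 5,
              dim = c(ns, nt, nf, nti))
  tfz <- make_tfd(pz, freqs = 1:nf, times = seq(0, 0.5, length.out = nti))
  mz <- pointwise_tf_maps(tfz, tr)
  mz$r_map[] <- 0
  clz <- cluster_permutation_test(mz, tfz, tr, "between", n_perm = 199,
                                  seed = 4)
  expect_equal(nrow(clz$clusters), 0)
})

test_that("connected components use 8-connectivity with sign separation", {
  stat <- matrix(0, 5, 5)
  stat[1, 1] <- 5; stat[2, 2] <- 5   # diagonal neighbours: one cluster
  stat[5, 5] <- 5                    # isolated: its own cluster
  stat[4, 1] <- -5                   # opposite sign: separate cluster
  got <- painvar:::.form_clusters(stat, 2)
  expect_equal(nrow(got$table), 3)
  expect_equal(sort(got$table$n_points), c(1, 1, 2))
  expect_equal(sum(got$table$sign == -1), 1)
  expect_equal(got$table$mass[got$table$n_points == 2], 10)
})

test_that("the feature summary pools the FDR family and flags the trait feature", {
  cf <- cohort_features(small_config(n_subjects = 12,
                                     n_trials_per_energy = 10, seed = 21),
                        filter = FALSE)
  s <- feature_correlation_summary(cf$features)
  expect_equal(nrow(s), 6)
  expect_identical(s$feature, c("N1", "N2", "P2", "LEP", "aERD", "gERS"))
  # q values are the pooled BH adjustment of all 12 p values
  q <- bh_stepup_oracle(c(s$within_p, s$between_p))
  expect_equal(s$within_q, q[1:6])
  expect_equal(s$between_q, q[7:12])
  expect_true(all(abs(s$within_r_mean) <= 1))
})
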