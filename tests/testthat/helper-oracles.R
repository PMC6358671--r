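# Independent brute-force oracles used to validate the package's
# statistics. These deliberately use naive enumeration, never the code
# paths they check.

# Benjamini-Hochberg step-up by direct enumeration
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  # step-up: running minimum from the largest p downwards
  for (i in m:1) q[i] <- min(adj[i:m], 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# ROC AUC by exhaustive pair counting
auc_pairs_oracle <- function(low, high) {
  wins <- 0
  for (h in high) for (l in low)
    wins <- wins + (h > l) + 0.5 * (h == l)
  wins / (length(low) * length(high))
}

# windowed-DFT power at one (trial, time, frequency) probe by direct sum
wft_point_oracle <- function(trace, fs, center_s, t0, f, window_s = 0.25) {
  half <- round(window_s * fs / 2)
  ci <- round((center_s - t0) * fs) + 1
  idx <- (ci - half):(ci + half)
  seg <- trace[idx]
  L <- length(seg)
  han <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  co <- sum(seg * han * exp(-2i * pi * f * (0:(L - 1)) / fs))
  Mod(co)^2
}

# full sums-of-squares decomposition of a balanced 2x2 mixed design on
# cell means: y[subject, trialcat], group[subject]
mixed2_ss_oracle <- function(y, group) {
  n <- nrow(y)
  gm <- mean(y)
  subj_mean <- rowMeans(y)
  trial_mean <- colMeans(y)
  grp <- levels(factor(group))
  ss_group <- 0; ss_trial <- 0; ss_int <- 0
  # between stratum
  for (g in grp) {
    sel <- group == g
    ss_group <- ss_group + 2 * sum(sel) * (mean(y[sel, ]) - gm)^2
  }
  ss_subj_strat <- 2 * sum((subj_mean - gm)^2)     # subjects total
  ss_err_between <- ss_subj_strat - ss_group
  # within stratum
  ss_trial <- n * sum((trial_mean - gm)^2)
  for (g in grp) for (tc in 1:2) {
    sel <- group == g
    cell <- mean(y[sel, tc])
    ss_int <- ss_int + sum(sel) *
      (cell - mean(y[sel, ]) - trial_mean[tc] + gm)^2
  }
  ss_tot <- sum((y - gm)^2)
  ss_err_within <- ss_tot - ss_subj_strat - ss_trial - ss_int
  ng <- length(grp)
  list(
    group = list(F = (ss_group / (ng - 1)) / (ss_err_between / (n - ng)),
                 ss = ss_group, ss_err = ss_err_between,
                 df = c(ng - 1, n - ng)),
    trial = list(F = (ss_trial / 1) / (ss_err_within / (n - ng)),
                 ss = ss_trial, ss_err = ss_err_within,
                 df = c(1, n - ng)),
    interaction = list(F = (ss_int / (ng - 1)) / (ss_err_within / (n - ng)),
                       ss = ss_int, ss_err = ss_err_within,
                       df = c(ng - 1, n - ng)))
}
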