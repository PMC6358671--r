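#' Pipeline run configuration
#'
#' Aggregates every stage's parameters with the conventional defaults:
#' 250-ms analysis window, 1-100 Hz in 1 Hz steps, 10-ms time step,
#' percent-change baseline -0.4 to -0.1 s, top-20% ROI fraction, 5000
#' permutations, rating cutoffs 4-7, 20 principal components, 1000 trees.
#' Stage seeds are derived from the single global seed by stable hashing
#' of the stage names (see [stage_seed()]).
#'
#' @param synth A [synth_config()] for the simulate stage.
#' @param filter List: `enabled`, `low_hz`, `high_hz`.
#' @param baseline_time Time-domain baseline window (s).
#' @param tfd List: `window_s`, `step_s`, `freq_step` (Hz; map grid),
#'   `baseline_s`.
#' @param stats List: `n_perm`, `alpha`, `run_maps` (compute the
#'   point-by-point maps and cluster tests, the slowest stage).
#' @param roc List: `cutoffs`.
#' @param prediction List: `n_components`, `n_trees`, `pca_global`.
#' @param seed Global integer seed.
#' @param verbose Emit stage messages to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       filter = list(enabled = TRUE, low_hz = 1,
                                     high_hz = 100),
                       baseline_time = c(-0.5, 0),
                       tfd = list(window_s = 0.25, step_s = 0.01,
                                  freq_step = 1, baseline_s = c(-0.4, -0.1)),
                       stats = list(n_perm = 5000, alpha = 0.05,
                                    run_maps = TRUE),
                       roc = list(cutoffs = c(4, 5, 6, 7)),
                       prediction = list(n_components = 20, n_trees = 1000,
                                         pca_global = FALSE),
                       seed = 1L, verbose = TRUE) {
  structure(list(synth = synth, filter = filter,
                 baseline_time = baseline_time, tfd = tfd, stats = stats,
                 roc = roc, prediction = prediction,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_synth_config(config$synth, tmp)
  lst$synth <- yaml::read_yaml(tmp)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(lst$synth, tmp)
  synth <- read_synth_config(tmp)
  lst$baseline_time <- as.numeric(unlist(lst$baseline_time))
  lst$tfd$baseline_s <- as.numeric(unlist(lst$tfd$baseline_s))
  lst$roc$cutoffs <- as.numeric(unlist(lst$roc$cutoffs))
  run_config(synth = synth, filter = lst$filter,
             baseline_time = lst$baseline_time, tfd = lst$tfd,
             stats = lst$stats, roc = lst$roc,
             prediction = lst$prediction, seed = lst$seed,
             verbose = isTRUE(lst$verbose))
}

#' Generate a cohort and extract its feature table in one call
#'
#' Convenience wrapper running the simulate, preprocess, time-frequency
#' and feature-extraction stages with the default ROIs. The TFD is
#' computed at Cz on the ROI frequencies only. Band-pass filtering can be
#' disabled for replicate studies on synthetic cohorts, whose background
#' noise carries no artifacts the filter would remove.
#'
#' @param config A [synth_config()].
#' @param filter Apply the 1-100 Hz band-pass (default TRUE).
#' @param step_s TFD time step in s (default 0.01).
#' @param keep_tfd Also return the baseline-corrected `tfd` (default
#'   FALSE).
#' @return List with `features`, `trials`, `manifest` and optionally
#'   `tfd`.
#' @export
cohort_features <- function(config, filter = TRUE, step_s = 0.01,
                            keep_tfd = FALSE) {
  sim <- generate_cohort(config)
  ep <- sim$epochs
  if (filter) ep <- bandpass_filter(ep, 1, 100)
  ep <- baseline_correct_time(ep, c(config$epoch_window[1], 0))
  rois <- default_rois()
  tf_rois <- Filter(function(r) r$domain == "tf", rois)
  freqs <- sort(unique(unlist(lapply(tf_rois, function(r)
    seq(ceiling(r$freq_window[1]), floor(r$freq_window[2]))))))
  tt <- epoch_times(ep)
  half_s <- round(0.25 * ep$sfreq / 2) / ep$sfreq
  grid <- seq(ceiling((tt[1] + half_s) / step_s),
              floor((tt[length(tt)] - half_s) / step_s)) * step_s
  tfd <- wft_tfd(ep, "Cz", window_s = 0.25, step_s = step_s,
                 freqs = freqs, times = grid)
  tfd <- tfd_baseline_correct(tfd, c(-0.4, -0.1))
  features <- extract_feature_table(ep, sim$trials, rois, tfd = tfd)
  out <- list(features = features, trials = sim$trials,
              manifest = sim$manifest)
  if (keep_tfd) out$tfd <- tfd
  out
}

.stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[painvar] ", fmt), ...))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess, time-frequency decomposition, feature
#' extraction, within/between correlation statistics, point-by-point maps
#' with cluster permutation tests, ROC analyses, mixed ANOVAs and the
#' LOOCV prediction, in order, each stage consuming only artifacts of the
#' previous ones. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return A `pain_report` holding each stage's result plus provenance.
#' @export
run_pipeline <- function(config = run_config()) {
  v <- config$verbose
  stage <- function(name, expr) {
    .stage_msg(v, "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  scfg <- config$synth
  scfg$seed <- stage_seed(config$seed, "simulate")
  sim <- stage("simulate", generate_cohort(scfg))
  ep <- sim$epochs
  if (isTRUE(config$filter$enabled))
    ep <- stage("preprocess",
                bandpass_filter(ep, config$filter$low_hz,
                                config$filter$high_hz))
  ep <- stage("preprocess", baseline_correct_time(ep, config$baseline_time))

  rois <- default_rois()
  tf_rois <- Filter(function(r) r$domain == "tf", rois)
  tp <- config$tfd
  freqs <- sort(unique(c(seq(1, 100, by = tp$freq_step),
                         unlist(lapply(tf_rois, function(r)
                           seq(ceiling(r$freq_window[1]),
                               floor(r$freq_window[2]),
                               by = tp$freq_step))))))
  tt <- epoch_times(ep)
  half_s <- round(tp$window_s * ep$sfreq / 2) / ep$sfreq
  grid <- seq(ceiling((tt[1] + half_s) / tp$step_s),
              floor((tt[length(tt)] - half_s) / tp$step_s)) * tp$step_s
  tfd <- stage("tfd", {
    x <- wft_tfd(ep, "Cz", window_s = tp$window_s, step_s = tp$step_s,
                 freqs = freqs, times = grid)
    tfd_baseline_correct(x, tp$baseline_s)
  })
  features <- stage("features",
                    extract_feature_table(ep, sim$trials, rois, tfd = tfd))
  correlations <- stage("stats", feature_correlation_summary(features))
  clusters <- NULL
  if (isTRUE(config$stats$run_maps)) {
    clusters <- stage("stats", {
      maps <- pointwise_tf_maps(tfd, sim$trials)
      list(maps = maps,
           within = cluster_permutation_test(
             maps, tfd, sim$trials, "within", config$stats$n_perm,
             config$stats$alpha, seed = stage_seed(config$seed, "stats")),
           between = cluster_permutation_test(
             maps, tfd, sim$trials, "between", config$stats$n_perm,
             config$stats$alpha,
             seed = stage_seed(config$seed, "stats") + 1L))
    })
  }
  roc_energy <- stage("roc", energy_discrimination(sim$trials))
  roc_sens <- stage("roc", suppressWarnings(
    sensitivity_classification(features, config$roc$cutoffs)))
  split <- stage("anova", split_assignment(sim$trials))
  anova2 <- stage("anova", {
    out <- lapply(names(rois), function(f)
      mixed_anova_2way(features, split, f))
    names(out) <- names(rois)
    out
  })
  anova3 <- stage("anova",
                  mixed_anova_3way(zscore_features(features, split)))
  prediction <- stage("predict", {
    gm <- gamma_feature_matrix(tfd)
    my <- tapply(sim$trials$rating, sim$trials$subject, mean)
    rf_loocv_predict(gm, as.numeric(my),
                     n_components = config$prediction$n_components,
                     n_trees = config$prediction$n_trees,
                     seed = stage_seed(config$seed, "predict"),
                     pca_global = isTRUE(config$prediction$pca_global))
  })
  structure(list(
    config = config, trials = sim$trials, manifest = sim$manifest,
    features = features, correlations = correlations, clusters = clusters,
    roc_energy = roc_energy, roc_sensitivity = roc_sens, split = split,
    anova2 = anova2, anova3 = anova3, prediction = prediction,
    provenance = list(seed = config$seed,
                      config_hash = stable_hash(unclass(config)),
                      package_version =
                        as.character(utils::packageVersion("painvar")))),
    class = "pain_report")
}

#' @export
print.pain_report <- function(x, ...) {
  cat("=== Within/between variability report ===\n")
  print(x$correlations)
  if (!is.null(x$clusters)) {
    cat("\nWithin-subject cluster test:\n"); print(x$clusters$within)
    cat("Between-subject cluster test:\n"); print(x$clusters$between)
  }
  cat("\n"); print(x$roc_energy)
  print(x$roc_sensitivity)
  cat("\n"); print(x$split)
  cat("\nThree-way mixed ANOVA (z-scored features):\n")
  print(x$anova3)
  cat("\n"); print(x$prediction)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the structured results as JSON (full double precision), the
#' feature table and per-feature correlation table as TSV, and a short
#' human-readable Markdown summary (6 significant digits).
#'
#' @param report A `pain_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(
    correlations = report$correlations,
    clusters = if (!is.null(report$clusters)) list(
      within = report$clusters$within$clusters,
      between = report$clusters$between$clusters),
    roc_energy = as.list(report$roc_energy$group_mean),
    roc_sensitivity = report$roc_sensitivity$auc,
    anova3 = as.data.frame(report$anova3),
    anova3_posthoc = attr(report$anova3, "posthoc"),
    prediction = report$prediction[c("predicted", "real", "mae", "r",
                                     "n_components")],
    provenance = report$provenance)
  jsonlite::write_json(res, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.table(report$features, file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$correlations,
                     file.path(dir, "correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  md <- c("# Variability analysis report", "",
          sprintf("Seed %d; config hash %s; painvar %s",
                  report$provenance$seed, report$provenance$config_hash,
                  report$provenance$package_version), "",
          "## Feature correlations",
          utils::capture.output(print(report$correlations)), "",
          "## Prediction",
          utils::capture.output(print(report$prediction)))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
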