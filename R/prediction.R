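#' Per-subject gamma-band feature matrix for prediction
#'
#' Vectorises, for every subject, the mean baseline-corrected power at all
#' time-frequency points inside the gamma ROI (a data-driven cluster
#' window when available, else the a priori 180-260 ms, 60-85 Hz window).
#'
#' @param tfd Baseline-corrected single-trial `tfd` for all subjects.
#' @param roi A time-frequency [roi_definition()]; default the a priori
#'   gamma-ERS ROI.
#' @return Numeric matrix, subjects x TF points.
#' @export
gamma_feature_matrix <- function(tfd, roi = default_rois()$gERS) {
  fsel <- which(tfd$freqs_hz >= roi$freq_window[1] &
                tfd$freqs_hz <= roi$freq_window[2])
  tsel <- which(tfd$times_s >= roi$time_window[1] - 1e-9 &
                tfd$times_s <= roi$time_window[2] + 1e-9)
  if (!length(fsel) || !length(tsel))
    stop("gamma ROI is empty on the TFD grid", call. = FALSE)
  d <- dim(tfd$power)
  t(vapply(seq_len(d[1]), function(s) {
    as.vector(apply(tfd$power[s, , fsel, tsel, drop = FALSE], c(3, 4), mean))
  }, numeric(length(fsel) * length(tsel))))
}

#' Centred principal-component reduction
#'
#' @param x Numeric matrix (subjects x variables).
#' @param n_components Number of leading components to keep (default 20).
#' @return List with `scores` (subjects x n_components),
#'   `variance_explained` (per-component fractions, non-increasing),
#'   `rotation` and `center`.
#' @export
pca_reduce <- function(x, n_components = 20) {
  if (n_components > min(dim(x)))
    stop("n_components exceeds matrix dimensions", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       variance_explained = ve[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center)
}

#' Leave-one-out random-forest prediction of mean ratings
#'
#' Each subject in turn is held out; the PCA is fit on the remaining
#' subjects' feature matrix (avoiding leakage; set `pca_global = TRUE` to
#' fit it once on everyone), the held-out subject is projected into that
#' space, and a random-forest regressor trained on the remaining subjects
#' predicts the held-out mean rating.
#'
#' @param x Feature matrix (subjects x TF points), e.g. from
#'   [gamma_feature_matrix()].
#' @param mean_ratings Per-subject mean ratings aligned with `x` rows.
#' @param n_components Leading principal components used (default 20).
#' @param n_trees Trees per forest (default 1000).
#' @param seed RNG seed for the forests.
#' @param pca_global Fit the PCA once on all subjects instead of per fold.
#' @return A `prediction_result`: `predicted`, `real`, `mae`, Pearson `r`
#'   between predicted and real, `n_components`,
#'   `variance_explained` (from a fit on all subjects, for reporting).
#' @export
rf_loocv_predict <- function(x, mean_ratings, n_components = 20,
                             n_trees = 1000, seed = 1L,
                             pca_global = FALSE) {
  n <- nrow(x)
  if (length(mean_ratings) != n)
    stop("feature matrix rows and ratings are misaligned", call. = FALSE)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  ncomp <- min(n_components, n - 2, ncol(x))
  set.seed(seed)
  pred <- numeric(n)
  if (pca_global) {
    pc <- pca_reduce(x, ncomp)
    scores_all <- pc$scores
  }
  for (i in seq_len(n)) {
    if (pca_global) {
      tr_scores <- scores_all[-i, , drop = FALSE]
      te_scores <- scores_all[i, , drop = FALSE]
    } else {
      pc <- pca_reduce(x[-i, , drop = FALSE], min(ncomp, n - 2))
      tr_scores <- pc$scores
      te_scores <- (x[i, ] - pc$center) %*% pc$rotation
    }
    colnames(te_scores) <- colnames(tr_scores)
    if (stats::sd(mean_ratings[-i]) == 0) {
      pred[i] <- mean_ratings[-i][1]   # constant target: forest is moot
      next
    }
    rf <- randomForest::randomForest(tr_scores, mean_ratings[-i],
                                     ntree = n_trees)
    pred[i] <- stats::predict(rf, te_scores)
  }
  ve <- pca_reduce(x, ncomp)$variance_explained
  structure(list(predicted = pred, real = mean_ratings,
                 mae = mean(abs(pred - mean_ratings)),
                 r = if (stats::sd(pred) > 0 && stats::sd(mean_ratings) > 0)
                       stats::cor(pred, mean_ratings) else NA_real_,
                 n_components = ncomp, variance_explained = ve,
                 n_trees = n_trees, pca_global = pca_global),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("LOOCV random-forest prediction (%d subjects, %d PCs, %d trees%s)\n",
              length(x$predicted), x$n_components, x$n_trees,
              if (x$pca_global) ", global PCA" else ""))
  cat(sprintf("  MAE = %.3f rating units; r(predicted, real) = %.3f\n",
              x$mae, x$r))
  cat(sprintf("  leading components explain %.1f%% of feature variance\n",
              100 * sum(x$variance_explained)))
  invisible(x)
}
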