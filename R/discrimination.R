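#' ROC area under the curve by pair counting
#'
#' AUC = P(high > low) + 0.5 P(high = low), the normalised Mann-Whitney
#' U statistic, computed from midranks so ties contribute half credit.
#'
#' @param scores_low Scores of the "low" (negative) group.
#' @param scores_high Scores of the "high" (positive) group.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores_low, scores_high) {
  nl <- length(scores_low); nh <- length(scores_high)
  if (!nl || !nh) stop("both groups must be nonempty", call. = FALSE)
  rk <- rank(c(scores_high, scores_low))
  u <- sum(rk[seq_len(nh)]) - nh * (nh + 1) / 2
  u / (nl * nh)
}

#' Within-subject stimulus-energy discrimination from ratings
#'
#' For every subject and every pair of stimulus energies, the AUC of the
#' single-trial ratings for discriminating the higher from the lower
#' energy; summarised by the group mean per pair (per-subject AUCs are
#' averaged rather than pooled so within- and between-subject variability
#' are not conflated).
#'
#' @param trials A `trial_table`.
#' @return A `roc_result`: `auc` data frame (subject, pair, auc) and
#'   `group_mean` named vector over the 6 energy pairs.
#' @export
energy_discrimination <- function(trials) {
  levels_present <- sort(unique(trials$energy_level))
  if (length(levels_present) != 4)
    stop("each subject needs trials at all 4 energies", call. = FALSE)
  pairs <- utils::combn(levels_present, 2)
  subj <- sort(unique(trials$subject))
  rows <- list()
  for (s in subj) {
    ts <- trials[trials$subject == s, ]
    if (!all(levels_present %in% ts$energy_level))
      stop(sprintf("subject %s is missing an energy level", s),
           call. = FALSE)
    for (j in seq_len(ncol(pairs))) {
      lo <- pairs[1, j]; hi <- pairs[2, j]
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, pair = sprintf("E%d-E%d", lo, hi),
        auc = roc_auc(ts$rating[ts$energy_level == lo],
                      ts$rating[ts$energy_level == hi]))
    }
  }
  auc <- do.call(rbind, rows)
  gm <- tapply(auc$auc, auc$pair, mean)
  structure(list(context = "energy-pair", auc = auc,
                 group_mean = gm[order(names(gm))]),
            class = "roc_result")
}

#' Between-subject pain-sensitivity classification from a feature
#'
#' At each rating cutoff, subjects are split into those whose mean rating
#' is at or below versus above the cutoff (ties go to the lower group),
#' and the AUC of the per-subject mean feature magnitude for separating
#' the groups is computed. Cutoffs leaving either group empty are skipped
#' with a warning.
#'
#' @param features A `feature_table`.
#' @param cutoffs Rating cutoffs (default 4, 5, 6, 7; 4 is the
#'   conventional pain threshold).
#' @param feature Feature column (default "gERS").
#' @return A `roc_result` with one row per populated cutoff: cutoff, AUC,
#'   and the two group sizes.
#' @export
sensitivity_classification <- function(features, cutoffs = c(4, 5, 6, 7),
                                       feature = "gERS") {
  mx <- tapply(features[[feature]], features$subject, mean)
  my <- tapply(features$rating, features$subject, mean)
  rows <- list()
  for (co in cutoffs) {
    low <- my <= co
    if (!any(low) || all(low)) {
      warning(sprintf("cutoff %g leaves an empty group; skipped", co),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      cutoff = co, auc = roc_auc(mx[low], mx[!low]),
      n_low = sum(low), n_high = sum(!low))
  }
  structure(list(context = "rating-cutoff", feature = feature,
                 auc = if (length(rows)) do.call(rbind, rows) else
                   data.frame(cutoff = numeric(), auc = numeric(),
                              n_low = integer(), n_high = integer())),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis (%s)\n", x$context))
  if (x$context == "energy-pair") {
    for (p in names(x$group_mean))
      cat(sprintf("  %s: group-mean AUC = %.3f\n", p, x$group_mean[[p]]))
  } else {
    for (i in seq_len(nrow(x$auc)))
      cat(sprintf("  cutoff %g: AUC = %.3f (n = %d vs %d)\n",
                  x$auc$cutoff[i], x$auc$auc[i], x$auc$n_low[i],
                  x$auc$n_high[i]))
  }
  invisible(x)
}
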