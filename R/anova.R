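#' Median split of a set of values
#'
#' Sorts ascending (stable in the original order) and assigns the lower
#' `floor(n/2)` values to "low" and the rest to "high", so even counts
#' split exactly in half. If all values are identical the split is still
#' performed deterministically by original index, with a warning.
#'
#' @param values Numeric vector (length >= 2).
#' @return Character vector of "low"/"high" labels aligned with `values`.
#' @export
median_split <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values to split", call. = FALSE)
  if (stats::sd(values) == 0)
    warning("all values identical; splitting by original index",
            call. = FALSE)
  ord <- order(values)              # stable: ties keep original index order
  lab <- character(n)
  lab[ord[seq_len(n %/% 2)]] <- "low"
  lab[ord[(n %/% 2 + 1):n]] <- "high"
  factor(lab, levels = c("low", "high"))
}

#' Subject- and trial-level median-split assignment
#'
#' Subjects are sorted by mean rating and median-split into low-pain and
#' high-pain subjects; within each subject, trials are sorted by rating
#' and median-split into low-pain and high-pain trials.
#'
#' @param trials A `trial_table`.
#' @return A `split_assignment`: `subject_label` (named factor per
#'   subject), `trial_label` (factor aligned with `trials` rows), and
#'   group sizes.
#' @export
split_assignment <- function(trials) {
  subj <- sort(unique(trials$subject))
  my <- tapply(trials$rating, trials$subject, mean)[as.character(subj)]
  subject_label <- median_split(as.numeric(my))
  names(subject_label) <- subj
  trial_label <- factor(rep(NA_character_, nrow(trials)),
                        levels = c("low", "high"))
  for (s in subj) {
    i <- which(trials$subject == s)
    trial_label[i] <- median_split(trials$rating[i])
  }
  structure(list(subject_label = subject_label, trial_label = trial_label,
                 n_subjects = table(subject_label),
                 n_trials = table(trial_label) / length(subj)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("Median splits: %d low / %d high subjects; %g low / %g high trials per subject\n",
              x$n_subjects[["low"]], x$n_subjects[["high"]],
              x$n_trials[["low"]], x$n_trials[["high"]]))
  invisible(x)
}

# per-subject cell means of one feature under the trial-category split
.cell_means <- function(features, split, feature) {
  subj <- sort(unique(features$subject))
  rows <- list()
  for (s in subj) {
    i <- features$subject == s
    for (tc in c("low", "high")) {
      sel <- i & split$trial_label == tc
      if (!any(sel))
        stop(sprintf("subject %s has no %s-pain trials", s, tc),
             call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, group = split$subject_label[[as.character(s)]],
        trialcat = tc, y = mean(features[[feature]][sel]))
    }
  }
  out <- do.call(rbind, rows)
  out$trialcat <- factor(out$trialcat, levels = c("low", "high"))
  out$group <- factor(out$group, levels = c("low", "high"))
  out$subject <- factor(out$subject)
  out
}

# extract effects + partial eta^2 from a summary.aovlist; each effect's
# error term is the residual of its own stratum
.harvest_aov <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    res <- terms == "Residuals"
    if (!any(res)) next
    ss_err <- tab[res, "Sum Sq"]
    df_err <- tab[res, "Df"]
    for (i in which(!res)) {
      ss <- tab[i, "Sum Sq"]
      fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      if (ss <= .Machine$double.eps * max(1, ss_err)) {
        fv <- 0; pv <- 1   # degenerate all-equal cells
      }
      rows[[length(rows) + 1]] <- data.frame(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df_err,
        F = fv, p = pv,
        peta2 = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Two-way mixed-design ANOVA on median-split cell means
#'
#' 2 x 2 mixed ANOVA of one feature's per-subject cell means, with trial
#' category (low/high-pain trials) as the within-subject factor and
#' subject category (low/high-pain subjects) as the between-subject
#' factor. Effect sizes are partial eta squared computed against each
#' effect's own stratum error.
#'
#' @param features A `feature_table`.
#' @param split A [split_assignment()].
#' @param feature Feature column name.
#' @return An `anova_result` data frame (effect, df1, df2, F, p, peta2).
#' @export
mixed_anova_2way <- function(features, split, feature) {
  cm <- .cell_means(features, split, feature)
  fit <- stats::aov(y ~ group * trialcat + Error(subject / trialcat),
                    data = cm)
  out <- .harvest_aov(fit)
  out$effect <- c("group" = "subject_category",
                  "trialcat" = "trial_category",
                  "group:trialcat" = "interaction")[out$effect]
  attr(out, "feature") <- feature
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Z-score feature cell means across the full sample
#'
#' Builds the per-subject cell means of the requested features under the
#' median splits and standardises each feature to mean 0, sd 1 across all
#' of its cell means, so features measured in different units (uV, percent
#' power change) can be compared in one model.
#'
#' @param features A `feature_table`.
#' @param split A [split_assignment()].
#' @param feature_names Features to include (default the three
#'   time-frequency features LEP, aERD, gERS).
#' @return Long data frame: subject, group, trialcat, feature, y (z-scored).
#' @export
zscore_features <- function(features, split,
                            feature_names = c("LEP", "aERD", "gERS")) {
  rows <- lapply(feature_names, function(f) {
    cm <- .cell_means(features, split, f)
    if (stats::sd(cm$y) == 0)
      stop(sprintf("degenerate variance: feature %s is constant", f),
           call. = FALSE)
    cm$y <- (cm$y - mean(cm$y)) / stats::sd(cm$y)
    cm$feature <- f
    cm
  })
  out <- do.call(rbind, rows)
  out$feature <- factor(out$feature, levels = feature_names)
  out
}

# Greenhouse-Geisser epsilon for a within-subject effect: Y is the
# subject x cell matrix, M the (cells x df) contrast of the effect
.gg_epsilon <- function(Y, M) {
  M <- qr.Q(qr(M))                       # orthonormalise
  S <- crossprod(M, stats::cov(Y)) %*% M
  d <- ncol(S)
  sum(diag(S))^2 / (d * sum(S * S))
}

#' Three-way mixed-design ANOVA on z-scored features
#'
#' Full mixed ANOVA with two within-subject factors (trial category:
#' low/high-pain trials; feature category: e.g. LEP, alpha-ERD,
#' gamma-ERS) and one between-subject factor (subject category). P values
#' of effects involving the (3-level) feature factor are
#' Greenhouse-Geisser corrected (`p_gg`); two-level within effects are
#' exact. Post hoc low- vs high-pain-subject contrasts are reported per
#' feature as uncorrected two-sample t tests with partial eta squared.
#'
#' @param zfeatures Long z-scored cell-mean table from [zscore_features()].
#' @return An `anova_result` with columns effect, df1, df2, F, p, peta2,
#'   gg_epsilon, p_gg, plus a `posthoc` attribute (per-feature contrast
#'   table).
#' @export
mixed_anova_3way <- function(zfeatures) {
  zf <- zfeatures
  zf$subject <- factor(zf$subject)
  fit <- stats::aov(y ~ group * trialcat * feature +
                      Error(subject / (trialcat * feature)), data = zf)
  out <- .harvest_aov(fit)
  rename <- c("group" = "subject_category",
              "trialcat" = "trial_category",
              "feature" = "feature_category",
              "group:trialcat" = "subject_x_trial",
              "group:feature" = "subject_x_feature",
              "trialcat:feature" = "trial_x_feature",
              "group:trialcat:feature" = "subject_x_trial_x_feature")
  out$effect <- rename[out$effect]

  # GG epsilon from the subject x cell matrix (cells: trialcat x feature)
  zf$cell <- interaction(zf$trialcat, zf$feature)
  Y <- tapply(zf$y, list(zf$subject, zf$cell), mean)
  lev <- levels(zf$cell)
  tc <- sub("\\..*$", "", lev)
  ft <- sub("^[^.]*\\.", "", lev)
  nfeat <- length(unique(ft))
  c_feat <- stats::contr.helmert(nfeat)
  c_tc <- matrix(c(1, -1), 2)
  ind_feat <- t(vapply(unique(ft), function(f) as.numeric(ft == f),
                       numeric(length(lev))))
  ind_tc <- t(vapply(unique(tc), function(g) as.numeric(tc == g),
                     numeric(length(lev))))
  M_feat <- t(ind_feat) %*% c_feat          # cells x (nfeat-1)
  M_tcfeat <- matrix(0, length(lev), nfeat - 1)
  for (j in seq_len(nfeat - 1)) {
    M_tcfeat[, j] <- (t(ind_feat) %*% c_feat[, j]) *
      (t(ind_tc) %*% c_tc)
  }
  eps_feat <- .gg_epsilon(Y, M_feat)
  eps_tf <- .gg_epsilon(Y, M_tcfeat)
  out$gg_epsilon <- 1
  out$gg_epsilon[out$effect %in% c("feature_category", "subject_x_feature")] <- eps_feat
  out$gg_epsilon[out$effect %in% c("trial_x_feature",
                                   "subject_x_trial_x_feature")] <- eps_tf
  out$p_gg <- stats::pf(out$F, out$gg_epsilon * out$df1,
                        out$gg_epsilon * out$df2, lower.tail = FALSE)

  # post hoc: per feature, low vs high subjects on subject-level means
  ph <- lapply(levels(zf$feature), function(f) {
    sub <- zf[zf$feature == f, ]
    m <- tapply(sub$y, sub$subject, mean)
    g <- tapply(as.character(sub$group), sub$subject, unique)
    ht <- stats::t.test(m[g == "high"], m[g == "low"], var.equal = TRUE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter)
    data.frame(feature = f, estimate = unname(diff(rev(ht$estimate))),
               t = tt, df = df, p = ht$p.value,
               peta2 = tt^2 / (tt^2 + df))
  })
  attr(out, "posthoc") <- do.call(rbind, ph)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' @export
print.anova_result <- function(x, ...) {
  feat <- attr(x, "feature")
  cat("Mixed-design ANOVA", if (!is.null(feat)) sprintf("(%s)", feat), "\n")
  for (i in seq_len(nrow(x))) {
    extra <- if (!is.null(x$p_gg)) sprintf(", GG p = %.3g", x$p_gg[i]) else ""
    cat(sprintf("  %-28s F(%g, %g) = %8.3f, P = %.3g%s, partial eta2 = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i], extra,
                x$peta2[i]))
  }
  ph <- attr(x, "posthoc")
  if (!is.null(ph)) {
    cat("  post hoc (high vs low subjects):\n")
    for (i in seq_len(nrow(ph)))
      cat(sprintf("    %-5s diff = %6.3f, t(%g) = %6.2f, P = %.3g, partial eta2 = %.3f\n",
                  ph$feature[i], ph$estimate[i], ph$df[i], ph$t[i], ph$p[i],
                  ph$peta2[i]))
  }
  invisible(x)
}
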