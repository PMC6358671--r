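#' Per-subject trial-wise correlation between a feature and ratings
#'
#' Computes, for each subject, the Pearson correlation between the
#' single-trial feature magnitude and the single-trial intensity rating.
#' Subjects with zero variance in either variable are excluded with a
#' warning and returned as `NA`.
#'
#' @param features A `feature_table` (contains the ratings).
#' @param feature Feature column name (e.g. "gERS").
#' @return Named numeric vector of per-subject r; excluded subjects `NA`,
#'   listed in the `excluded` attribute.
#' @export
within_subject_correlation <- function(features, feature) {
  subj <- unique(features$subject)
  r <- vapply(subj, function(s) {
    i <- features$subject == s
    x <- features[[feature]][i]
    y <- features$rating[i]
    if (length(x) < 3) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  names(r) <- subj
  if (anyNA(r)) {
    warning(sprintf("excluded %d subject(s) with degenerate variance for %s",
                    sum(is.na(r)), feature), call. = FALSE)
    attr(r, "excluded") <- subj[is.na(r)]
  }
  r
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)`, antisymmetric in r. Correlations of magnitude 1 are an
#' error; callers that must handle them clip to +/-(1 - 1e-12) first
#' (see [clip_r()]).
#'
#' @param r Correlation coefficient(s), |r| < 1.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("|r| = 1 gives infinite z; clip first (see clip_r)", call. = FALSE)
  atanh(r)
}

#' Clip correlations away from +/-1
#' @param r Correlations.
#' @param eps Clip margin (default 1e-12).
#' @return Correlations clipped into (-1, 1).
#' @export
clip_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' One-sample group test of Fisher z values against zero
#'
#' @param z Finite Fisher z values (NA dropped).
#' @return List with `t`, `df` (n - 1), two-sided `p`, `mean_r`
#'   (back-transformed mean of the input r) and `n`.
#' @export
group_level_test <- function(z) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 2) stop("need at least 2 finite z values", call. = FALSE)
  if (stats::sd(z) == 0)
    stop("degenerate variance: all z values identical", call. = FALSE)
  ht <- stats::t.test(z, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_z = mean(z), n = n)
}

#' Between-subject correlation of mean magnitude and mean rating
#'
#' Pearson correlation, across subjects, of the per-subject mean feature
#' magnitude with the per-subject mean rating.
#'
#' @inheritParams within_subject_correlation
#' @return List with `r`, two-sided `p` and `n` subjects.
#' @export
between_subject_correlation <- function(features, feature) {
  mx <- tapply(features[[feature]], features$subject, mean)
  my <- tapply(features$rating, features$subject, mean)
  if (length(mx) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(mx) == 0 || stats::sd(my) == 0)
    stop("degenerate variance across subjects", call. = FALSE)
  ht <- stats::cor.test(mx, my)
  list(r = unname(ht$estimate), p = ht$p.value, n = length(mx))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q values; monotone in the order statistics and never
#' below the raw p.
#'
#' @param p P values in [0, 1].
#' @return Adjusted q values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Within/between correlation summary for all features
#'
#' Reproduces the standard per-feature summary: per-subject trial-wise
#' correlations (mean and sd of r), Fisher-z group t test, between-subject
#' correlation, and FDR q values. Following the convention that the
#' within- and between-subject tests of the six features form one
#' multiple-comparison family, the twelve p values are adjusted jointly.
#'
#' @param features A `feature_table`.
#' @param feature_names Feature columns to summarise.
#' @return A `correlation_result` data frame, one row per feature:
#'   within_r_mean, within_r_sd, within_t, within_df, within_p, within_q,
#'   between_r, between_p, between_q.
#' @export
feature_correlation_summary <- function(features,
                                        feature_names = c("N1", "N2", "P2",
                                                          "LEP", "aERD",
                                                          "gERS")) {
  rows <- lapply(feature_names, function(f) {
    r <- suppressWarnings(within_subject_correlation(features, f))
    z <- fisher_z(clip_r(r[!is.na(r)]))
    g <- group_level_test(z)
    b <- between_subject_correlation(features, f)
    data.frame(feature = f,
               within_r_mean = mean(r, na.rm = TRUE),
               within_r_sd = stats::sd(r, na.rm = TRUE),
               within_t = g$t, within_df = g$df, within_p = g$p,
               between_r = b$r, between_p = b$p, n = b$n)
  })
  out <- do.call(rbind, rows)
  q <- fdr_adjust(c(out$within_p, out$between_p))
  out$within_q <- q[seq_len(nrow(out))]
  out$between_q <- q[nrow(out) + seq_len(nrow(out))]
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Within- and between-subject correlations with intensity ratings\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-5s within r = %6.3f +/- %.3f (t = %6.2f, P = %.2g, q = %.2g)  between r = %6.3f (P = %.2g, q = %.2g)\n",
      x$feature[i], x$within_r_mean[i], x$within_r_sd[i], x$within_t[i],
      x$within_p[i], x$within_q[i], x$between_r[i], x$between_p[i],
      x$between_q[i]))
  }
  invisible(x)
}

# Per-subject pointwise correlation machinery shared by the map and the
# permutation engine. power: subject x trial x freq x time (percent
# change); returns a list with centred/scaled per-subject matrices.
.prep_pointwise <- function(tfd, trials) {
  d <- dim(tfd$power)
  k <- d[3] * d[4]
  subj <- sort(unique(trials$subject))
  stopifnot(length(subj) == d[1])
  per <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    p <- matrix(tfd$power[s, , , ], nrow = d[2])   # trials x points
    pc <- sweep(p, 2, colMeans(p))
    ss <- sqrt(colSums(pc^2))
    ss[ss == 0] <- NA_real_                         # degenerate points
    y <- trials$rating[trials$subject == subj[s]]
    per[[s]] <- list(pc = pc, ss = ss, y = y)
  }
  list(per = per, nf = d[3], nt = d[4], k = k,
       mean_rating = vapply(per, function(e) mean(e$y), numeric(1)))
}

.within_tmap <- function(prep, ratings = NULL) {
  ns <- length(prep$per)
  zmat <- matrix(NA_real_, ns, prep$k)
  for (s in seq_len(ns)) {
    e <- prep$per[[s]]
    y <- if (is.null(ratings)) e$y else ratings[[s]]
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    r <- if (sy == 0) rep(NA_real_, prep$k)
         else as.vector(crossprod(e$pc, yc)) / (e$ss * sy)
    zmat[s, ] <- atanh(clip_r(r))
  }
  n <- colSums(is.finite(zmat))
  m <- colMeans(zmat, na.rm = TRUE)
  sdv <- sqrt((colSums(zmat^2, na.rm = TRUE) - n * m^2) / (n - 1))
  tval <- m / (sdv / sqrt(n))
  list(t = tval, df = n - 1)
}

.between_rmap <- function(mean_power, mean_ratings) {
  yc <- mean_ratings - mean(mean_ratings)
  pc <- sweep(mean_power, 2, colMeans(mean_power))
  ss <- sqrt(colSums(pc^2))
  ss[ss == 0] <- NA_real_
  as.vector(crossprod(pc, yc)) / (ss * sqrt(sum(yc^2)))
}

#' Point-by-point time-frequency statistic maps
#'
#' At every time-frequency point, the within-subject map is the group t
#' statistic of the per-subject Fisher-z trial-wise correlations between
#' single-trial power and ratings; the between-subject map is the Pearson
#' correlation of subject-mean power with subject-mean rating. Points
#' with degenerate variance drop the affected subjects pointwise.
#'
#' @param tfd A baseline-corrected single-trial `tfd` covering all
#'   subjects.
#' @param trials Matching `trial_table`.
#' @return A `tf_maps` object: `t_map` and `r_map` (freq x time
#'   matrices), `df` (per-point group df), grids, and subject count.
#' @export
pointwise_tf_maps <- function(tfd, trials) {
  prep <- .prep_pointwise(tfd, trials)
  w <- .within_tmap(prep)
  d <- dim(tfd$power)
  mean_power <- t(vapply(seq_len(d[1]), function(s)
    as.vector(colMeans(matrix(tfd$power[s, , , ], nrow = d[2]))),
    numeric(prep$k)))
  r <- .between_rmap(mean_power, prep$mean_rating)
  structure(list(
    t_map = matrix(w$t, prep$nf, prep$nt),
    r_map = matrix(r, prep$nf, prep$nt),
    df = matrix(w$df, prep$nf, prep$nt),
    freqs_hz = tfd$freqs_hz, times_s = tfd$times_s,
    n_subjects = d[1]), class = "tf_maps")
}

#' @export
print.tf_maps <- function(x, ...) {
  cat(sprintf("TF statistic maps: %d freqs x %d times, %d subjects\n",
              length(x$freqs_hz), length(x$times_s), x$n_subjects))
  cat(sprintf("  within t in [%.2f, %.2f]; between r in [%.2f, %.2f]\n",
              min(x$t_map, na.rm = TRUE), max(x$t_map, na.rm = TRUE),
              min(x$r_map, na.rm = TRUE), max(x$r_map, na.rm = TRUE)))
  invisible(x)
}

# 8-connected components of a logical matrix; returns integer label
# matrix (0 = background).
.connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# clusters of same-signed suprathreshold points; returns data frame of
# cluster masses and a label matrix
.form_clusters <- function(stat, thresh) {
  out <- list()
  lab_all <- matrix(0L, nrow(stat), ncol(stat))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- is.finite(stat) & (sgn * stat > thresh)
    if (!any(mask)) next
    lab <- .connected_components(mask)
    for (cl in seq_len(max(lab))) {
      members <- which(lab == cl)
      next_id <- next_id + 1L
      lab_all[members] <- next_id
      out[[next_id]] <- data.frame(
        cluster = next_id, sign = sgn, n_points = length(members),
        mass = sum(abs(stat[members])))
    }
  }
  list(table = if (length(out)) do.call(rbind, out) else
         data.frame(cluster = integer(), sign = numeric(),
                    n_points = integer(), mass = numeric()),
       labels = lab_all)
}

#' Cluster-based permutation test of time-frequency maps
#'
#' Thresholds the observed statistic map at pointwise two-sided
#' `p < alpha`, forms 8-connected clusters of same-signed suprathreshold
#' points, and scores each cluster by its mass (sum of absolute statistic
#' values). The family-wise null distribution is the maximum cluster mass
#' under label permutation: in `within` mode ratings are shuffled across
#' trials independently within each subject; in `between` mode subject-
#' mean ratings are shuffled across subjects. The permutation p value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`, never zero.
#'
#' @param maps `tf_maps` from [pointwise_tf_maps()] (must come from the
#'   same `tfd`/`trials`).
#' @param tfd Baseline-corrected single-trial `tfd`.
#' @param trials Matching `trial_table`.
#' @param mode "within" or "between".
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Pointwise cluster-forming threshold (default 0.05).
#' @param seed Optional RNG seed for the permutations.
#' @return A `cluster_result`: cluster table (extent, mass, permutation
#'   p), label matrix, significance mask at `alpha`, null distribution
#'   summary and `n_perm`.
#' @export
cluster_permutation_test <- function(maps, tfd, trials,
                                     mode = c("within", "between"),
                                     n_perm = 5000, alpha = 0.05,
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prep <- .prep_pointwise(tfd, trials)
  ns <- length(prep$per)
  if (mode == "within") {
    stat <- maps$t_map
    df <- ns - 1
    thresh <- stats::qt(1 - alpha / 2, df)
  } else {
    stat <- maps$r_map
    tcrit <- stats::qt(1 - alpha / 2, ns - 2)
    thresh <- tcrit / sqrt(ns - 2 + tcrit^2)   # critical |r|
  }
  obs <- .form_clusters(stat, thresh)
  null_max <- numeric(n_perm)
  if (mode == "within") {
    for (b in seq_len(n_perm)) {
      perm_ratings <- lapply(prep$per, function(e) sample(e$y))
      w <- .within_tmap(prep, perm_ratings)
      pm <- .form_clusters(matrix(w$t, prep$nf, prep$nt), thresh)
      null_max[b] <- if (nrow(pm$table)) max(pm$table$mass) else 0
    }
  } else {
    d <- dim(tfd$power)
    mean_power <- t(vapply(seq_len(d[1]), function(s)
      as.vector(colMeans(matrix(tfd$power[s, , , ], nrow = d[2]))),
      numeric(prep$k)))
    for (b in seq_len(n_perm)) {
      r <- .between_rmap(mean_power, sample(prep$mean_rating))
      pm <- .form_clusters(matrix(r, prep$nf, prep$nt), thresh)
      null_max[b] <- if (nrow(pm$table)) max(pm$table$mass) else 0
    }
  }
  tab <- obs$table
  if (nrow(tab)) {
    tab$p <- vapply(tab$mass, function(m)
      (1 + sum(null_max >= m)) / (1 + n_perm), numeric(1))
    ext <- lapply(seq_len(nrow(tab)), function(i) {
      members <- which(obs$labels == tab$cluster[i])
      fi <- (members - 1L) %% prep$nf + 1L
      ti <- (members - 1L) %/% prep$nf + 1L
      c(f_lo = min(maps$freqs_hz[fi]), f_hi = max(maps$freqs_hz[fi]),
        t_lo = min(maps$times_s[ti]), t_hi = max(maps$times_s[ti]))
    })
    ext <- do.call(rbind, ext)
    tab <- cbind(tab, ext)
    tab <- tab[order(tab$p, -tab$mass), ]
  }
  structure(list(clusters = tab, labels = obs$labels,
                 mask = obs$labels > 0 &
                   matrix(tab$p[match(obs$labels, tab$cluster)] <= alpha,
                          prep$nf, prep$nt),
                 stat_map = stat, threshold = thresh, mode = mode,
                 null_max = null_max, n_perm = n_perm, alpha = alpha,
                 freqs_hz = maps$freqs_hz, times_s = maps$times_s),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s mode, %d permutations, alpha = %g)\n",
              x$mode, x$n_perm, x$alpha))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  cluster %d: %d points, %.0f-%.0f ms, %g-%g Hz, mass %.1f, p = %.4g\n",
                  cl$cluster, cl$n_points, cl$t_lo * 1000, cl$t_hi * 1000,
                  cl$f_lo, cl$f_hi, cl$mass, cl$p))
    }
  }
  invisible(x)
}
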