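#' Signed two-sample pooled-variance t statistics across thresholds
#'
#' Computes, at each threshold, the pooled-variance two-sample t statistic
#' comparing patients and controls, signed so that the hypothesized
#' direction yields positive values: with
#' `direction = "patient_lt_control"` (the default, testing reduced network
#' metrics in patients), `t = (mean_control - mean_patient) / se`.
#'
#' @param X numeric `subject x threshold` matrix of metric values.
#' @param group factor/character per subject, levels `"patient"` and
#'   `"control"`.
#' @param direction `"patient_lt_control"` or `"control_lt_patient"`.
#' @return Numeric vector of t values, one per threshold.  Thresholds with
#'   zero pooled variance give t = 0 with a warning.
#' @export
observed_t <- function(X, group, direction = "patient_lt_control") {
  X <- as.matrix(X)
  group <- as.character(group)
  if (length(group) != nrow(X)) stop("group length must match rows of X")
  if (!all(group %in% c("patient", "control"))) {
    stop("group must contain only 'patient' and 'control'")
  }
  pat <- group == "patient"
  n1 <- sum(pat); n2 <- sum(!pat)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  if (any(!is.finite(X))) stop("metric matrix contains missing values")
  m_pat <- colMeans(X[pat, , drop = FALSE])
  m_ctl <- colMeans(X[!pat, , drop = FALSE])
  v_pat <- apply(X[pat, , drop = FALSE], 2, stats::var)
  v_ctl <- apply(X[!pat, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v_pat + (n2 - 1) * v_ctl) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- switch(direction,
              patient_lt_control = m_ctl - m_pat,
              control_lt_patient = m_pat - m_ctl,
              stop("unknown direction: ", direction))
  t <- d / se
  if (any(se == 0)) {
    warning("zero pooled variance at some thresholds; t set to 0")
    t[se == 0] <- 0
  }
  t
}

# t statistics for a batch of permutations.
# X: n x T metric matrix; P: n_perm x n 0/1 indicator of "patient" labels.
perm_t_matrix <- function(X, P, n1, n2) {
  sum_all <- colSums(X)
  ssq_all <- colSums(X^2)
  s1 <- P %*% X                              # n_perm x T patient sums
  q1 <- P %*% X^2
  m1 <- s1 / n1
  m2 <- sweep(-s1, 2, sum_all, `+`) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (sweep(-q1, 2, ssq_all, `+`) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se                        # control - patient orientation
  t[se == 0] <- 0
  t
}

# Trapezoidal AUC of t over the threshold axis, restricted to maximal runs
# of consecutive supracritical thresholds.  Vectorized over the rows of a
# t matrix: adjacent pairs that are both supracritical are exactly the
# within-run segments, so a single-threshold cluster contributes 0.
cluster_auc_rows <- function(tmat, thresholds, s_crit) {
  e <- tmat > s_crit
  Tn <- length(thresholds)
  auc <- numeric(nrow(tmat))
  if (Tn >= 2) {
    for (j in seq_len(Tn - 1)) {
      seg <- e[, j] & e[, j + 1]
      dx <- thresholds[j + 1] - thresholds[j]
      auc <- auc + ifelse(seg, 0.5 * (tmat[, j] + tmat[, j + 1]) * dx, 0)
    }
  }
  list(auc = auc, any_supra = rowSums(e) > 0)
}

#' Multi-threshold permutation correction (MTPC) for a group comparison
#'
#' Tests whether a graph metric is reduced in patients consistently across
#' a family of network densities, controlling the family-wise error over
#' thresholds with a max-statistic permutation scheme:
#'
#' 1. the observed signed t statistic is computed at every threshold
#'    ([observed_t()]);
#' 2. group labels are permuted `n_perm` times (group sizes preserved,
#'    seeded) and the maximum t across thresholds recorded per permutation;
#' 3. the critical value `S_crit` is the `(1 - alpha)` empirical quantile
#'    of that null maximum distribution;
#' 4. observed "clusters" are maximal runs of consecutive thresholds with
#'    `t > S_crit`; `A_mtpc` is their summed trapezoidal area under the
#'    t-curve over the density axis;
#' 5. the same cluster area is computed for every permutation; `A_crit` is
#'    the mean over permutations showing any supracritical threshold;
#' 6. the effect is significant when a cluster exists and
#'    `A_mtpc > A_crit`.
#'
#' The per-analysis p-value is the add-one max-statistic estimate
#' `p = (1 + #\{null max >= S_mtpc\}) / (n_perm + 1)`.
#'
#' A cluster consisting of a single threshold has zero area and therefore
#' cannot exceed a positive `A_crit`; it is still reported.  If no
#' permutation produces a supracritical threshold, `A_crit = 0` and any
#' observed cluster with positive area is significant.
#'
#' @param X `subject x threshold` metric matrix.
#' @param group per-subject `"patient"` / `"control"` labels.
#' @param thresholds strictly increasing density grid matching the columns
#'   of `X`.
#' @param n_perm number of label permutations (default 5000; fewer than 100
#'   triggers a warning).
#' @param alpha nominal level (default 0.05), one-sided.
#' @param direction hypothesized direction, see [observed_t()].
#' @param seed RNG seed; results are reproducible given `(seed, n_perm)`,
#'   and passing the same seed across metrics reuses the same permutation
#'   sequence so analyses are comparable.
#' @return Object of class `mtpc_result`: list with `t_observed`,
#'   `S_mtpc`, `S_crit`, `A_mtpc`, `A_crit`, `clusters` (list of integer
#'   threshold-index runs), `significant`, `p`, `null_max` (the permutation
#'   null sample of maxima), plus the call parameters.
#' @export
mtpc_test <- function(X, group, thresholds, n_perm = 5000, alpha = 0.05,
                      direction = "patient_lt_control", seed = 1) {
  X <- as.matrix(X)
  thresholds <- as.numeric(thresholds)
  if (ncol(X) != length(thresholds)) stop("thresholds must match columns of X")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  group <- as.character(group)
  pat <- group == "patient"
  n <- nrow(X); n1 <- sum(pat); n2 <- n - n1
  t_obs <- observed_t(X, group, direction)
  # orient X so perm_t_matrix's control-minus-patient sign matches t_obs
  Xo <- if (direction == "control_lt_patient") -X else X

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  P <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) P[b, sample.int(n, n1)] <- 1
  tmat <- perm_t_matrix(Xo, P, n1, n2)

  null_max <- apply(tmat, 1L, max)
  S_crit <- stats::quantile(null_max, 1 - alpha, type = 1, names = FALSE)
  S_mtpc <- max(t_obs)

  exceed <- t_obs > S_crit
  runs <- rle(exceed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  clusters <- Map(seq, starts[runs$values], ends[runs$values])

  obs_auc <- cluster_auc_rows(matrix(t_obs, nrow = 1), thresholds, S_crit)
  A_mtpc <- obs_auc$auc
  nul <- cluster_auc_rows(tmat, thresholds, S_crit)
  A_crit <- if (any(nul$any_supra)) mean(nul$auc[nul$any_supra]) else 0

  significant <- length(clusters) > 0 && A_mtpc > A_crit
  p <- (1 + sum(null_max >= S_mtpc)) / (n_perm + 1)

  structure(list(
    t_observed = t_obs, thresholds = thresholds,
    S_mtpc = S_mtpc, S_crit = S_crit,
    A_mtpc = A_mtpc, A_crit = A_crit,
    clusters = clusters, significant = significant, p = p,
    null_max = null_max,
    n_perm = n_perm, alpha = alpha, direction = direction, seed = seed,
    n_patient = n1, n_control = n2), class = "mtpc_result")
}

#' @export
print.mtpc_result <- function(x, ...) {
  cat(sprintf(
    "<mtpc_result> %d vs %d subjects, %d thresholds, %d permutations\n",
    x$n_patient, x$n_control, length(x$thresholds), x$n_perm))
  cat(sprintf("  S.mtpc = %.3f  S.crit = %.3f  A.mtpc = %.4f  A.crit = %.4f\n",
              x$S_mtpc, x$S_crit, x$A_mtpc, x$A_crit))
  cat(sprintf("  %s (p = %.4f, one-sided %s)\n",
              if (x$significant) "SIGNIFICANT" else "not significant",
              x$p, x$direction))
  invisible(x)
}

#' Benjamini-Hochberg correction across MTPC analyses
#'
#' Adjusts the per-analysis MTPC p-values against each other (the second,
#' across-analyses correction stage).
#'
#' @param results list of `mtpc_result` objects, or a numeric p-value
#'   vector.
#' @return Numeric vector of BH-adjusted p-values.
#' @export
fdr_across <- function(results) {
  p <- if (is.numeric(results)) results else
    vapply(results, function(r) r$p, numeric(1))
  if (length(p) == 0) stop("no results to adjust")
  stats::p.adjust(p, method = "BH")
}

#' Run the MTPC suite over every (band, metric) combination
#'
#' Builds the `subject x threshold` matrix for each band and metric column
#' in a long-format metric table, runs [mtpc_test()] on each with the same
#' permutation seed, and applies [fdr_across()] to the per-analysis
#' p-values.
#'
#' @param metrics long-format table from [metric_table()].
#' @param cohort data.frame with `subject_id` and `group` columns.
#' @param metric_cols metric columns to test.
#' @param ... passed to [mtpc_test()] (`n_perm`, `alpha`, `direction`,
#'   `seed`).
#' @return List with `results` (named list of `mtpc_result`, names
#'   `"band.metric"`) and `summary` (data.frame with S/A statistics, p and
#'   `p_across`).
#' @export
run_mtpc_suite <- function(metrics, cohort,
                           metric_cols = c("modularity", "global_efficiency",
                                           "local_efficiency"),
                           ...) {
  thresholds <- sort(unique(metrics$threshold))
  bands <- unique(metrics$band)
  results <- list()
  for (b in bands) {
    for (mc in metric_cols) {
      sub <- metrics[metrics$band == b, c("subject_id", "threshold", mc)]
      sub <- sub[order(match(sub$subject_id, unique(sub$subject_id)),
                       sub$threshold), ]
      X <- stats::reshape(sub, idvar = "subject_id", timevar = "threshold",
                          direction = "wide")
      ids <- X$subject_id
      X <- as.matrix(X[, -1, drop = FALSE])
      grp <- cohort$group[match(ids, cohort$subject_id)]
      if (anyNA(grp)) stop("subjects in metrics missing from cohort table")
      results[[paste(b, mc, sep = ".")]] <-
        mtpc_test(X, grp, thresholds, ...)
    }
  }
  p_across <- fdr_across(results)
  summary <- data.frame(
    analysis = names(results),
    band = rep(bands, each = length(metric_cols)),
    metric = rep(metric_cols, times = length(bands)),
    S_mtpc = vapply(results, `[[`, numeric(1), "S_mtpc"),
    S_crit = vapply(results, `[[`, numeric(1), "S_crit"),
    A_mtpc = vapply(results, `[[`, numeric(1), "A_mtpc"),
    A_crit = vapply(results, `[[`, numeric(1), "A_crit"),
    significant = vapply(results, `[[`, logical(1), "significant"),
    p = vapply(results, `[[`, numeric(1), "p"),
    p_across = p_across,
    row.names = NULL, stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}

#' Threshold-versus-t plot of an MTPC analysis
#'
#' Base-graphics rendering of one analysis: observed t-curve across
#' densities, the critical value as a dashed line, the permutation null
#' maxima as jittered points, and supracritical clusters shaded.
#'
#' @param x an `mtpc_result`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.mtpc_result <- function(x, main = "MTPC", ...) {
  th <- x$thresholds
  jitter_x <- rep(th, each = min(length(x$null_max), 200))
  sub_null <- utils::head(x$null_max, 200)
  ylim <- range(c(x$t_observed, x$null_max, x$S_crit))
  graphics::plot(th, x$t_observed, type = "n", ylim = ylim,
                 xlab = "network density", ylab = "t statistic",
                 main = main, ...)
  for (cl in x$clusters) {
    if (length(cl) >= 2) {
      graphics::polygon(c(th[cl], rev(th[cl])),
                        c(x$t_observed[cl], rep(x$S_crit, length(cl))),
                        col = "grey85", border = NA)
    }
  }
  graphics::points(rep(th, each = length(sub_null)),
                   rep(sub_null, times = length(th)),
                   pch = 16, cex = 0.2, col = "grey70")
  graphics::abline(h = x$S_crit, lty = 2)
  graphics::lines(th, x$t_observed, lwd = 2)
  graphics::points(th, x$t_observed, pch = 19)
  invisible(x)
}
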