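#' Select the density with the strongest group difference
#'
#' For each analysis, returns the threshold at which the observed group
#' t statistic is maximal (equivalently where the group-difference p-value
#' is lowest); ties are broken toward the lower density.
#'
#' @param mtpc_results named list of `mtpc_result` objects (as returned in
#'   `run_mtpc_suite()$results`), or a single `mtpc_result`.
#' @return For a list: data.frame with `analysis` and `threshold`; for a
#'   single result: the selected threshold.
#' @export
select_threshold <- function(mtpc_results) {
  pick <- function(r) r$thresholds[which.max(r$t_observed)]
  if (inherits(mtpc_results, "mtpc_result")) return(pick(mtpc_results))
  data.frame(analysis = names(mtpc_results),
             threshold = vapply(mtpc_results, pick, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress a cognitive score on a graph metric (with optional sex covariate)
#'
#' Ordinary least squares of one cognitive score on one network metric,
#' optionally controlling for sex.  Subjects missing the score are dropped
#' listwise (their count is reported).  Standardized coefficients are
#' obtained by refitting on z-scored response and predictors, so for a
#' single-predictor model the standardized slope equals the Pearson
#' correlation.  A simple linearity diagnostic — the correlation of the
#' residuals with the squared fitted values and its p-value — is attached,
#' since small-sample network-cognition regressions frequently violate
#' linearity.
#'
#' @param y numeric cognitive scores (NA allowed; dropped).
#' @param metric numeric metric values, same length.
#' @param sex per-subject `"F"`/`"M"` (or 0/1); coded 0 = F, 1 = M.
#' @param include_sex include the sex covariate (default TRUE).
#' @return Object of class `assoc_result`: a list with a per-term
#'   coefficient table (`B`, `SE`, `beta`, `t`, `p`, `ci_low`, `ci_high`),
#'   model-level `F`, `model_p`, `adj_r2`, `n_used`, `n_dropped`,
#'   `linearity_r`, `linearity_p`, and the underlying `lm` fit.
#' @export
fit_model <- function(y, metric, sex = NULL, include_sex = TRUE) {
  n0 <- length(y)
  if (length(metric) != n0) stop("y and metric lengths differ")
  if (include_sex) {
    if (is.null(sex)) stop("sex covariate requested but not supplied")
    sex_num <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  } else {
    sex_num <- NULL
  }
  keep <- is.finite(y) & is.finite(metric)
  if (include_sex) keep <- keep & is.finite(sex_num)
  n_dropped <- n0 - sum(keep)
  y <- y[keep]; metric <- metric[keep]
  if (include_sex) sex_num <- sex_num[keep]
  n <- length(y)
  n_pred <- 1L + as.integer(include_sex)
  if (n <= n_pred + 1L) stop("too few complete observations for the model")
  if (stats::sd(metric) == 0) stop("constant predictor: metric")
  if (include_sex && stats::sd(sex_num) == 0) stop("constant predictor: sex")

  dat <- data.frame(y = y, metric = metric)
  form <- y ~ metric
  if (include_sex) {
    dat$sex <- sex_num
    form <- y ~ metric + sex
  }
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  datz <- as.data.frame(lapply(dat, function(v) as.numeric(scale(v))))
  fitz <- stats::lm(form, data = datz)
  beta <- stats::coef(fitz)[-1]

  terms <- rownames(sm$coefficients)[-1]
  tab <- data.frame(
    term = terms,
    B = sm$coefficients[-1, 1],
    SE = sm$coefficients[-1, 2],
    beta = as.numeric(beta),
    t = sm$coefficients[-1, 3],
    p = sm$coefficients[-1, 4],
    ci_low = ci[-1, 1],
    ci_high = ci[-1, 2],
    row.names = NULL, stringsAsFactors = FALSE)

  fstat <- sm$fstatistic
  model_p <- as.numeric(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE))
  res <- stats::residuals(fit)
  fit2 <- stats::fitted(fit)^2
  lin <- if (stats::sd(fit2) > 0) {
    ct <- stats::cor.test(res, fit2)
    c(ct$estimate, ct$p.value)
  } else c(NA_real_, NA_real_)

  structure(list(
    coefficients = tab,
    F = as.numeric(fstat[1]), df = as.numeric(fstat[2:3]),
    model_p = model_p, adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
    n_used = n, n_dropped = n_dropped,
    linearity_r = as.numeric(lin[1]), linearity_p = as.numeric(lin[2]),
    include_sex = include_sex, fit = fit), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> n = %d (%d dropped), F(%g,%g) = %.3f, p = %.3f, adj R2 = %.3f\n",
              x$n_used, x$n_dropped, x$df[1], x$df[2], x$F, x$model_p,
              x$adj_r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Spearman rank correlation between a metric and a cognitive score
#'
#' Non-parametric fallback used when regression linearity assumptions fail;
#' tie-corrected, with the t-approximation p-value.
#'
#' @param x,y numeric vectors, length >= 4, neither constant.
#' @return List with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = as.numeric(ct$estimate), p = ct$p.value)
}

#' Pearson chi-square statistic of a 2x2 contingency table
#'
#' Without continuity correction (df = 1), e.g. for a sex-by-group
#' demographics comparison.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `statistic`, `df` and `p`.
#' @export
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = as.numeric(ct$statistic), df = as.numeric(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg correction over association models
#'
#' Adjusts the metric-term p-values across a family of regression models.
#'
#' @param p numeric vector of p-values (the metric term of each model).
#' @return BH-adjusted p-values, same order.
#' @export
fdr_models <- function(p) {
  if (!is.numeric(p) || length(p) == 0) stop("p must be a non-empty numeric vector")
  stats::p.adjust(p, method = "BH")
}

#' Default association model layout
#'
#' The standard seven-model family linking band-specific graph metrics to
#' cognition: modularity against working memory in both bands, and
#' modularity/global/local efficiency against processing speed.
#'
#' @return data.frame with columns `model`, `dv`, `band`, `metric`.
#' @export
default_model_spec <- function() {
  data.frame(
    model = 1:7,
    dv = c("WMI", "PSI", "PSI", "WMI", "PSI", "PSI", "PSI"),
    band = c("theta", "theta", "theta", "delta", "delta", "delta", "delta"),
    metric = c("modularity", "global_efficiency", "local_efficiency",
               "modularity", "modularity", "global_efficiency",
               "local_efficiency"),
    stringsAsFactors = FALSE)
}

#' Fit the full family of metric-cognition regressions
#'
#' For each model in `models`, extracts each subject's metric at the
#' selected density (from [select_threshold()] output or a fixed density),
#' fits [fit_model()], and applies [fdr_models()] across the metric-term
#' p-values of the family.
#'
#' @param metrics long-format table from [metric_table()].
#' @param cohort data.frame with `subject_id`, `sex`, and the cognitive
#'   score columns named in `models$dv`.
#' @param selection data.frame with `analysis` (`"band.metric"`) and
#'   `threshold`, as from [select_threshold()]; or a single numeric density
#'   applied to all models.
#' @param models model layout (default [default_model_spec()]).
#' @param include_sex include the sex covariate (default TRUE).
#' @return List with `table` (one row per model term, Table-style columns
#'   plus `p_fdr` on metric terms), `fits` (the `assoc_result` objects) and
#'   `spearman` (rho/p per model).
#' @export
run_association <- function(metrics, cohort, selection,
                            models = default_model_spec(),
                            include_sex = TRUE) {
  get_thr <- function(band, metric) {
    if (is.numeric(selection)) return(selection[1])
    key <- paste(band, metric, sep = ".")
    thr <- selection$threshold[selection$analysis == key]
    if (length(thr) != 1) stop("no selected threshold for ", key)
    thr
  }
  fits <- list()
  sp <- list()
  rows <- list()
  for (i in seq_len(nrow(models))) {
    mrow <- models[i, ]
    thr <- get_thr(mrow$band, mrow$metric)
    sub <- metrics[metrics$band == mrow$band &
                     abs(metrics$threshold - thr) < 1e-9, ]
    mv <- sub[[mrow$metric]][match(cohort$subject_id, sub$subject_id)]
    if (anyNA(mv)) stop("missing metric values for model ", mrow$model)
    y <- cohort[[mrow$dv]]
    fit <- fit_model(y, mv, sex = cohort$sex, include_sex = include_sex)
    fits[[i]] <- fit
    keepxy <- is.finite(y)
    sp[[i]] <- spearman_assoc(mv[keepxy], y[keepxy])
    co <- fit$coefficients
    co$model <- mrow$model
    co$dv <- mrow$dv
    co$predictor <- ifelse(co$term == "metric",
                           paste(mrow$band, mrow$metric, sep = "."), co$term)
    co$threshold <- thr
    rows[[i]] <- co
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("model", "dv", "predictor", "threshold", "B", "SE", "beta",
                 "t", "p", "ci_low", "ci_high")]
  is_metric <- tab$predictor != "sex"
  tab$p_fdr <- NA_real_
  tab$p_fdr[is_metric] <- fdr_models(tab$p[is_metric])
  spearman <- data.frame(
    model = models$model,
    rho = vapply(sp, `[[`, numeric(1), "rho"),
    p = vapply(sp, `[[`, numeric(1), "p"))
  list(table = tab, fits = fits, spearman = spearman)
}
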