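fake_mtpc <- function(tvec, th = c(0.10, 0.14, 0.18)) {
  structure(list(thresholds = th, t_observed = tvec), class = "mtpc_result")
}

test_that("threshold selection takes the argmax t, ties toward lower density", {
  expect_equal(select_threshold(fake_mtpc(c(1.0, 2.5, 2.0))), 0.14)
  expect_equal(select_threshold(fake_mtpc(c(1, 1, 1))), 0.10)
  sel <- select_threshold(list(a = fake_mtpc(c(0, 3, 1)),
                               b = fake_mtpc(c(2, 1, 0))))
  expect_equal(sel$threshold, c(0.14, 0.10))
  expect_equal(sel$analysis, c("a", "b"))
})

test_that("OLS association recovers exact and standardized coefficients", {
  set.seed(44)
  n <- 20
  metric <- rnorm(n)
  sex <- rep(c("F", "M"), each = n / 2)
  # exactly linear response: perfect fit
  y <- 3 + 2 * metric + 5 * (sex == "M")
  # a perfect fit makes summary.lm warn; the point here is the exactness
  fit <- suppressWarnings(fit_model(y, metric, sex))
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit$fit))), 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$B[fit$coefficients$term == "metric"], 2,
               tolerance = 1e-8)
  # single-predictor standardized beta equals the Pearson correlation
  y2 <- 1 + metric + rnorm(n)
  f2 <- fit_model(y2, metric, include_sex = FALSE)
  expect_equal(f2$coefficients$beta[1], cor(y2, metric), tolerance = 1e-10)
  # CI brackets B; adjusted R2 below R2
  expect_true(with(f2$coefficients, ci_low[1] <= B[1] && B[1] <= ci_high[1]))
  expect_lte(f2$adj_r2, f2$r2)
  expect_error(fit_model(y, rep(1, n), sex), "constant predictor: metric")
})

test_that("subjects missing the score are dropped listwise and counted", {
  set.seed(45)
  y <- rnorm(12); y[3] <- NA
  metric <- rnorm(12)
  sex <- rep(c("F", "M"), 6)
  fit <- fit_model(y, metric, sex)
  expect_equal(fit$n_used, 11)
  expect_equal(fit$n_dropped, 1)
})

test_that("confidence intervals attain nominal coverage in simulation", {
  set.seed(46)
  hits <- 0
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    n <- 22
    metric <- rnorm(n)
    sexM <- rbinom(n, 1, 0.5)
    y <- 100 - 8 * metric - 4 * sexM + rnorm(n, sd = 10)
    fit <- fit_model(y, metric, sexM)
    co <- fit$coefficients[fit$coefficients$term == "metric", ]
    if (co$ci_low <= -8 && -8 <= co$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.93)
})

test_that("sex covariate orthogonal to the metric leaves its slope stable", {
  set.seed(47)
  n <- 200
  metric <- rnorm(n)
  sexM <- rep(0:1, each = n / 2)      # balanced, independent of metric
  y <- 50 + 6 * metric + 3 * sexM + rnorm(n, sd = 2)
  b_with <- fit_model(y, metric, sexM)$coefficients
  b_wo <- fit_model(y, metric, include_sex = FALSE)$coefficients
  expect_equal(b_with$B[b_with$term == "metric"],
               b_wo$B[b_wo$term == "metric"], tolerance = 0.05)
})

test_that("Spearman correlation handles monotone transforms and direction", {
  x <- 1:11
  expect_equal(spearman_assoc(x, exp(x))$rho, 1)
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  # independent draws exceed the 5% two-sided critical value rarely
  set.seed(48)
  exceed <- mean(replicate(300, {
    abs(spearman_assoc(rnorm(11), rnorm(11))$rho) >= 0.602
  }))
  expect_lte(exceed, 0.06 + 0.03)
  expect_error(spearman_assoc(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
})

test_that("2x2 chi-square equals the direct Sum((O-E)^2/E) formula", {
  direct_chisq <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  expect_equal(chisq_2x2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  for (s in 1:5) {
    set.seed(s)
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(suppressWarnings(chisq_2x2(tab))$statistic,
                 direct_chisq(tab), tolerance = 1e-12)
  }
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(chisq_2x2(matrix(1:6, 3, 2)), "2x2")
})

test_that("model-family FDR is BH and order-preserving", {
  p <- c(0.032, 0.742, 0.947, 0.564, 0.836, 0.613, 0.977)
  adj <- fdr_models(p)
  expect_equal(adj[1], min(1, 0.032 * 7 / 1))
  expect_equal(fdr_models(0.04), 0.04)
  # monotone: sorting by raw p sorts the adjusted values too
  expect_true(!is.unsorted(adj[order(p)]))
})

test_that("the association driver fits the model family on selected thresholds", {
  set.seed(50)
  subj <- sprintf("sub-%02d", 1:16)
  grid <- expand.grid(subject_id = subj, band = c("delta", "theta"),
                      threshold = default_thresholds(),
                      stringsAsFactors = FALSE)
  grid$modularity <- rnorm(nrow(grid), 0.3, 0.05)
  grid$global_efficiency <- rnorm(nrow(grid), 0.6, 0.05)
  grid$local_efficiency <- rnorm(nrow(grid), 0.5, 0.05)
  cohort <- data.frame(
    subject_id = subj, group = rep(c("patient", "control"), each = 8),
    sex = rep(c("F", "M"), 8), age = runif(16, 6, 16),
    WMI = rnorm(16, 100, 15), PSI = rnorm(16, 100, 15),
    stringsAsFactors = FALSE)
  res <- run_association(grid, cohort, selection = 0.14)
  expect_equal(nrow(res$table), 14)            # 7 models x 2 terms
  expect_equal(sum(!is.na(res$table$p_fdr)), 7) # FDR over metric terms only
  expect_equal(nrow(res$spearman), 7)
  expect_true(all(res$table$ci_low <= res$table$B &
                    res$table$B <= res$table$ci_high))
})
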