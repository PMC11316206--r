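test_that("cohort configuration validates covariances, bands and counts", {
  expect_s3_class(small_cohort_config(), "cohort_config")
  # non-PSD envelope covariance is rejected
  bad <- matrix(0.99, 4, 4); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(
    cohort_config(n_regions = 4, envelope_cov_control = bad,
                  module_assignment = rep(1:2, each = 2)),
    "positive semi-definite")
  # Nyquist violation
  expect_error(small_cohort_config(fs = 12), "Nyquist")
  # degenerate band
  expect_error(small_cohort_config(bands = list(bad = c(4, 2))), "degenerate")
  # module assignment must cover all regions
  expect_error(cohort_config(n_regions = 8, module_assignment = rep(1, 5)),
               "cover every region")
  expect_error(small_cohort_config(n_per_group = 0), "positive")
})

test_that("the default configuration encodes the study conditions", {
  cfg <- cohort_config()
  expect_equal(cfg$n_per_group, 12)
  expect_equal(cfg$n_regions, 68)
  expect_equal(cfg$epoch_seconds, 10)
  expect_equal(unname(cfg$n_epochs_mean), c(37.5, 37.33))
  expect_equal(cfg$bands, list(delta = c(1, 4), theta = c(5, 8)))
  expect_equal(dim(cfg$envelope_cov_control), c(68, 68))
  # the patient within-module coupling is reduced, between-module untouched
  same <- outer(cfg$module_assignment, cfg$module_assignment, `==`)
  diag(same) <- FALSE
  expect_true(all(cfg$envelope_cov_patient[same] <
                    cfg$envelope_cov_control[same]))
  expect_equal(cfg$envelope_cov_patient[!same & upper.tri(same)],
               cfg$envelope_cov_control[!same & upper.tri(same)])
})

test_that("generation is deterministic and subjects reproduce independently", {
  cfg <- small_cohort_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ts[[1]]$epochs, b$ts[[1]]$epochs)
  expect_identical(a$ts[[6]]$epochs, b$ts[[6]]$epochs)
  expect_identical(a$ground_truth$gt_metric, b$ground_truth$gt_metric)
  # a different seed changes the data
  c2 <- generate_cohort(small_cohort_config(seed = 124))
  expect_false(identical(a$ts[[1]]$epochs, c2$ts[[1]]$epochs))
})

test_that("cohort table is well-formed", {
  sim <- generate_cohort(small_cohort_config(n_per_group = 4, seed = 7),
                         generate_ts = FALSE)
  tab <- sim$cohort
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$group), c("patient", "control"))
  expect_true(all(is.finite(tab$WMI) & is.finite(tab$PSI)))
  expect_true(all(tab$sex %in% c("F", "M")))
  expect_false(anyDuplicated(tab$subject_id) > 0)
  # sex counts can be pinned to a fixed ratio per group
  sim2 <- generate_cohort(
    small_cohort_config(n_per_group = 12, seed = 7,
                        sex_counts = list(patient = c(F = 7, M = 5),
                                          control = c(F = 4, M = 8))),
    generate_ts = FALSE)
  expect_equal(sum(sim2$cohort$sex == "F" & sim2$cohort$group == "patient"), 7)
  expect_equal(sum(sim2$cohort$sex == "F" & sim2$cohort$group == "control"), 4)
})

test_that("uncoupled regions yield AEC centred on zero", {
  cfg <- small_cohort_config(
    n_per_group = 1, n_regions = 6, n_epochs = 37, epoch_seconds = 10,
    seed = 55, within_r = 0, between_r = 0,
    module_assignment = rep(1:2, each = 3))
  sim <- generate_cohort(cfg)
  m_raw <- local({
    pts <- sim$ts[[1]]
    mats <- lapply(seq_len(dim(pts$epochs)[1]), function(e) {
      ep <- pts$epochs[e, , ]
      rownames(ep) <- pts$region_labels
      aec_epoch(band_analytic(ep, pts$fs, c(5, 8)))
    })
    average_epochs(mats)
  })
  off <- m_raw[upper.tri(m_raw)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("recovered envelopes correlate with the planted ones at high SNR", {
  cfg <- small_cohort_config(n_per_group = 1, n_regions = 4, n_epochs = 3,
                             epoch_seconds = 10, seed = 66, noise_sd = 0.05,
                             bands = list(theta = c(5, 8)))
  sim <- generate_cohort(cfg, keep_planted_envelopes = TRUE)
  pts <- sim$ts[[1]]
  planted <- sim$ground_truth$planted_envelopes[[1]]$theta
  fs <- pts$fs
  core <- (fs + 1):(dim(pts$epochs)[3] - fs)
  rs <- c()
  for (e in 1:3) {
    ep <- pts$epochs[e, , ]
    env <- envelope(band_analytic(ep, fs, c(5, 8)))
    for (r in 1:4) rs <- c(rs, cor(env[r, core], planted[e, r, core]))
  }
  expect_gt(mean(rs), 0.8)
})

test_that("planted two-module structure is recovered by the full chain", {
  cfg <- cohort_config(
    n_per_group = 1, n_regions = 68,
    module_assignment = rep(1:2, each = 34),
    within_r = 0.8, between_r = 0, noise_sd = 0.05,
    n_epochs_mean = c(patient = 12, control = 12),
    n_epochs_sd = c(patient = 0, control = 0), n_epochs_min = 12,
    epoch_seconds = 5, fs = 100, bands = list(delta = c(1, 4)),
    seed = 77)
  sim <- generate_cohort(cfg)
  # use the control subject (index 2): full planted coupling
  W <- subject_connectivity(sim$ts[[2]], c(1, 4), "delta")
  G <- proportional_threshold(W, 0.30)
  memb <- modularity_q(G, n_restarts = 10, seed = 1)$membership
  ari <- adjusted_rand_index(memb, cfg$module_assignment)
  expect_gt(ari, 0.9)
})

test_that("cognitive scores regress back to the generating coefficients", {
  # two modules of 4 regions so the planted networks of the two groups have
  # distinct (and non-zero) local efficiency at the ground-truth density
  cfg <- small_cohort_config(n_per_group = 40, seed = 88,
                             effect_size_local = 0.4,
                             module_assignment = rep(1:2, each = 4))
  sim <- generate_cohort(cfg, generate_ts = FALSE)
  gt <- sim$ground_truth
  metric <- gt$gt_metric[sim$cohort$group]
  sexM <- as.numeric(sim$cohort$sex == "M")
  fit <- fit_model(sim$cohort$WMI, metric, sexM)
  co <- fit$coefficients[fit$coefficients$term == "metric", ]
  truth <- gt$cog_model$WMI$beta_metric
  expect_true(co$ci_low <= truth && truth <= co$ci_high)
})
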