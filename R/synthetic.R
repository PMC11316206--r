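#' Build a block-modular envelope correlation matrix
#'
#' Unit-diagonal correlation matrix with constant coupling `within_r`
#' inside modules and `between_r` across modules.
#'
#' @param module_assignment integer module id per region.
#' @param within_r,between_r envelope correlations within / between
#'   modules.
#' @return Symmetric PSD matrix with unit diagonal.
#' @export
modular_envelope_cov <- function(module_assignment, within_r = 0.35,
                                 between_r = 0.05) {
  n <- length(module_assignment)
  same <- outer(module_assignment, module_assignment, `==`)
  S <- ifelse(same, within_r, between_r)
  diag(S) <- 1
  S
}

#' Configuration of a synthetic MEG cohort
#'
#' Defines the study conditions the generator emulates: two groups of
#' `n_per_group` subjects, roughly 37 non-overlapping 10-s epochs per
#' subject, and narrowband delta (1-4 Hz) and theta (5-8 Hz) signals whose
#' amplitude envelopes follow a planted modular correlation structure.  In
#' the patient group the within-module envelope coupling is scaled down by
#' `effect_size_local`, producing a ground-truth reduction in local network
#' connectivity.  Cognitive scores (WMI, PSI) follow a linear model on the
#' group's noise-free planted graph metric plus a sex effect plus Gaussian
#' noise.
#'
#' The default sampling rate is 250 Hz, a decimated stand-in for 2 kHz
#' acquisition: the bands of interest lie at or below 8 Hz, so nothing is
#' lost at desk scale, and every filter scales with `fs`.
#'
#' @param n_per_group subjects per group (default 12).
#' @param n_epochs_mean,n_epochs_sd named vectors (`patient`, `control`)
#'   for the per-subject epoch-count draw; defaults 37.5/1.6 and
#'   37.33/1.1.  Counts are rounded Gaussians clipped to `n_epochs_min`.
#' @param n_epochs_min lower clip for epoch counts (default 30).
#' @param epoch_seconds epoch duration (default 10 s).
#' @param fs sampling rate in Hz (default 250).
#' @param bands named list of `(low, high)` Hz pairs; defaults delta
#'   `c(1,4)` and theta `c(5,8)`.
#' @param n_regions number of parcels (default 68 = Desikan-Killiany).
#' @param module_assignment integer module id per region; default 4 equal
#'   modules.
#' @param envelope_cov_control,envelope_cov_patient region x region
#'   positive-semidefinite envelope correlation matrices with unit
#'   diagonal; defaults are block-modular with `within_r`/`between_r`,
#'   the patient within-module coupling scaled by `effect_size_local`.
#' @param within_r,between_r default modular coupling strengths.
#' @param effect_size_local multiplicative reduction of patients'
#'   within-module coupling (default 0.6; 1 = no group effect).
#' @param envelope_sigma scale of the log-envelope map
#'   `exp(envelope_sigma * latent)`; default `sqrt(log(1.25))` gives an
#'   envelope coefficient of variation of 0.5.
#' @param env_cutoff_hz low-pass cut-off of the latent envelope process
#'   (default 0.5 Hz: envelopes fluctuate slowly relative to the carriers).
#' @param noise_sd broadband sensor-like additive noise SD, relative to
#'   unit-SD carriers (default 0.2).
#' @param cog_model list with `metric` (which ground-truth graph metric
#'   drives cognition), `threshold` (density at which it is evaluated) and,
#'   per score (`WMI`, `PSI`), `intercept`, `beta_metric`, `beta_sex` and
#'   `sd`.
#' @param sex_counts optional named list (`patient`, `control`) of
#'   `c(F=, M=)` counts; default: sex is Bernoulli(0.5) per subject.
#' @param seed top-level RNG seed; expands to per-subject child seeds so
#'   subjects are reproducible independently.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 12,
                          n_epochs_mean = c(patient = 37.5, control = 37.33),
                          n_epochs_sd = c(patient = 1.6, control = 1.1),
                          n_epochs_min = 30,
                          epoch_seconds = 10,
                          fs = 250,
                          bands = list(delta = c(1, 4), theta = c(5, 8)),
                          n_regions = 68,
                          module_assignment = NULL,
                          envelope_cov_control = NULL,
                          envelope_cov_patient = NULL,
                          within_r = 0.35,
                          between_r = 0.05,
                          effect_size_local = 0.6,
                          envelope_sigma = sqrt(log(1.25)),
                          env_cutoff_hz = 0.5,
                          noise_sd = 0.2,
                          cog_model = NULL,
                          sex_counts = NULL,
                          seed = 1) {
  if (is.null(module_assignment)) {
    n_mod <- if (n_regions %% 4 == 0) 4L else 2L
    module_assignment <- rep(seq_len(n_mod), each = ceiling(n_regions / n_mod),
                             length.out = n_regions)[seq_len(n_regions)]
    module_assignment <- sort(module_assignment)
  }
  if (length(module_assignment) != n_regions) {
    stop("module_assignment must cover every region exactly once")
  }
  if (is.null(envelope_cov_control)) {
    envelope_cov_control <- modular_envelope_cov(module_assignment,
                                                 within_r, between_r)
  }
  if (is.null(envelope_cov_patient)) {
    same <- outer(module_assignment, module_assignment, `==`)
    S <- envelope_cov_control
    S[same] <- S[same] * effect_size_local
    diag(S) <- 1
    envelope_cov_patient <- S
  }
  if (is.null(cog_model)) {
    cog_model <- list(
      metric = "local_efficiency", threshold = 0.14,
      WMI = list(intercept = 92, beta_metric = 40, beta_sex = -4, sd = 12),
      PSI = list(intercept = 90, beta_metric = 45, beta_sex = -3, sd = 12))
  }
  cfg <- structure(list(
    n_per_group = n_per_group, n_epochs_mean = n_epochs_mean,
    n_epochs_sd = n_epochs_sd, n_epochs_min = n_epochs_min,
    epoch_seconds = epoch_seconds, fs = fs, bands = bands,
    n_regions = n_regions, module_assignment = module_assignment,
    envelope_cov_control = envelope_cov_control,
    envelope_cov_patient = envelope_cov_patient,
    within_r = within_r, between_r = between_r,
    effect_size_local = effect_size_local,
    envelope_sigma = envelope_sigma, env_cutoff_hz = env_cutoff_hz,
    noise_sd = noise_sd, cog_model = cog_model, sex_counts = sex_counts,
    seed = seed), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

check_psd_corr <- function(S, name) {
  if (!is_square_symmetric(S, tol = 1e-8)) {
    stop(name, " must be a symmetric matrix")
  }
  if (max(abs(diag(S) - 1)) > 1e-8) stop(name, " must have a unit diagonal")
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 name, ev))
  }
  invisible(TRUE)
}

#' Validate a cohort configuration
#'
#' @param cfg a `cohort_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_per_group < 1) stop("n_per_group must be positive")
    if (any(n_epochs_mean <= 0) || any(n_epochs_sd < 0)) {
      stop("epoch count parameters must be positive")
    }
    if (abs(epoch_seconds * fs - round(epoch_seconds * fs)) > 1e-9) {
      stop("epoch_seconds * fs must be an integer sample count")
    }
    for (bn in names(bands)) {
      b <- bands[[bn]]
      if (b[1] <= 0 || b[1] >= b[2]) stop("degenerate band: ", bn)
      if (b[2] >= fs / 2) {
        stop(sprintf("band '%s' upper edge %g Hz violates Nyquist at fs = %g",
                     bn, b[2], fs))
      }
    }
    if (n_regions == length(dk_region_labels())) {
      check_region_labels(dk_region_labels())
    }
    check_psd_corr(envelope_cov_control, "envelope_cov_control")
    check_psd_corr(envelope_cov_patient, "envelope_cov_patient")
    if (nrow(envelope_cov_control) != n_regions) {
      stop("envelope covariance dimension does not match n_regions")
    }
  })
  invisible(cfg)
}

smooth_rows <- function(Z, fs, cutoff) {
  bf <- butter_sos(2, cutoff / (fs / 2), "low")
  t(apply(Z, 1L, function(r) {
    s <- signal::filtfilt(bf, r)
    (s - mean(s)) / stats::sd(s)
  }))
}

# One subject's epoched broadband signal with planted band envelopes.
gen_subject_ts <- function(child_seed, Sigma, cfg, subject_id, labels) {
  set.seed(child_seed)
  grp_key <- attr(Sigma, "grp_key")
  n_ep <- max(cfg$n_epochs_min,
              round(stats::rnorm(1, cfg$n_epochs_mean[[grp_key]],
                                 cfg$n_epochs_sd[[grp_key]])))
  S <- as.integer(round(cfg$epoch_seconds * cfg$fs))
  n <- cfg$n_regions
  L <- t(chol(Sigma + diag(1e-9, n)))
  bands <- cfg$bands
  carriers_bf <- lapply(bands, function(b) butter_sos(4, b / (cfg$fs / 2), "pass"))
  arr <- array(0, dim = c(n_ep, n, S))
  envs <- vector("list", length(bands))
  names(envs) <- names(bands)
  for (bn in names(bands)) envs[[bn]] <- array(0, dim = c(n_ep, n, S))
  for (e in seq_len(n_ep)) {
    total <- matrix(0, n, S)
    for (bn in names(bands)) {
      Z <- matrix(stats::rnorm(n * S), n, S)
      latent <- L %*% smooth_rows(Z, cfg$fs, cfg$env_cutoff_hz)
      env <- exp(cfg$envelope_sigma * latent)
      C <- matrix(stats::rnorm(n * S), n, S)
      # constant-modulus carrier: cosine of the instantaneous phase of
      # band-limited noise; its own amplitude is flat, so the band signal's
      # Hilbert envelope is the planted envelope (up to the additive noise)
      carrier <- t(apply(C, 1L, function(r) {
        s <- signal::filtfilt(carriers_bf[[bn]], r)
        a <- analytic_signal(s)
        f <- Re(a / Mod(a))
        f / stats::sd(f)
      }))
      total <- total + env * carrier
      envs[[bn]][e, , ] <- env
    }
    arr[e, , ] <- total + cfg$noise_sd * matrix(stats::rnorm(n * S), n, S)
  }
  list(pts = parcel_ts(arr, cfg$fs, labels, subject_id),
       planted_envelopes = envs, n_epochs = n_ep)
}

planted_metric <- function(Sigma, metric, threshold, seed = 1) {
  # Noise-free planted network: correlations are already in [0, 1], so the
  # empirical divide-by-max step is skipped — it would cancel the planted
  # within-module scaling and hide the true group effect.
  W <- Sigma
  diag(W) <- 0
  W[W < 0] <- 0
  G <- proportional_threshold(W, threshold)
  switch(metric,
         local_efficiency = local_efficiency_mean(G),
         global_efficiency = global_efficiency(G),
         modularity = modularity_q(G, n_restarts = 20, seed = seed)$Q,
         stop("unknown ground-truth metric: ", metric))
}

#' Generate a synthetic cohort
#'
#' Produces, per subject, an epoched broadband parcel time series in which
#' each band's signal is a slowly varying lognormal envelope (with the
#' group's planted cross-region envelope correlation) multiplying an
#' independent narrowband carrier, plus broadband noise; a cohort table
#' with group, sex, age and cognitive scores generated from the configured
#' linear model on the group's noise-free planted graph metric; and the
#' ground truth needed for parameter-recovery tests.  The same seed gives
#' byte-identical output; subjects are generated from independent child
#' seeds.
#'
#' @param cfg a [cohort_config()].
#' @param keep_planted_envelopes retain each subject's planted envelope
#'   arrays in the ground truth (memory-heavy; default FALSE).
#' @param generate_ts generate the parcel time series (default TRUE); set
#'   FALSE to draw only the cohort table and ground truth, e.g. for
#'   cognitive-model recovery studies.
#' @return List with `ts` (list of [parcel_ts]), `cohort` (data.frame:
#'   `subject_id, group, sex, age, WMI, PSI`) and `ground_truth` (planted
#'   envelope correlation matrices, module partition, expected direction of
#'   group differences, generating cognitive coefficients, per-group
#'   planted metric values, per-subject seeds).
#' @export
generate_cohort <- function(cfg, keep_planted_envelopes = FALSE,
                            generate_ts = TRUE) {
  validate_cohort_config(cfg)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n_tot <- 2L * cfg$n_per_group
  groups <- rep(c("patient", "control"), each = cfg$n_per_group)
  ids <- sprintf("sub-%02d", seq_len(n_tot))
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)

  if (is.null(cfg$sex_counts)) {
    sex <- ifelse(stats::runif(n_tot) < 0.5, "F", "M")
  } else {
    sex <- character(n_tot)
    for (g in c("patient", "control")) {
      idx <- which(groups == g)
      pool <- rep(c("F", "M"), times = cfg$sex_counts[[g]][c("F", "M")])
      sex[idx] <- sample(pool)
    }
  }
  age <- round(stats::runif(n_tot, 6.2, 15.8), 1)

  gt_metric <- c(
    patient = planted_metric(cfg$envelope_cov_patient, cfg$cog_model$metric,
                             cfg$cog_model$threshold),
    control = planted_metric(cfg$envelope_cov_control, cfg$cog_model$metric,
                             cfg$cog_model$threshold))
  scores <- list()
  for (sc in c("WMI", "PSI")) {
    cm <- cfg$cog_model[[sc]]
    scores[[sc]] <- cm$intercept +
      cm$beta_metric * gt_metric[groups] +
      cm$beta_sex * as.numeric(sex == "M") +
      stats::rnorm(n_tot, 0, cm$sd)
  }
  cohort <- data.frame(subject_id = ids, group = groups, sex = sex, age = age,
                       WMI = round(as.numeric(scores$WMI), 1),
                       PSI = round(as.numeric(scores$PSI), 1),
                       stringsAsFactors = FALSE)

  labels <- if (cfg$n_regions == length(dk_region_labels())) {
    dk_region_labels()
  } else {
    paste0("region", seq_len(cfg$n_regions))
  }
  Sig_p <- cfg$envelope_cov_patient; attr(Sig_p, "grp_key") <- "patient"
  Sig_c <- cfg$envelope_cov_control; attr(Sig_c, "grp_key") <- "control"
  planted_env <- if (keep_planted_envelopes) vector("list", n_tot)
  if (generate_ts) {
    ts <- vector("list", n_tot)
    names(ts) <- ids
    for (i in seq_len(n_tot)) {
      Sig <- if (groups[i] == "patient") Sig_p else Sig_c
      g <- gen_subject_ts(subj_seeds[i], Sig, cfg, ids[i], labels)
      ts[[i]] <- g$pts
      if (keep_planted_envelopes) planted_env[[i]] <- g$planted_envelopes
    }
    if (keep_planted_envelopes) names(planted_env) <- ids
  } else {
    ts <- NULL
  }

  ground_truth <- list(
    envelope_cor = list(patient = cfg$envelope_cov_patient,
                        control = cfg$envelope_cov_control),
    module_assignment = cfg$module_assignment,
    expected_direction = "patient_lt_control",
    cog_model = cfg$cog_model,
    gt_metric = gt_metric,
    subject_seeds = stats::setNames(subj_seeds, ids),
    planted_envelopes = if (keep_planted_envelopes) planted_env)

  list(ts = ts, cohort = cohort, ground_truth = ground_truth)
}
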