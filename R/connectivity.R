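#' Orthogonalize one analytic signal with respect to another
#'
#' Removes the zero-lag collinear (leakage) component of `y` with respect to
#' `x` in the time domain: at each sample,
#' `y_perp(t) = Im( y(t) * Conj(x(t)) / |x(t)| )`.  Any shared
#' instantaneous component (as produced by source leakage, which mixes
#' signals with zero lag) is cancelled, so a scaled copy of `x`
#' orthogonalizes to exactly zero, while a 90-degree-rotated copy is fully
#' retained.  Samples where `|x| = 0` contribute 0 by convention.
#'
#' @param x,y complex analytic signals of equal length; `x` is the
#'   reference and must not be identically zero.
#' @return Real numeric vector `y_perp`, same length.
#' @export
orthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  mx <- Mod(x)
  if (all(mx == 0)) stop("reference signal x is identically zero")
  ratio <- Conj(x) / mx
  ratio[mx == 0] <- 0 + 0i
  Im(y * ratio)
}

#' Leakage-corrected amplitude envelope correlation for one epoch
#'
#' For every ordered region pair (i, j), correlates the envelope of region i
#' with the envelope of region j after orthogonalizing j's analytic signal
#' with respect to i's; the two directions are then averaged to give a
#' symmetric matrix with zero diagonal.  Orthogonalization can be switched
#' off to obtain plain envelope correlation.  Because the band-pass and
#' Hilbert transforms ring at epoch boundaries, the first and last
#' `edge_trim_s` seconds of each envelope are excluded from the correlation.
#'
#' @param a an `analytic_epoch` from [band_analytic()].
#' @param edge_trim_s seconds to drop at each end of the envelope before
#'   correlating (default 1; set 0 to disable).
#' @param orthogonalize_pairs if `FALSE`, skip leakage correction.
#' @return Symmetric `region x region` matrix of raw AEC values in
#'   `[-1, 1]`, diagonal 0, with attributes `stage = "raw"` and `band`.
#'   Region pairs with a zero-variance envelope are set to 0 with a warning.
#' @export
aec_epoch <- function(a, edge_trim_s = 1, orthogonalize_pairs = TRUE) {
  stopifnot(inherits(a, "analytic_epoch"))
  A <- a$signal
  n <- nrow(A)
  if (n < 2) stop("need at least 2 regions")
  n_trim <- round(edge_trim_s * a$fs)
  keep <- seq_len(ncol(A))
  if (n_trim > 0) {
    if (2 * n_trim + 8 > ncol(A)) stop("edge trim leaves too few samples")
    keep <- (n_trim + 1L):(ncol(A) - n_trim)
  }
  env <- Mod(A)
  D <- matrix(0, n, n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    mi <- env[i, ]
    if (orthogonalize_pairs) {
      ratio <- Conj(A[i, ]) / mi
      ratio[mi == 0] <- 0 + 0i
      env_perp <- abs(Im(A * matrix(ratio, n, ncol(A), byrow = TRUE)))
      # a numerically null residual (e.g. an exact scaled copy of region i)
      # carries only float noise; its correlation is defined as 0
      tiny <- sqrt(rowMeans(env_perp^2)) < 1e-8 * sqrt(rowMeans(env^2))
    } else {
      env_perp <- env
      tiny <- rep(FALSE, n)
    }
    r <- suppressWarnings(
      as.numeric(stats::cor(mi[keep], t(env_perp[, keep, drop = FALSE]))))
    if (anyNA(r) || any(tiny[-i])) degenerate <- TRUE
    r[is.na(r) | tiny] <- 0
    D[i, ] <- r
  }
  if (degenerate) {
    warning("zero-variance envelope encountered; affected correlations set to 0")
  }
  out <- (D + t(D)) / 2
  diag(out) <- 0
  dimnames(out) <- list(rownames(A), rownames(A))
  attr(out, "stage") <- "raw"
  attr(out, "band") <- a$band
  out
}

#' Average per-epoch connectivity matrices
#'
#' Element-wise weighted mean across epochs.  With equal-length epochs the
#' default uniform weights coincide with duration weighting.
#'
#' @param mats list of same-shaped raw connectivity matrices.
#' @param weights optional non-negative weights, one per epoch; default
#'   uniform.
#' @return The weighted mean matrix, stage `"raw"`.
#' @export
average_epochs <- function(mats, weights = NULL) {
  if (length(mats) == 0) stop("no matrices to average")
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    stop("matrices differ in shape")
  }
  w <- weights %||% rep(1, length(mats))
  if (length(w) != length(mats) || any(w < 0) || sum(w) == 0) {
    stop("invalid weights")
  }
  w <- w / sum(w)
  out <- Reduce(`+`, Map(function(m, wi) m * wi, mats, w))
  attr(out, "stage") <- "raw"
  attr(out, "band") <- attr(mats[[1]], "band")
  out
}

#' Post-process an averaged connectivity matrix
#'
#' Sets negative correlations to zero, then rescales so the maximum weight
#' is exactly 1 ("0 = no connection, 1 = maximum connectivity").  Division
#' by the maximum (rather than min-max scaling) preserves the meaning of
#' zero.  An all-zero matrix passes through with a warning.
#'
#' @param m symmetric raw connectivity matrix.
#' @return Normalized matrix with entries in `[0, 1]`, zero diagonal,
#'   `stage = "normalized"`.
#' @export
postprocess <- function(m) {
  if (!is_square_symmetric(m)) stop("connectivity matrix must be symmetric")
  band <- attr(m, "band")
  m[m < 0] <- 0
  diag(m) <- 0
  mx <- max(m)
  if (mx > 0) {
    m <- m / mx
  } else {
    warning("all-zero connectivity matrix; normalization skipped")
  }
  attr(m, "stage") <- "normalized"
  attr(m, "band") <- band
  m
}

#' Per-subject band-limited connectivity matrix
#'
#' Full connectivity stage for one subject and one band: per epoch,
#' band-pass + analytic transform then orthogonalized AEC; matrices are
#' averaged across epochs, negatives zeroed and weights normalized to
#' `[0, 1]`.
#'
#' @param pts a [parcel_ts].
#' @param band numeric `(low, high)` Hz.
#' @param band_name label stored with the output (e.g. `"delta"`).
#' @param edge_trim_s,orthogonalize_pairs passed to [aec_epoch()].
#' @param order band-pass filter order.
#' @return Normalized `region x region` matrix with attributes
#'   `subject_id`, `band`, `band_name`, `n_epochs`, `stage`.
#' @export
subject_connectivity <- function(pts, band, band_name = NULL,
                                 edge_trim_s = 1, orthogonalize_pairs = TRUE,
                                 order = 4) {
  stopifnot(inherits(pts, "parcel_ts"))
  n_ep <- dim(pts$epochs)[1]
  mats <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    ep <- pts$epochs[e, , , drop = TRUE]
    if (!is.matrix(ep)) ep <- matrix(ep, nrow = dim(pts$epochs)[2])
    rownames(ep) <- pts$region_labels
    a <- band_analytic(ep, pts$fs, band, order = order)
    mats[[e]] <- aec_epoch(a, edge_trim_s = edge_trim_s,
                           orthogonalize_pairs = orthogonalize_pairs)
  }
  out <- postprocess(average_epochs(mats))
  dimnames(out) <- list(pts$region_labels, pts$region_labels)
  attr(out, "subject_id") <- pts$subject_id
  attr(out, "band_name") <- band_name %||% paste0(band[1], "-", band[2], "Hz")
  attr(out, "n_epochs") <- n_ep
  out
}
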