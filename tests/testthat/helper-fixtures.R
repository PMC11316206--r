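# Shared fixtures: reduced-scale study configurations and independent
# brute-force graph oracles used to pin the weighted metric formulas.

small_cohort_config <- function(n_per_group = 3, n_regions = 8, fs = 100,
                                epoch_seconds = 5, n_epochs = 5, seed = 42,
                                ...) {
  cohort_config(
    n_per_group = n_per_group,
    n_epochs_mean = c(patient = n_epochs, control = n_epochs),
    n_epochs_sd = c(patient = 0, control = 0),
    n_epochs_min = n_epochs,
    epoch_seconds = epoch_seconds, fs = fs, n_regions = n_regions,
    seed = seed, ...)
}

# Exhaustive simple-path shortest distances (independent of igraph/Dijkstra).
# L: symmetric matrix of edge lengths, Inf (or 0-weight) = no edge.
bf_shortest_paths <- function(L) {
  n <- nrow(L)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    rec <- function(node, visited, dist) {
      if (dist < best[s, node]) best[s, node] <<- dist
      for (nb in seq_len(n)) {
        if (is.finite(L[node, nb]) && !(nb %in% visited)) {
          if (dist + L[node, nb] < best[s, nb] + 1e-15) {
            rec(nb, c(visited, nb), dist + L[node, nb])
          }
        }
      }
    }
    rec(s, s, 0)
  }
  best
}

lengths_from_weights <- function(W, exponent = 1) {
  L <- ifelse(W > 0, (1 / W)^exponent, Inf)
  diag(L) <- Inf
  L
}

bf_global_efficiency <- function(W) {
  n <- nrow(W)
  d <- bf_shortest_paths(lengths_from_weights(W))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Independent evaluation of the cube-root weighted local efficiency:
# neighbourhood shortest paths by exhaustive enumeration.
bf_local_efficiency <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (u in seq_len(n)) {
    V <- which(W[u, ] > 0)
    k <- length(V)
    if (k < 2) next
    d <- bf_shortest_paths(lengths_from_weights(W[V, V, drop = FALSE],
                                                exponent = 1 / 3))
    di <- 1 / d
    diag(di) <- 0
    acc <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b) acc <- acc + (W[u, V[a]] * W[u, V[b]])^(1 / 3) * di[a, b]
      }
    }
    vals[u] <- acc / (k * (k - 1))
  }
  mean(vals)
}

random_weighted_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < p_edge
  W[ut[on]] <- runif(sum(on), 0.1, 1)
  W + t(W)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Planted-envelope pair of analytic epochs: two regions whose lognormal
# envelopes have latent correlation rho, riding on independent narrowband
# carriers.  Returns the analytic_epoch for the requested band.
planted_pair_epoch <- function(rho, fs = 100, seconds = 10, band = c(5, 8),
                               sigma = sqrt(log(1.25))) {
  S <- fs * seconds
  bf_env <- signal::butter(2, 0.5 / (fs / 2), type = "low")
  z <- replicate(2, {
    s <- signal::filtfilt(bf_env, rnorm(S))
    (s - mean(s)) / sd(s)
  })
  lat <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  env <- exp(sigma * lat)
  bf_car <- signal::butter(2, band / (fs / 2), type = "pass")
  car <- replicate(2, {
    s <- signal::filtfilt(bf_car, rnorm(S))
    s / sd(s)
  })
  x <- t(env * car)
  band_analytic(x, fs, band)
}
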