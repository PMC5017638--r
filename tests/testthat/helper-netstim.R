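# shared fixtures and independent oracles, built in code at test time

make_regions <- function(n, systems = rep("ctx", n)) {
  data.frame(
    label = sprintf("r%02d", seq_len(n)),
    x_mm = seq_len(n) * 10, y_mm = 0, z_mm = 0,
    volume = 1, system = systems,
    stringsAsFactors = FALSE
  )
}

# symmetric, hollow, nonnegative random weight matrix
rand_symmetric_net <- function(n, seed, density = 0.5, scale = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  vals <- rexp(sum(ut)) * (runif(sum(ut)) < density)
  m[ut] <- vals * scale
  m + t(m)
}

# random Schur-stable matrix (spectral radius <= rho)
rand_stable <- function(n, seed, rho = 0.8, symmetric = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  if (symmetric) m <- (m + t(m)) / 2
  m * (rho / max(Mod(eigen(m, only.values = TRUE)$values)))
}

# brute-force truncated-series Gramian: sum_t A^t B B' (A^t)'
series_gramian <- function(A, B, terms = 500L) {
  W <- tcrossprod(B)
  At <- diag(nrow(A))
  for (t in seq_len(terms)) {
    At <- A %*% At
    W <- W + tcrossprod(At %*% B)
  }
  W
}

# naive per-lag Pearson cross-correlation maximum (double loop)
naive_max_lagged_cor <- function(x, y, max_lag) {
  T <- length(x)
  best <- -Inf; best_lag <- 0L
  for (l in -max_lag:max_lag) {
    if (l >= 0) { xs <- x[1:(T - l)]; ys <- y[(1 + l):T] }
    else { xs <- x[(1 - l):T]; ys <- y[1:(T + l)] }
    r <- suppressWarnings(cor(xs, ys))
    if (is.finite(r) && r > best) { best <- r; best_lag <- l }
  }
  list(r = best, lag = best_lag)
}

# reference Euler integrator in plain R (delays in steps, no noise)
r_reference_wc <- function(A, dsteps, p, P, n_steps, dt, e0 = 0.1, i0 = 0.1) {
  n <- nrow(A)
  S <- function(x, a, th) 1 / (1 + exp(-a * (x - th))) - 1 / (1 + exp(a * th))
  E <- matrix(e0, n, n_steps + 1); I <- matrix(i0, n, n_steps + 1)
  for (t in 1:n_steps) {
    coup <- numeric(n)
    for (j in 1:n) for (k in 1:n) {
      if (A[j, k] != 0) {
        ts <- t - dsteps[j, k]
        coup[j] <- coup[j] + A[j, k] * (if (ts >= 1) E[k, ts] else e0)
      }
    }
    xe <- p$c1 * E[, t] - p$c2 * I[, t] + p$c5 * coup + P
    xi <- p$c3 * E[, t] - p$c4 * I[, t]
    E[, t + 1] <- E[, t] + dt / p$tau *
      (-E[, t] + (p$s_e_max - E[, t]) * S(xe, p$a_e, p$theta_e))
    I[, t + 1] <- I[, t] + dt / p$tau *
      (-I[, t] + (p$s_i_max - I[, t]) * S(xi, p$a_i, p$theta_i))
  }
  list(E = E, I = I)
}

region_coords <- function(regions) as.matrix(regions[, c("x_mm", "y_mm", "z_mm")])
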