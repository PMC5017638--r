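#' Functional connectivity by maximum lagged cross-correlation
#'
#' The functional brain state is the matrix of pairwise maximum normalized
#' cross-correlations between regional excitatory firing-rate traces:
#' `fc(i, j)` is the maximum over signed lags `l` in
#' `[-max_lag_ms, max_lag_ms]` of the Pearson correlation between `E_i(t)`
#' and `E_j(t + l)`, computed over the overlapping samples of the first
#' `window_ms` of the traces. The maximum is over signed correlations (not
#' magnitudes) since coupled excitatory populations synchronize positively;
#' set `use_abs = TRUE` to maximize `|r|` instead. The matrix is symmetric
#' by construction (`r_ij(l) = r_ji(-l)`) with unit diagonal.
#'
#' Cross-products over all lags are computed by FFT; the per-lag means and
#' variances of the shrinking overlap segments come from cumulative sums,
#' so every lag's value is an exact Pearson correlation. A trace with
#' (near-)zero variance over the window would make the correlation
#' undefined; its fc entries are set to 0 and flagged, with a warning. Lags
#' attaining the maximum on the boundary of the lag range are flagged in
#' `boundary` (possible sign of a too-short lag window).
#'
#' @param E N x T matrix of firing-rate traces (rows = regions), or a
#'   `wc_simulation` (its `E` is used).
#' @param dt_ms sampling step in ms.
#' @param window_ms correlation window; must be a multiple of `dt_ms` and
#'   no longer than the trace.
#' @param max_lag_ms maximum lag; must be a multiple of `dt_ms`.
#' @param use_abs maximize `|r|` over lags instead of signed `r`.
#' @param var_tol variance below which a trace counts as flat.
#' @return list of class `functional_state`: `fc` (N x N), `lag_ms` (N x N
#'   matrix of argmax lags), `boundary` (logical N x N), `zero_variance`
#'   (logical N), `window_ms`, `max_lag_ms`.
#' @export
functional_connectivity <- function(E, dt_ms, window_ms = 1000,
                                    max_lag_ms = 250, use_abs = FALSE,
                                    var_tol = 1e-24) {
  if (inherits(E, "wc_simulation")) { dt_ms <- E$dt_ms; E <- E$E }
  E <- as.matrix(E)
  n <- nrow(E)
  Tw <- window_ms / dt_ms
  L <- max_lag_ms / dt_ms
  if (abs(Tw - round(Tw)) > 1e-9 || abs(L - round(L)) > 1e-9) {
    stop("window_ms and max_lag_ms must be integer multiples of dt_ms",
         call. = FALSE)
  }
  Tw <- as.integer(round(Tw)); L <- as.integer(round(L))
  if (ncol(E) < Tw) stop("traces shorter than the correlation window", call. = FALSE)
  if (L >= Tw) stop("max_lag_ms must be smaller than window_ms", call. = FALSE)
  X <- E[, seq_len(Tw), drop = FALSE]

  # per-trace cumulative sums for segment means/variances at every lag
  cs <- apply(X, 1L, cumsum)            # Tw x n
  cs2 <- apply(X^2, 1L, cumsum)
  tot <- cs[Tw, ]; tot2 <- cs2[Tw, ]
  v_full <- tot2 - tot^2 / Tw
  flat <- v_full / Tw < var_tol
  if (any(flat)) {
    warning(sprintf("%d trace(s) have ~zero variance; their fc entries are set to 0",
                    sum(flat)))
  }

  M <- 2^ceiling(log2(Tw + L + 1))
  FX <- stats::mvfft(rbind(t(X), matrix(0, M - Tw, n)))  # M x n

  lags_pos <- 0:L
  npos <- Tw - lags_pos
  fc <- diag(1, n)
  lag_best <- matrix(0, n, n)
  boundary <- matrix(FALSE, n, n)

  seg_sums <- function(i, j) {
    # lag l >= 0: x = X[i, 1:(Tw-l)], y = X[j, (1+l):Tw]
    Sx <- cs[npos, i]
    Sxx <- cs2[npos, i]
    Sy <- tot[j] - c(0, cs[lags_pos[-1], j])
    Syy <- tot2[j] - c(0, cs2[lags_pos[-1], j])
    list(Sx = Sx, Sxx = Sxx, Sy = Sy, Syy = Syy)
  }

  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (flat[i] || flat[j]) { fc[i, j] <- fc[j, i] <- 0; next }
      cc <- Re(fft(Conj(FX[, i]) * FX[, j], inverse = TRUE)) / M
      # cc[l + 1] = sum_t X[i, t] X[j, t + l] for l = 0..L;
      # cc[M - l + 1] = sum_t X[i, t + l] X[j, t] for l = 1..L
      sp <- seg_sums(i, j)
      r_pos <- (cc[lags_pos + 1] - sp$Sx * sp$Sy / npos) /
        sqrt(pmax(sp$Sxx - sp$Sx^2 / npos, 0) * pmax(sp$Syy - sp$Sy^2 / npos, 0))
      sn <- seg_sums(j, i)
      r_neg <- (cc[M - lags_pos + 1 - M * (lags_pos == 0)] -
                  sn$Sx * sn$Sy / npos) /
        sqrt(pmax(sn$Sxx - sn$Sx^2 / npos, 0) * pmax(sn$Syy - sn$Sy^2 / npos, 0))
      lags_all <- c(-rev(lags_pos[-1]), lags_pos)
      r_all <- c(rev(r_neg[-1]), r_pos)
      r_all[!is.finite(r_all)] <- 0
      k <- if (use_abs) which.max(abs(r_all)) else which.max(r_all)
      fc[i, j] <- fc[j, i] <- r_all[k]
      lag_best[i, j] <- lags_all[k] * dt_ms
      lag_best[j, i] <- -lags_all[k] * dt_ms
      boundary[i, j] <- boundary[j, i] <- abs(lags_all[k]) == L && L > 0
    }
  }
  structure(list(fc = fc, lag_ms = lag_best, boundary = boundary,
                 zero_variance = flat, window_ms = window_ms,
                 max_lag_ms = max_lag_ms),
            class = "functional_state")
}

as_fc <- function(x) {
  if (inherits(x, "functional_state")) x$fc else as.matrix(x)
}

upper_vals <- function(m) m[upper.tri(m)]

#' Functional effect of stimulation
#'
#' Mean absolute change in pairwise functional connectivity between the
#' pre-stimulation and stimulation windows, averaged over all unordered
#' off-diagonal region pairs. Zero means the stimulation did not
#' reconfigure the functional state at all.
#'
#' @param fc_before,fc_during functional states ([functional_connectivity()]
#'   results or plain matrices) of matching size.
#' @return nonnegative scalar.
#' @export
functional_effect <- function(fc_before, fc_during) {
  a <- as_fc(fc_before); b <- as_fc(fc_during)
  if (!all(dim(a) == dim(b))) stop("functional states differ in shape", call. = FALSE)
  mean(abs(upper_vals(b) - upper_vals(a)))
}

#' Two-dimensional correlation between matrices
#'
#' Pearson correlation between the upper-triangle off-diagonal entries of
#' two symmetric matrices. The diagonal is excluded by default because it
#' is uninformative here (structurally forced to 0 in an adjacency matrix
#' and to 1 in a correlation matrix); `include_diagonal = TRUE` reproduces
#' the full-matrix convention instead.
#'
#' @param a,b matrices of matching size.
#' @param include_diagonal correlate all entries rather than the strict
#'   upper triangle.
#' @return correlation coefficient.
#' @export
corr2 <- function(a, b, include_diagonal = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("matrices differ in shape", call. = FALSE)
  x <- if (include_diagonal) as.vector(a) else upper_vals(a)
  y <- if (include_diagonal) as.vector(b) else upper_vals(b)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("corr2 undefined: an input matrix is constant over the compared entries",
         call. = FALSE)
  }
  cor(x, y)
}

#' Structural effect of stimulation
#'
#' Change in similarity between the structural connectivity matrix and the
#' functional state, from before to during stimulation:
#' `corr2(A, fc_during) - corr2(A, fc_before)`. Positive values mean
#' stimulation pulled the functional state toward the underlying anatomy.
#'
#' @param net [structural_network()] or weight matrix.
#' @param fc_before,fc_during functional states or matrices.
#' @param include_diagonal passed to [corr2()].
#' @return scalar (positive or negative).
#' @export
structural_effect <- function(net, fc_before, fc_during,
                              include_diagonal = FALSE) {
  A <- as_weights(net)
  corr2(A, as_fc(fc_during), include_diagonal) -
    corr2(A, as_fc(fc_before), include_diagonal)
}

#' Fractional activation
#'
#' Fraction of unordered region pairs whose functional-connectivity change
#' exceeds `threshold` in absolute value. High values mean stimulation had
#' a global impact on the functional state; low values a focal one.
#'
#' @param fc_before,fc_during functional states or matrices.
#' @param threshold nonnegative change threshold.
#' @return fraction in \[0, 1\].
#' @export
fractional_activation <- function(fc_before, fc_during, threshold = 0.6) {
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  a <- as_fc(fc_before); b <- as_fc(fc_during)
  if (!all(dim(a) == dim(b))) stop("functional states differ in shape", call. = FALSE)
  d <- abs(upper_vals(b) - upper_vals(a))
  mean(d > threshold)
}
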