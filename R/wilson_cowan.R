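#' Wilson-Cowan model parameters
#'
#' Parameter set for a network of Wilson-Cowan neural mass oscillators. The
#' defaults are the classic limit-cycle parameterization: with no external
#' current the uncoupled unit rests at a low fixed point, a moderate
#' constant current (P = 1.25) pushes it onto a limit cycle, and a strong
#' current (P = 2.5) onto a high fixed point.
#'
#' The sigmoid ceilings `s_e_max` / `s_i_max` default to the supremum of the
#' transfer function, `1 - 1/(1 + exp(a * theta))`, which keeps the firing
#' rates inside `[0, s_max)` (the refractory convention of the original
#' mean-field derivation). They are configurable.
#'
#' @param tau time constant in ms.
#' @param c1,c2,c3,c4 local excitatory/inhibitory coupling gains.
#' @param c5 global coupling: scales the delayed excitatory input received
#'   through the structural network.
#' @param a_e,a_i sigmoid slopes, `theta_e,theta_i` sigmoid thresholds.
#' @param theta_e,theta_i sigmoid thresholds.
#' @param sigma additive noise amplitude (standard normal draws per step).
#' @param s_e_max,s_i_max sigmoid ceilings; `NULL` means the supremum of the
#'   corresponding transfer function.
#' @return list of class `wc_params`.
#' @export
wc_params <- function(tau = 8, c1 = 16, c2 = 12, c3 = 15, c4 = 3, c5 = 1,
                      a_e = 1.3, a_i = 2, theta_e = 4, theta_i = 3.7,
                      sigma = 1e-5, s_e_max = NULL, s_i_max = NULL) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (a_e <= 0 || a_i <= 0) stop("sigmoid slopes must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (c5 < 0) stop("c5 must be nonnegative", call. = FALSE)
  p <- list(tau = tau, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
            a_e = a_e, a_i = a_i, theta_e = theta_e, theta_i = theta_i,
            sigma = sigma,
            s_e_max = s_e_max %||% (1 - 1 / (1 + exp(a_e * theta_e))),
            s_i_max = s_i_max %||% (1 - 1 / (1 + exp(a_i * theta_i))))
  class(p) <- "wc_params"
  p
}

#' Sigmoidal transfer function
#'
#' `S(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`. The offset
#' makes `S(0) = 0`, so zero drive produces zero output and the origin is a
#' fixed point of the unstimulated system. The supremum is
#' `1 - 1/(1 + exp(a theta))`.
#'
#' @param x input drive (may be a vector).
#' @param a slope (> 0).
#' @param theta threshold.
#' @return transfer value(s), same shape as `x`.
#' @export
sigmoid_transfer <- function(x, a, theta) {
  stopifnot(a > 0)
  1 / (1 + exp(-a * (x - theta))) - 1 / (1 + exp(a * theta))
}

sigmoid_deriv <- function(x, a, theta) {
  s <- 1 / (1 + exp(-a * (x - theta)))
  a * s * (1 - s)
}

#' Stimulation protocol
#'
#' A constant step current applied to one target region between `onset_ms`
#' and `offset_ms`, on top of a per-region baseline current.
#'
#' @param target_region region index to stimulate, or `NULL` for none.
#' @param amplitude stimulating current amplitude.
#' @param onset_ms,offset_ms stimulation window in ms (`onset < offset`).
#' @param baseline constant baseline current, scalar or per-region vector.
#' @return list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target_region = NULL, amplitude = 1.25,
                              onset_ms = 0, offset_ms = 0, baseline = 0) {
  if (!is.null(target_region)) {
    stopifnot(length(target_region) == 1, target_region >= 1)
    if (!is.finite(amplitude)) stop("amplitude must be finite", call. = FALSE)
    if (onset_ms >= offset_ms) {
      stop("onset_ms must be < offset_ms when a target is set", call. = FALSE)
    }
  }
  structure(list(target_region = target_region, amplitude = amplitude,
                 onset_ms = onset_ms, offset_ms = offset_ms,
                 baseline = baseline),
            class = "stimulus_protocol")
}

#' Fixed points of a single uncoupled oscillator
#'
#' Finds all intersections of the excitatory and inhibitory nullclines of a
#' single Wilson-Cowan unit under a constant current `P` (coupling and noise
#' absent) and classifies each by the eigenvalues of the local Jacobian.
#' For each value of E the I-nullcline is solved by bracketing; the
#' resulting scalar equation in E is scanned on a fine grid for sign
#' changes (plus an explicit check of the origin, which is an exact root
#' when `P = 0`).
#'
#' @param params a [wc_params()] object.
#' @param P constant external current.
#' @param n_grid grid resolution for root scanning.
#' @return data.frame with columns `E`, `I`, `stable` (logical) and
#'   `max_re_eig`, ordered by `E`. Zero rows (with a warning) if no root is
#'   bracketed.
#' @export
find_fixed_points <- function(params, P = 0, n_grid = 4000L) {
  p <- params
  i_null <- function(E) {
    f <- function(I) -I + (p$s_i_max - I) *
      sigmoid_transfer(p$c3 * E - p$c4 * I, p$a_i, p$theta_i)
    uniroot(f, c(0, p$s_i_max), tol = 1e-14)$root
  }
  g <- function(E) {
    I <- i_null(E)
    -E + (p$s_e_max - E) *
      sigmoid_transfer(p$c1 * E - p$c2 * I + P, p$a_e, p$theta_e)
  }
  grid <- seq(0, p$s_e_max, length.out = n_grid)
  gv <- vapply(grid, g, numeric(1))
  roots <- numeric(0)
  if (abs(gv[1]) < 1e-12) roots <- c(roots, grid[1])
  sc <- which(gv[-1] * gv[-length(gv)] < 0)
  for (k in sc) {
    roots <- c(roots, uniroot(g, c(grid[k], grid[k + 1]), tol = 1e-14)$root)
  }
  roots <- roots[!duplicated(round(roots, 10))]
  if (!length(roots)) {
    warning("no fixed point bracketed on the rate grid")
    return(data.frame(E = numeric(0), I = numeric(0), stable = logical(0),
                      max_re_eig = numeric(0)))
  }
  res <- lapply(roots, function(E) {
    I <- i_null(E)
    xe <- p$c1 * E - p$c2 * I + P
    xi <- p$c3 * E - p$c4 * I
    se <- sigmoid_transfer(xe, p$a_e, p$theta_e)
    si <- sigmoid_transfer(xi, p$a_i, p$theta_i)
    dse <- sigmoid_deriv(xe, p$a_e, p$theta_e)
    dsi <- sigmoid_deriv(xi, p$a_i, p$theta_i)
    J <- matrix(c(
      -1 - se + (p$s_e_max - E) * dse * p$c1,
      (p$s_e_max - E) * dse * (-p$c2),
      (p$s_i_max - I) * dsi * p$c3,
      -1 - si + (p$s_i_max - I) * dsi * (-p$c4)
    ), 2, 2, byrow = TRUE) / p$tau
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(E = E, I = I, stable = all(Re(ev) < 0),
               max_re_eig = max(Re(ev)))
  })
  out <- do.call(rbind, res)
  out[order(out$E), , drop = FALSE]
}

#' Simulate a network of delay-coupled Wilson-Cowan oscillators
#'
#' Fixed-step Euler integration of the coupled stochastic delay equations.
#' Regions are coupled through their excitatory populations by the weight
#' matrix; each connection's signal is delayed by its conduction delay,
#' quantized to an integer number of steps (round-half-to-even). The delay
#' history before t = 0 is filled with the initial condition. Noise enters
#' as per-step standard-normal draws scaled by `sigma` inside the
#' right-hand side (set `noise = "sqrt_dt"` for the Euler-Maruyama
#' interpretation with Wiener increments instead). Identical arguments and
#' seed reproduce the trajectory bit-for-bit.
#'
#' @param net [structural_network()] or weight matrix (use a 1 x 1 zero
#'   matrix for a single uncoupled unit).
#' @param delays delay matrix in ms (e.g. from [compute_delays()]), or
#'   `NULL` for no delays.
#' @param params [wc_params()].
#' @param protocol [stimulus_protocol()].
#' @param duration_ms,dt_ms total simulated time and step, ms.
#' @param seed integer seed for the noise stream.
#' @param init length-2 vector: initial `E` and `I` for every region.
#' @param noise `"step"` (per-step draws in the RHS) or `"sqrt_dt"`.
#' @return list of class `wc_simulation` with `times` (ms), `E`, `I`
#'   (N x T matrices), `dt_ms`, `protocol`, `params`, `seed`.
#' @export
simulate_network <- function(net, delays = NULL, params = wc_params(),
                             protocol = stimulus_protocol(),
                             duration_ms = 3000, dt_ms = 0.1, seed = 1L,
                             init = c(0.1, 0.1), noise = c("step", "sqrt_dt")) {
  noise <- match.arg(noise)
  A <- as_weights(net)
  n <- nrow(A)
  if (dt_ms <= 0) stop("dt_ms must be positive", call. = FALSE)
  if (dt_ms > params$tau / 10) {
    stop(sprintf("dt_ms = %g too coarse: must be <= tau/10 = %g ms",
                 dt_ms, params$tau / 10), call. = FALSE)
  }
  if (is.null(delays)) delays <- matrix(0, n, n)
  delays <- as.matrix(delays)
  stopifnot(all(dim(delays) == n), all(delays >= 0))
  pos <- delays[A != 0 & delays > 0]
  if (length(pos) && dt_ms > min(pos)) {
    stop(sprintf("dt_ms = %g exceeds the smallest positive delay (%g ms)",
                 dt_ms, min(pos)), call. = FALSE)
  }
  if (!is.null(protocol$target_region)) {
    if (protocol$target_region > n) {
      stop("protocol target region exceeds network size", call. = FALSE)
    }
    if (duration_ms < protocol$offset_ms) {
      stop("duration_ms must cover the stimulation window", call. = FALSE)
    }
  }
  n_steps <- round(duration_ms / dt_ms)
  dsteps <- matrix(as.integer(round(delays / dt_ms)), n, n)
  p_base <- rep_len(protocol$baseline, n)
  target0 <- if (is.null(protocol$target_region)) -1L else
    as.integer(protocol$target_region - 1L)
  out <- with_seed(seed, wc_integrate_cpp(
    A, dsteps, unclass(params), p_base,
    target0, protocol$amplitude,
    as.integer(round(protocol$onset_ms / dt_ms)),
    as.integer(round(protocol$offset_ms / dt_ms)),
    as.integer(n_steps), dt_ms, init[1], init[2],
    noise == "sqrt_dt"
  ))
  structure(list(times = seq(0, by = dt_ms, length.out = n_steps + 1),
                 E = out$E, I = out$I, dt_ms = dt_ms, protocol = protocol,
                 params = params, seed = seed),
            class = "wc_simulation")
}

#' @export
print.wc_simulation <- function(x, ...) {
  cat(sprintf("wc_simulation: %d regions, %.0f ms at dt = %g ms (seed %d)\n",
              nrow(x$E), max(x$times), x$dt_ms, x$seed))
  if (!is.null(x$protocol$target_region)) {
    cat(sprintf("  stimulation: region %d, amplitude %g, [%g, %g) ms\n",
                x$protocol$target_region, x$protocol$amplitude,
                x$protocol$onset_ms, x$protocol$offset_ms))
  }
  invisible(x)
}

#' Dominant oscillation frequency of a firing-rate trace
#'
#' Estimates the dominant frequency after discarding an initial transient,
#' using the spectral peak of the demeaned trace, cross-checked against the
#' mean inter-peak interval of local maxima. A flat (fixed-point) trace
#' returns 0 Hz flagged non-oscillatory; if the two estimators disagree by
#' more than 10% a warning is raised and the spectral estimate is returned.
#'
#' @param trace numeric vector of firing rates (one region).
#' @param dt_ms sampling step in ms.
#' @param discard_ms initial transient to drop.
#' @param flat_tol peak-to-peak range below which the trace counts as flat.
#' @return frequency in Hz with attributes `oscillatory` (logical),
#'   `spectral_hz` and `interpeak_hz`.
#' @export
estimate_dominant_frequency <- function(trace, dt_ms, discard_ms = 1000,
                                        flat_tol = 1e-4) {
  ndrop <- round(discard_ms / dt_ms)
  if (ndrop >= length(trace) - 4) stop("trace shorter than discard window", call. = FALSE)
  x <- trace[-seq_len(ndrop)]
  if (diff(range(x)) < flat_tol) {
    return(structure(0, oscillatory = FALSE, spectral_hz = 0, interpeak_hz = 0))
  }
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(fft(x))^2
  half <- 2:(n %/% 2)
  k <- half[which.max(spec[half])]
  f_spec <- (k - 1) / (n * dt_ms * 1e-3)
  # inter-peak interval among local maxima above the midline
  mid <- mean(range(x))
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk <- pk[x[pk] > mid]
  f_ipi <- if (length(pk) >= 3) 1000 / (mean(diff(pk)) * dt_ms) else NA_real_
  if (is.finite(f_ipi) && abs(f_ipi - f_spec) > 0.1 * f_spec) {
    warning(sprintf(
      "frequency estimators disagree (spectral %.2f Hz vs inter-peak %.2f Hz)",
      f_spec, f_ipi))
  }
  structure(f_spec, oscillatory = TRUE, spectral_hz = f_spec,
            interpeak_hz = f_ipi)
}
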