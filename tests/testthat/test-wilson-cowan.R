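test_that("sigmoid transfer matches its closed form", {
  expect_equal(sigmoid_transfer(0, 1.3, 4), 0)
  expect_equal(sigmoid_transfer(0, 2, 3.7), 0)
  expect_equal(sigmoid_transfer(4, 1.3, 4), 0.5 - 1 / (1 + exp(5.2)))
  expect_equal(sigmoid_transfer(1e3, 1.3, 4), 1 - 1 / (1 + exp(5.2)),
               tolerance = 1e-12)
  # monotone increasing
  x <- seq(-5, 10, by = 0.1)
  expect_true(all(diff(sigmoid_transfer(x, 1.3, 4)) > 0))
})

test_that("the three single-oscillator regimes appear at P = 0, 1.25, 2.5", {
  p <- wc_params(sigma = 0)
  fp0 <- find_fixed_points(p, P = 0)
  expect_true(any(fp0$stable & fp0$E < 0.05))
  fp25 <- find_fixed_points(p, P = 2.5)
  expect_true(any(fp25$stable))
  expect_gt(max(fp25$E[fp25$stable]), max(fp0$E[fp0$stable]))
  # P = 1.25: no stable fixed point attracts (0.1, 0.1); trajectory keeps
  # oscillating
  fp125 <- find_fixed_points(p, P = 1.25)
  expect_false(any(fp125$stable))
  sim <- simulate_network(matrix(0, 1, 1), NULL, wc_params(c5 = 0, sigma = 0),
                          stimulus_protocol(baseline = 1.25), 3000, 0.1, 1)
  last_s <- sim$E[1, sim$times > 2000]
  expect_gt(diff(range(last_s)), 0.1)
})

test_that("uncoupled simulation converges to the root-found fixed point", {
  p <- wc_params(c5 = 0, sigma = 0)
  for (P in c(0, 2.5)) {
    fp <- find_fixed_points(p, P = P)
    stable <- fp[fp$stable, ]
    sim <- simulate_network(matrix(0, 1, 1), NULL, p,
                            stimulus_protocol(baseline = P), 4000, 0.1, 1)
    e_end <- sim$E[1, ncol(sim$E)]
    i_end <- sim$I[1, ncol(sim$I)]
    k <- which.min(abs(stable$E - e_end))
    expect_lt(abs(e_end - stable$E[k]), 1e-6)
    expect_lt(abs(i_end - stable$I[k]), 1e-6)
  }
})

test_that("compiled integrator matches a plain-R reference step for step", {
  set.seed(5)
  n <- 4
  A <- rand_symmetric_net(n, seed = 5, density = 0.8, scale = 2)
  dsteps <- matrix(sample(0:30, n * n, replace = TRUE), n, n)
  dsteps[lower.tri(dsteps)] <- t(dsteps)[lower.tri(dsteps)]
  diag(dsteps) <- 0L
  p <- wc_params(c5 = 1.2, sigma = 0)
  sim <- simulate_network(A, dsteps * 0.1, p, stimulus_protocol(baseline = 0.6),
                          duration_ms = 50, dt_ms = 0.1, seed = 1)
  ref <- r_reference_wc(A, dsteps, p, P = 0.6, n_steps = 500, dt = 0.1)
  expect_equal(sim$E, ref$E, tolerance = 1e-12)
  expect_equal(sim$I, ref$I, tolerance = 1e-12)
})

test_that("identical seeds reproduce noisy trajectories bit for bit", {
  A <- rand_symmetric_net(5, seed = 6)
  p <- wc_params(c5 = 1)
  s1 <- simulate_network(A, NULL, p, duration_ms = 100, dt_ms = 0.1, seed = 33)
  s2 <- simulate_network(A, NULL, p, duration_ms = 100, dt_ms = 0.1, seed = 33)
  expect_identical(s1$E, s2$E)
  s3 <- simulate_network(A, NULL, p, duration_ms = 100, dt_ms = 0.1, seed = 34)
  expect_false(identical(s1$E, s3$E))
})

test_that("simulation does not leak RNG state", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_network(matrix(0, 1, 1), NULL, wc_params(),
                                           duration_ms = 10, dt_ms = 0.1,
                                           seed = 7))
  expect_identical(runif(1), before)
})

test_that("disconnected regions reproduce the single-oscillator trajectory", {
  p <- wc_params(c5 = 1, sigma = 0)
  two <- simulate_network(matrix(0, 2, 2), NULL, p,
                          stimulus_protocol(baseline = 1.25), 500, 0.1, 1)
  one <- simulate_network(matrix(0, 1, 1), NULL, p,
                          stimulus_protocol(baseline = 1.25), 500, 0.1, 1)
  expect_equal(two$E[1, ], one$E[1, ])
  expect_equal(two$E[2, ], one$E[1, ])
})

test_that("halving dt barely moves the fixed-point endpoint", {
  p <- wc_params(c5 = 0, sigma = 0)
  ends <- vapply(c(0.1, 0.05), function(dt) {
    sim <- simulate_network(matrix(0, 1, 1), NULL, p,
                            stimulus_protocol(baseline = 2.5), 2000, dt, 1)
    sim$E[1, ncol(sim$E)]
  }, numeric(1))
  expect_lt(abs(diff(ends)), 1e-3)
})

test_that("relabeling regions permutes trajectories identically", {
  n <- 6
  A <- rand_symmetric_net(n, seed = 8, scale = 2)
  co <- matrix(runif(n * 3, 0, 100), n, 3)
  d <- compute_delays(co)
  p <- wc_params(c5 = 1.3, sigma = 0)
  prot <- stimulus_protocol(2, 1.25, 50, 100)
  perm <- c(3, 1, 6, 2, 5, 4)
  s1 <- simulate_network(A, d, p, prot, 100, 0.1, 1)
  prot2 <- stimulus_protocol(which(perm == 2), 1.25, 50, 100)
  s2 <- simulate_network(A[perm, perm], d[perm, perm], p, prot2, 100, 0.1, 1)
  expect_equal(s2$E, s1$E[perm, ])
  expect_equal(s2$I, s1$I[perm, ])
})

test_that("population rate responds monotonically to coupling below transition", {
  A <- rand_symmetric_net(10, seed = 9, density = 0.6)
  A <- A * (3 / mean(rowSums(A)))
  p <- wc_params(sigma = 0)
  means <- vapply(c(0, 0.3, 0.6), function(c5) {
    p$c5 <- c5
    sim <- simulate_network(A, NULL, p, stimulus_protocol(baseline = 0.25),
                            2000, 0.1, 1)
    mean(sim$E[, ncol(sim$E)])
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-9))
})

test_that("stimulation window raises the target region only while on", {
  A <- rand_symmetric_net(3, seed = 10, scale = 0.1)
  p <- wc_params(c5 = 0.5, sigma = 0)
  sim <- simulate_network(A, NULL, p, stimulus_protocol(2, 1.25, 100, 200),
                          300, 0.1, 1)
  during <- sim$times > 120 & sim$times < 200
  before <- sim$times < 100
  expect_gt(mean(sim$E[2, during]), mean(sim$E[2, before]) + 0.05)
})

test_that("precondition violations are rejected", {
  expect_error(simulate_network(matrix(0, 1, 1), NULL, wc_params(),
                                duration_ms = 10, dt_ms = 2, seed = 1),
               "tau/10")
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  d <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  expect_error(simulate_network(A, d, wc_params(), duration_ms = 10,
                                dt_ms = 0.1, seed = 1), "delay")
  expect_error(stimulus_protocol(1, 1.25, 200, 100), "onset")
  expect_error(wc_params(tau = -1), "tau")
  expect_error(wc_params(sigma = -1), "sigma")
})

test_that("frequency estimation recovers a pure tone and flags flat traces", {
  t_ms <- seq(0, 3000, by = 0.1)
  x <- sin(2 * pi * 20 * t_ms / 1000)
  f <- estimate_dominant_frequency(x, 0.1, discard_ms = 1000)
  expect_equal(as.numeric(f), 20, tolerance = 0.025)
  expect_true(attr(f, "oscillatory"))
  flat <- estimate_dominant_frequency(rep(0.2, 30000), 0.1, 1000)
  expect_identical(as.numeric(flat), 0)
  expect_false(attr(flat, "oscillatory"))
})

test_that("the two frequency estimators agree on the model's limit cycle", {
  sim <- simulate_network(matrix(0, 1, 1), NULL, wc_params(c5 = 0, sigma = 0),
                          stimulus_protocol(baseline = 1.25), 3000, 0.1, 1)
  f <- estimate_dominant_frequency(sim$E[1, ], 0.1, 1000)
  expect_lt(abs(attr(f, "interpeak_hz") - attr(f, "spectral_hz")),
            0.1 * attr(f, "spectral_hz"))
  # the continuous-time cycle runs at 25.0 Hz (adaptive-solver oracle);
  # explicit Euler at dt = 0.1 ms slows it by ~6%
  expect_gt(as.numeric(f), 21)
  expect_lt(as.numeric(f), 26)
})

test_that("the continuous-time limit cycle runs at 25 Hz (adaptive-solver oracle)", {
  p <- wc_params(c5 = 0, sigma = 0)
  rhs <- function(t, y, parms) {
    xe <- p$c1 * y[1] - p$c2 * y[2] + 1.25
    xi <- p$c3 * y[1] - p$c4 * y[2]
    list(c((-y[1] + (p$s_e_max - y[1]) * sigmoid_transfer(xe, p$a_e, p$theta_e)) / p$tau,
           (-y[2] + (p$s_i_max - y[2]) * sigmoid_transfer(xi, p$a_i, p$theta_i)) / p$tau))
  }
  out <- deSolve::ode(c(0.1, 0.1), seq(0, 4000, by = 0.1), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  f <- estimate_dominant_frequency(out[, 2], 0.1, discard_ms = 1000)
  expect_equal(as.numeric(f), 25, tolerance = 0.01)
})
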