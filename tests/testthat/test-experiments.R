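test_that("a negligibly coupled network shows no transition on the sweep grid", {
  g <- generate_connectome(20, seed = 31)
  tiny <- g$network$weights * 1e-6
  scan <- find_transition_point(tiny, NULL, wc_params(), seed = 1)
  expect_false(scan$transition_found)
  expect_true(is.na(scan$c5_transition))
  expect_true(all(scan$mean_rate < 0.05))
})

test_that("the transition sweep is deterministic for a fixed seed", {
  g <- generate_connectome(25, seed = 32)
  d <- compute_delays(region_coords(g$regions))
  s1 <- find_transition_point(g$network, d, wc_params(), seed = 5)
  s2 <- find_transition_point(g$network, d, wc_params(), seed = 5)
  expect_identical(s1$mean_rate, s2$mean_rate)
  expect_identical(s1$c5_transition, s2$c5_transition)
})

test_that("scaling all weights up cannot delay the transition", {
  g <- generate_connectome(30, seed = 33)
  d <- compute_delays(region_coords(g$regions))
  grid <- seq(0.6, 1.8, by = 0.05)
  trans <- vapply(c(1, 1.15, 1.3), function(f) {
    scan <- find_transition_point(g$network$weights * f, d, wc_params(),
                                  c5_grid = grid, sim_seconds = 0.5,
                                  stabilize_seconds = 0.5, seed = 9)
    if (scan$transition_found) scan$c5_transition else Inf
  }, numeric(1))
  expect_true(all(is.finite(trans)))
  expect_true(all(diff(trans) <= 0))
})

test_that("icc matches an explicit sum-of-squares ANOVA oracle", {
  set.seed(34)
  I <- 8; J <- 3
  y <- matrix(rnorm(I * J, sd = 0.1) + rep(rnorm(I, sd = 0.15), J), I, J)
  rep_icc <- icc(y)
  # oracle: explicit loops over the two-way decomposition
  gm <- mean(y)
  ssr <- 0; sss <- 0; sse <- 0
  for (i in 1:I) ssr <- ssr + J * (mean(y[i, ]) - gm)^2
  for (j in 1:J) sss <- sss + I * (mean(y[, j]) - gm)^2
  for (i in 1:I) for (j in 1:J) {
    sse <- sse + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + gm)^2
  }
  RMS <- ssr / (I - 1); SMS <- sss / (J - 1); EMS <- sse / ((I - 1) * (J - 1))
  den <- J * SMS + I * RMS + (I * J - I - J) * EMS
  expect_equal(rep_icc$icc_between, J * (SMS - EMS) / den, tolerance = 1e-10)
  expect_equal(rep_icc$icc_within, I * (RMS - EMS) / den, tolerance = 1e-10)
  # cross-check the mean squares against aov()
  df <- data.frame(y = as.vector(y),
                   subj = factor(rep(1:I, J)), scan = factor(rep(1:J, each = I)))
  ms <- summary(aov(y ~ subj + scan, df))[[1]][["Mean Sq"]]
  expect_equal(c(rep_icc$RMS, rep_icc$SMS, rep_icc$EMS), ms, tolerance = 1e-10)
})

test_that("icc handles the degenerate designs", {
  # scans identical within subject, subjects distinct: perfect within-subject
  # reproducibility, no scan or error variance
  y <- matrix(rep(c(1, 2, 5, 9), 3), 4, 3)
  r <- icc(y)
  expect_equal(r$icc_within, 1)
  expect_equal(r$icc_between, 0)
  expect_equal(r$var_within, 0)
  expect_gt(r$var_between, 0)
  # all values identical: 0/0, flagged
  r2 <- icc(matrix(3, 4, 3))
  expect_true(r2$degenerate)
  expect_true(is.na(r2$icc_between))
  expect_error(icc(matrix(1:3, 1, 3)), "2 subjects")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("icc_within recovers a known generating intraclass correlation", {
  sd_b <- 0.12; sd_e <- 0.04
  true_icc <- sd_b^2 / (sd_b^2 + sd_e^2)  # 0.9
  set.seed(35)
  est <- replicate(200, {
    y <- rep(rnorm(8, sd = sd_b), 3) + rnorm(24, sd = sd_e)
    icc(matrix(y, 8, 3))$icc_within
  })
  expect_lt(abs(mean(est) - true_icc), 0.15)
})

test_that("campaign with zero amplitude stays at the noise floor", {
  g <- generate_connectome(30, seed = 33)
  d <- compute_delays(region_coords(g$regions))
  scan <- find_transition_point(g$network, d, wc_params(), seed = 2)
  expect_true(scan$transition_found)
  targets <- c(2, 9, 17, 25)
  null_camp <- stimulation_campaign(g$network, d, wc_params(),
                                    scan$c5_operating, seed = 3,
                                    stim_amplitude = 0, targets = targets)
  stim_camp <- stimulation_campaign(g$network, d, wc_params(),
                                    scan$c5_operating, seed = 3,
                                    targets = targets)
  # the null protocol measures pure window-to-window drift of the baseline
  # state; real stimulation must stand clearly above it on average
  expect_gt(mean(stim_camp$outcomes$functional_effect),
            2 * mean(null_camp$outcomes$functional_effect))
})

test_that("campaign statistics permute with the regions when noise is off", {
  n <- 8
  A <- rand_symmetric_net(n, seed = 37, density = 0.7)
  A <- A * (6 / mean(rowSums(A)))
  p <- wc_params(sigma = 0)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  c1 <- suppressWarnings(
    stimulation_campaign(A, NULL, p, 1.0, seed = 1, stabilize_ms = 200,
                         window_ms = 200, max_lag_ms = 50))
  c2 <- suppressWarnings(
    stimulation_campaign(A[perm, perm], NULL, p, 1.0, seed = 1,
                         stabilize_ms = 200, window_ms = 200,
                         max_lag_ms = 50))
  # region i of the permuted network is original region perm[i]
  # permutation reorders floating-point sums, so agreement is to round-off
  expect_lt(max(abs(c2$outcomes$functional_effect -
                      c1$outcomes$functional_effect[perm])), 1e-8)
  expect_lt(max(abs(c2$outcomes$structural_effect -
                      c1$outcomes$structural_effect[perm])), 1e-8)
  expect_equal(c2$outcomes$fractional_activation,
               c1$outcomes$fractional_activation[perm])
})

test_that("system aggregation computes block densities and flags singletons", {
  # complete graph: all densities one
  n <- 6
  A <- matrix(1, n, n); diag(A) <- 0
  sys <- c("a", "a", "a", "b", "b", "b")
  expect_true(all(connection_density(A, sys) == 1))
  # two systems with no between edges
  A2 <- matrix(0, n, n)
  A2[1:3, 1:3] <- 1; A2[4:6, 4:6] <- 1; diag(A2) <- 0
  d2 <- connection_density(A2, sys)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "a"], 1)
  regions <- make_regions(n, systems = c("a", "a", "a", "b", "b", "solo")[c(1:5, 6)])
  outcomes <- data.frame(region = 1:n,
                         functional_effect = (1:n) / 10,
                         structural_effect = rev(1:n) / 20,
                         fractional_activation = 0.1)
  expect_warning(agg <- system_aggregate(outcomes, regions, A), "singleton")
  ss <- agg$system_summary
  expect_equal(ss$functional_mean[ss$system == "a"], 0.2)
  expect_true(is.na(ss$functional_sem[ss$system == "solo"]))
  expect_identical(agg$density_table, t(agg$density_table))
})

test_that("default generator reproduces the subcortical > default-mode density ordering", {
  g <- generate_connectome(83, seed = 38)
  d <- connection_density(g$network, g$regions$system)
  expect_gt(d["subcortical", "subcortical"], d["default_mode", "default_mode"])
  expect_gt(d["default_mode", "default_mode"],
            max(d["sensory_association", "sensory_association"],
                d["higher_order", "higher_order"]))
})
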