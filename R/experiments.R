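#' Locate the oscillatory transition of a coupled network
#'
#' Sweeps the global coupling parameter `c5` over a grid, running an
#' unstimulated (P = 0) simulation at each value, and records the mean
#' excitatory firing rate of every region over the analysis window (after
#' discarding an initial stabilization period). The transition is the first
#' grid point at which (a) the across-region median mean rate jumps by more
#' than `jump_factor` relative to the previous grid point and (b) more than
#' half the regions exceed `rate_floor` — i.e. a sudden network-wide
#' increase in firing rate marking the jump from the low fixed point to the
#' limit-cycle regime. The operating point is the grid point immediately
#' before the transition.
#'
#' @param net [structural_network()] or weight matrix.
#' @param delays delay matrix in ms (or `NULL`).
#' @param params [wc_params()]; its `c5` is overridden by the grid.
#' @param c5_grid increasing grid of coupling values.
#' @param sim_seconds analysis window length, s.
#' @param stabilize_seconds discarded initial period, s.
#' @param dt_ms integration step.
#' @param seed integer; grid point k uses noise seed `seed + k - 1`.
#' @param jump_factor multiplicative jump in the median rate that signals
#'   the transition.
#' @param rate_floor firing-rate level a majority of regions must exceed.
#' @return list of class `transition_scan`: `c5_grid`, `mean_rate`
#'   (N x length(grid)), `median_rate`, `c5_transition`, `c5_operating`
#'   (both `NA` with `transition_found = FALSE` when no jump is detected).
#' @export
find_transition_point <- function(net, delays = NULL, params = wc_params(),
                                  c5_grid = seq(1.0, 1.5, by = 0.05),
                                  sim_seconds = 1, stabilize_seconds = 1,
                                  dt_ms = 0.1, seed = 1L,
                                  jump_factor = 3, rate_floor = 0.05) {
  if (is.unsorted(c5_grid, strictly = TRUE)) {
    stop("c5_grid must be strictly increasing", call. = FALSE)
  }
  A <- as_weights(net)
  n <- nrow(A)
  dur <- (stabilize_seconds + sim_seconds) * 1000
  keep <- seq.int(round(stabilize_seconds * 1000 / dt_ms) + 1L,
                  round(dur / dt_ms) + 1L)
  mean_rate <- matrix(NA_real_, n, length(c5_grid))
  for (k in seq_along(c5_grid)) {
    p <- params; p$c5 <- c5_grid[k]
    sim <- simulate_network(A, delays, p, stimulus_protocol(),
                            duration_ms = dur, dt_ms = dt_ms,
                            seed = seed + k - 1L)
    mean_rate[, k] <- rowMeans(sim$E[, keep, drop = FALSE])
  }
  med <- apply(mean_rate, 2L, median)
  trans <- NA_integer_
  for (k in 2:length(c5_grid)) {
    jump <- med[k] > jump_factor * med[k - 1]
    majority <- mean(mean_rate[, k] > rate_floor) > 0.5
    if (jump && majority) { trans <- k; break }
  }
  structure(list(
    c5_grid = c5_grid, mean_rate = mean_rate, median_rate = med,
    c5_transition = if (is.na(trans)) NA_real_ else c5_grid[trans],
    c5_operating = if (is.na(trans)) NA_real_ else c5_grid[trans - 1L],
    transition_found = !is.na(trans)
  ), class = "transition_scan")
}

#' Intraclass correlation from a subjects-by-scans table
#'
#' Two-way ANOVA decomposition of a balanced I subjects x J scans table of
#' a scalar measurement, yielding the between-subject and within-subject
#' intraclass correlation coefficients from the mean squares (RMS between
#' subjects, SMS between scans, EMS error):
#' \deqn{ICC_B = J(SMS - EMS) / (J SMS + I RMS + (IJ - I - J) EMS)}
#' \deqn{ICC_W = I(RMS - EMS) / (J SMS + I RMS + (IJ - I - J) EMS)}
#' High `icc_within` means scans of the same subject agree (reproducible
#' within subject) while subjects differ. Also reports the between-subject
#' variance (variance of per-subject means) and the within-subject variance
#' (per-subject variance averaged across subjects).
#'
#' @param values numeric I x J matrix, rows = subjects, columns = scans;
#'   no missing cells (the formulas assume a balanced design).
#' @return list of class `icc_report`: `icc_between`, `icc_within`,
#'   `var_between`, `var_within`, `I`, `J`, the three mean squares, and
#'   `degenerate` (TRUE when the denominator vanishes, e.g. all values
#'   identical, in which case the ICCs are `NA`).
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  I <- nrow(values); J <- ncol(values)
  if (I < 2 || J < 2) stop("need at least 2 subjects and 2 scans", call. = FALSE)
  if (anyNA(values)) stop("missing cells: the balanced ANOVA formulas do not apply",
                          call. = FALSE)
  gm <- mean(values)
  rm_ <- rowMeans(values); cm <- colMeans(values)
  ss_subj <- J * sum((rm_ - gm)^2)
  ss_scan <- I * sum((cm - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_scan
  RMS <- ss_subj / (I - 1)
  SMS <- ss_scan / (J - 1)
  EMS <- ss_err / ((I - 1) * (J - 1))
  denom <- J * SMS + I * RMS + (I * J - I - J) * EMS
  degenerate <- denom <= .Machine$double.eps * max(1, abs(gm))^2
  structure(list(
    icc_between = if (degenerate) NA_real_ else J * (SMS - EMS) / denom,
    icc_within = if (degenerate) NA_real_ else I * (RMS - EMS) / denom,
    var_between = var(rm_),
    var_within = mean(apply(values, 1L, var)),
    I = I, J = J, RMS = RMS, SMS = SMS, EMS = EMS,
    degenerate = degenerate
  ), class = "icc_report")
}

#' Region-by-region stimulation campaign
#'
#' For every target region (or a subset), runs one simulation on the
#' network at the operating coupling `c5`: 1 s of stabilization, a 1 s
#' stimulation-free window, then a 1 s window during which the target
#' receives a constant stimulating current. Functional states are computed
#' separately for the before- and during-windows and summarized as the
#' functional effect, structural effect, and fractional activation of each
#' region's stimulation. Controllability diagnostics for the same network
#' and Spearman rank correlations among all measures are attached.
#'
#' @param net [structural_network()] or weight matrix.
#' @param delays delay matrix (ms) or `NULL`.
#' @param params [wc_params()]; `c5` is set to `c5_operating`.
#' @param c5_operating global coupling at which the network sits just below
#'   the oscillatory transition (see [find_transition_point()]).
#' @param seed integer; the simulation for target region r uses seed
#'   `seed + r`.
#' @param dt_ms integration step, ms.
#' @param stim_amplitude stimulating current.
#' @param stabilize_ms,window_ms stabilization period and analysis window
#'   lengths, ms.
#' @param max_lag_ms,threshold functional-connectivity settings (see
#'   [functional_connectivity()] and [fractional_activation()]).
#' @param targets region indices to stimulate (default: all).
#' @return list of class `stimulation_campaign`: `outcomes` (data.frame
#'   with one row per stimulated region: functional/structural effect and
#'   fractional activation), `profile` (from [controllability_profile()]),
#'   `correlations` (Spearman matrix over the six per-region measures),
#'   `c5_operating`, and the call settings.
#' @export
stimulation_campaign <- function(net, delays = NULL, params = wc_params(),
                                 c5_operating, seed = 1L, dt_ms = 0.1,
                                 stim_amplitude = 1.25,
                                 stabilize_ms = 1000, window_ms = 1000,
                                 max_lag_ms = 250, threshold = 0.6,
                                 targets = NULL) {
  A <- as_weights(net)
  n <- nrow(A)
  targets <- targets %||% seq_len(n)
  p <- params; p$c5 <- c5_operating
  onset <- stabilize_ms + window_ms
  offset <- onset + window_ms
  steps_win <- round(window_ms / dt_ms)
  idx_before <- seq.int(round(stabilize_ms / dt_ms) + 1L, length.out = steps_win)
  idx_during <- seq.int(round(onset / dt_ms) + 1L, length.out = steps_win)

  rows <- vector("list", length(targets))
  for (m in seq_along(targets)) {
    r <- targets[m]
    prot <- stimulus_protocol(target_region = r, amplitude = stim_amplitude,
                              onset_ms = onset, offset_ms = offset)
    sim <- tryCatch(
      simulate_network(A, delays, p, prot, duration_ms = offset,
                       dt_ms = dt_ms, seed = seed + r),
      error = function(e) stop("simulation for target region ", r,
                               " failed: ", conditionMessage(e), call. = FALSE)
    )
    fcb <- functional_connectivity(sim$E[, idx_before, drop = FALSE], dt_ms,
                                   window_ms, max_lag_ms)
    fcd <- functional_connectivity(sim$E[, idx_during, drop = FALSE], dt_ms,
                                   window_ms, max_lag_ms)
    rows[[m]] <- data.frame(
      region = r,
      functional_effect = functional_effect(fcb, fcd),
      structural_effect = structural_effect(A, fcb, fcd),
      fractional_activation = fractional_activation(fcb, fcd, threshold)
    )
  }
  outcomes <- do.call(rbind, rows)
  profile <- controllability_profile(net)
  meas <- cbind(profile[outcomes$region, c("degree", "avg_ctrl", "modal_ctrl")],
                outcomes[, c("functional_effect", "structural_effect",
                             "fractional_activation")])
  # a measure that is constant across regions has no rank ordering; its
  # correlations are reported as NA without the sd-zero warning
  correlations <- suppressWarnings(cor(meas, method = "spearman"))
  structure(list(outcomes = outcomes, profile = profile,
                 correlations = correlations, c5_operating = c5_operating,
                 seed = seed, dt_ms = dt_ms, threshold = threshold,
                 window_ms = window_ms, max_lag_ms = max_lag_ms),
            class = "stimulation_campaign")
}

#' Aggregate stimulation outcomes by cognitive system
#'
#' Per-system mean and standard error of the functional and structural
#' effects, plus the system-by-system connection density table:
#' `density(s, t)` is the number of present (nonzero-weight) edges between
#' systems s and t divided by the number of possible pairs (within-system
#' pairs counted as `n (n - 1) / 2`).
#'
#' @param outcomes `stimulation_campaign` result or its `outcomes`
#'   data.frame.
#' @param regions region table with a `system` column.
#' @param net [structural_network()] or weight matrix (for the density
#'   table).
#' @return list with `system_summary` (data.frame: system, n, mean and SEM
#'   of each effect) and `density_table` (symmetric systems x systems
#'   matrix). Singleton systems get `NA` SEM with a warning.
#' @export
system_aggregate <- function(outcomes, regions, net) {
  if (inherits(outcomes, "stimulation_campaign")) outcomes <- outcomes$outcomes
  validate_regions(regions)
  A <- as_weights(net)
  sys <- as.character(regions$system)
  if (nrow(regions) != nrow(A)) stop("region table does not match network size",
                                     call. = FALSE)
  sys_of_outcome <- sys[outcomes$region]
  lv <- unique(sys)
  summ <- do.call(rbind, lapply(lv, function(s) {
    sel <- outcomes[sys_of_outcome == s, , drop = FALSE]
    n <- nrow(sel)
    sem <- function(x) if (n > 1) sd(x) / sqrt(n) else NA_real_
    data.frame(system = s, n = n,
               functional_mean = mean(sel$functional_effect),
               functional_sem = sem(sel$functional_effect),
               structural_mean = mean(sel$structural_effect),
               structural_sem = sem(sel$structural_effect),
               stringsAsFactors = FALSE)
  }))
  if (any(summ$n == 1)) {
    warning("singleton system(s): SEM undefined for ",
            paste(summ$system[summ$n == 1], collapse = ", "))
  }
  density_table <- connection_density(A, sys)
  list(system_summary = summ, density_table = density_table)
}

#' System-block connection density
#'
#' @param net [structural_network()] or weight matrix.
#' @param systems character vector of per-region system tags.
#' @return symmetric matrix of realized edge densities per system pair.
#' @export
connection_density <- function(net, systems) {
  A <- as_weights(net)
  lv <- unique(systems)
  k <- length(lv)
  dens <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  present <- A > 0
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(systems == lv[a]); ib <- which(systems == lv[b])
      if (a == b) {
        na <- length(ia)
        possible <- na * (na - 1) / 2
        edges <- sum(present[ia, ia]) / 2
      } else {
        possible <- length(ia) * length(ib)
        edges <- sum(present[ia, ib])
      }
      dens[a, b] <- dens[b, a] <- if (possible > 0) edges / possible else NA_real_
    }
  }
  dens
}
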