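#' Default cognitive-system labels and block density profile
#'
#' Four coarse cognitive systems are used by default: sensory/association
#' cortex, higher-order cognitive regions, the medial default mode network,
#' and subcortical structures. The default block densities follow the
#' empirical ordering of connection densities between these systems in human
#' structural connectomes: the subcortical block is by far the densest
#' (0.412 within), the default mode next (0.257), with sparse connectivity
#' within and between the distributed cortical systems.
#'
#' @return A symmetric 4x4 matrix of edge probabilities with system names as
#'   dimnames.
#' @export
default_density_profile <- function() {
  sys <- c("sensory_association", "higher_order", "default_mode", "subcortical")
  m <- matrix(c(
    0.054, 0.025, 0.059, 0.094,
    0.025, 0.067, 0.046, 0.068,
    0.059, 0.046, 0.257, 0.137,
    0.094, 0.068, 0.137, 0.412
  ), 4, 4, byrow = TRUE, dimnames = list(sys, sys))
  m
}

# default number of regions per system for an 83-region parcellation
default_system_sizes <- function(n_regions, n_systems) {
  if (n_systems == 4L && n_regions == 83L) {
    return(c(sensory_association = 34L, higher_order = 22L,
             default_mode = 12L, subcortical = 15L))
  }
  base <- rep(n_regions %/% n_systems, n_systems)
  extra <- n_regions %% n_systems
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  names(base) <- if (n_systems == 4L) {
    rownames(default_density_profile())
  } else {
    paste0("system", seq_len(n_systems))
  }
  base
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  needed <- c("label", "x_mm", "y_mm", "z_mm", "volume", "system")
  missing <- setdiff(needed, names(regions))
  if (length(missing)) {
    stop("region table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regions) < 2L) stop("need at least 2 regions", call. = FALSE)
  coords <- as.matrix(regions[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(coords))) stop("region coordinates must be finite", call. = FALSE)
  if (!all(is.finite(regions$volume)) || any(regions$volume <= 0)) {
    stop("region volumes must be positive and finite", call. = FALSE)
  }
  if (any(!nzchar(as.character(regions$system)))) {
    stop("system tags must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(regions$label)) stop("region labels must be unique", call. = FALSE)
  invisible(regions)
}

#' Construct a structural network object
#'
#' Bundles a symmetric, nonnegative, zero-diagonal weight matrix (streamline
#' density between region pairs) with its region metadata table.
#'
#' @param weights N x N numeric matrix; symmetric, nonnegative, zero diagonal.
#' @param regions data.frame with columns `label`, `x_mm`, `y_mm`, `z_mm`,
#'   `volume`, `system` and one row per region.
#' @param symmetry_tol absolute tolerance when checking symmetry.
#' @return An object of class `structural_network` (a list with elements
#'   `weights` and `regions`).
#' @export
structural_network <- function(weights, regions, symmetry_tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop(sprintf("weight matrix must be square, got %d x %d",
                 nrow(weights), ncol(weights)), call. = FALSE)
  }
  validate_regions(regions)
  if (nrow(regions) != nrow(weights)) {
    stop(sprintf("matrix is %d x %d but region table has %d rows",
                 nrow(weights), ncol(weights), nrow(regions)), call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("weights must be finite (no NaN/NA)", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetry_tol) {
    stop(sprintf("weight matrix is asymmetric (max |A - t(A)| = %.3g > %.3g)",
                 asym, symmetry_tol), call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal", call. = FALSE)
  if (all(weights == 0)) stop("weight matrix has no positive entries", call. = FALSE)
  dimnames(weights) <- list(regions$label, regions$label)
  structure(list(weights = weights, regions = regions),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("structural_network: %d regions, %d edges (density %.3f)\n",
              n, ne, ne / (n * (n - 1) / 2)))
  cat("systems:", paste(sprintf("%s (%d)", names(table(x$regions$system)),
                                table(x$regions$system)), collapse = ", "), "\n")
  invisible(x)
}

# accept either a structural_network or a bare matrix
as_weights <- function(net) {
  if (inherits(net, "structural_network")) net$weights else as.matrix(net)
}

#' Normalize streamline counts by regional volume
#'
#' Converts raw streamline counts into streamline densities by dividing each
#' count by the summed volume of the two endpoint regions:
#' `density(i, j) = counts(i, j) / (volume(i) + volume(j))`.
#'
#' @param streamline_counts symmetric nonnegative N x N matrix.
#' @param volumes positive numeric vector of length N.
#' @return N x N density matrix (symmetry is preserved).
#' @export
volume_normalize <- function(streamline_counts, volumes) {
  m <- as.matrix(streamline_counts)
  stopifnot(nrow(m) == ncol(m), length(volumes) == nrow(m))
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("all volumes must be positive and finite", call. = FALSE)
  }
  if (any(m < 0)) stop("streamline counts must be nonnegative", call. = FALSE)
  m / outer(volumes, volumes, `+`)
}

#' Inter-regional conduction delays from coordinates
#'
#' Delays are Euclidean distance divided by a constant transmission
#' velocity. The default velocity of 10 mm/ms (= 10 m/s) is typical for
#' myelinated long-range fibers.
#'
#' @param coords N x 3 matrix of region coordinates in mm.
#' @param velocity transmission velocity in mm/ms.
#' @return Symmetric N x N matrix of delays in ms with zero diagonal.
#' @export
compute_delays <- function(coords, velocity = 10) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (!is.numeric(velocity) || length(velocity) != 1 || velocity <= 0) {
    stop("velocity must be a single positive number (mm/ms)", call. = FALSE)
  }
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d / velocity
}

# Sample spatially clustered coordinates: one Gaussian cluster per system
# inside a bounded box, with a minimum inter-region distance so that no two
# regions are (physiologically implausibly) coincident.
sample_coords <- function(systems, box_mm, cluster_sd, min_dist) {
  sys_names <- unique(systems)
  n <- length(systems)
  # cluster centers inside the central half of the box
  centers <- matrix(runif(3 * length(sys_names), box_mm * 0.25, box_mm * 0.75),
                    ncol = 3, dimnames = list(sys_names, NULL))
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (attempt in seq_len(200L)) {
      p <- centers[systems[i], ] + rnorm(3, 0, cluster_sd)
      p <- pmin(pmax(p, 0.1 * box_mm), 0.9 * box_mm)
      ok <- i == 1L ||
        min(sqrt(colSums((t(coords[seq_len(i - 1L), , drop = FALSE]) - p)^2))) >= min_dist
      if (ok) break
    }
    if (!ok) stop("could not place region ", i, " with min_dist = ", min_dist,
                  "; enlarge the box or reduce min_dist", call. = FALSE)
    coords[i, ] <- p
  }
  coords
}

#' Generate a synthetic structural connectome
#'
#' Builds a sparse, weighted, undirected structural brain network with
#' modular block structure and a spatial embedding, emulating
#' volume-normalized streamline-density connectomes from deterministic
#' tractography. Edges are drawn independently per region pair with a
#' probability given by the block `density_profile` for the pair of systems
#' involved; nonzero streamline counts are log-normal (heavy-tailed, so the
#' network has hubs), then divided by the summed endpoint volumes, and
#' finally rescaled so the mean weighted degree (mean row sum) of the
#' weight matrix equals `weight_scale`. Pinning the mean weighted degree
#' standardizes the coupling strength of downstream neural-mass simulations
#' across realizations, the role played by cross-subject matrix
#' normalization in empirical studies.
#'
#' Coordinates are sampled as per-system Gaussian clusters inside a bounded
#' box so that conduction delays at 10 mm/ms fall in the sub-millisecond to
#' ~20 ms range observed for human inter-regional distances.
#'
#' @param n_regions number of regions (default 83, a whole-brain
#'   cortical + subcortical parcellation scale).
#' @param n_systems number of cognitive systems (default 4).
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param density_profile symmetric `n_systems` x `n_systems` matrix of edge
#'   probabilities in (0, 1]; defaults to [default_density_profile()] when
#'   `n_systems == 4`, otherwise 0.25 within / 0.06 between systems.
#' @param weight_scale target mean weighted degree of the final weight
#'   matrix. The default of 6 places the oscillatory transition of the
#'   coupled Wilson-Cowan model with default parameters inside the standard
#'   global coupling sweep range (c5 in \[1.0, 1.5\]).
#' @param box_mm edge length of the bounding box for coordinates (mm).
#' @param cluster_sd spatial spread of each system's regions (mm).
#' @param min_dist_mm minimum distance between any two regions (mm).
#' @param weight_meanlog,weight_sdlog log-normal parameters for raw
#'   streamline counts.
#' @param volume_meanlog,volume_sdlog log-normal parameters for region
#'   volumes (arbitrary units).
#' @return A list with elements `network` (a [structural_network()]) and
#'   `regions` (its region table, for convenience).
#' @export
generate_connectome <- function(n_regions = 83L, n_systems = 4L, seed = 1L,
                                density_profile = NULL, weight_scale = 6,
                                box_mm = 140, cluster_sd = 16, min_dist_mm = 6,
                                weight_meanlog = 0, weight_sdlog = 0.75,
                                volume_meanlog = 0, volume_sdlog = 0.4) {
  n_regions <- as.integer(n_regions)
  n_systems <- as.integer(n_systems)
  if (n_regions < 2L) stop("n_regions must be >= 2", call. = FALSE)
  if (n_systems > n_regions) stop("n_systems may not exceed n_regions", call. = FALSE)
  if (!is.numeric(weight_scale) || weight_scale <= 0) {
    stop("weight_scale must be positive", call. = FALSE)
  }
  if (is.null(density_profile)) {
    density_profile <- if (n_systems == 4L) {
      default_density_profile()
    } else {
      p <- matrix(0.06, n_systems, n_systems)
      diag(p) <- 0.25
      p
    }
  }
  density_profile <- as.matrix(density_profile)
  if (!all(dim(density_profile) == n_systems)) {
    stop("density_profile must be ", n_systems, " x ", n_systems, call. = FALSE)
  }
  if (any(density_profile <= 0) || any(density_profile > 1)) {
    stop("density_profile entries must lie in (0, 1]", call. = FALSE)
  }
  density_profile <- (density_profile + t(density_profile)) / 2

  sizes <- default_system_sizes(n_regions, n_systems)
  sys_names <- rownames(density_profile) %||% names(sizes)
  rownames(density_profile) <- colnames(density_profile) <- sys_names
  names(sizes) <- sys_names

  with_seed(seed, {
    systems <- rep(sys_names, times = sizes)
    sys_idx <- rep(seq_len(n_systems), times = sizes)
    volumes <- rlnorm(n_regions, volume_meanlog, volume_sdlog)
    coords <- sample_coords(systems, box_mm, cluster_sd, min_dist_mm)

    counts <- matrix(0, n_regions, n_regions)
    ut <- which(upper.tri(counts), arr.ind = TRUE)
    p_edge <- density_profile[cbind(sys_idx[ut[, 1]], sys_idx[ut[, 2]])]
    present <- rbinom(nrow(ut), 1L, p_edge) == 1L
    w_raw <- numeric(nrow(ut))
    w_raw[present] <- rlnorm(sum(present), weight_meanlog, weight_sdlog)
    counts[ut] <- w_raw
    counts <- counts + t(counts)

    dens <- volume_normalize(counts, volumes)
    mdeg <- mean(rowSums(dens))
    if (mdeg == 0) stop("generated network has no edges; increase densities",
                        call. = FALSE)
    weights <- dens * (weight_scale / mdeg)

    regions <- data.frame(
      label = sprintf("region_%03d", seq_len(n_regions)),
      x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
      volume = volumes, system = systems,
      stringsAsFactors = FALSE
    )
    net <- structural_network(weights, regions)
    list(network = net, regions = regions)
  })
}

#' Weighted degree (strength) of each region
#'
#' @param net a [structural_network()] or weight matrix.
#' @return numeric vector of row sums of the weight matrix.
#' @export
weighted_degree <- function(net) {
  rowSums(as_weights(net))
}
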