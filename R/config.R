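default_config_tree <- function() {
  list(
    paths = list(network = NULL, regions = NULL, output_dir = "."),
    params = list(tau = 8, c1 = 16, c2 = 12, c3 = 15, c4 = 3, c5 = 1,
                  a_e = 1.3, a_i = 2, theta_e = 4, theta_i = 3.7,
                  sigma = 1e-5, s_e_max = NULL, s_i_max = NULL),
    simulation = list(dt_ms = 0.1, duration_ms = 3000),
    sweep = list(c5_min = 1.0, c5_max = 1.5, c5_step = 0.05,
                 jump_factor = 3, rate_floor = 0.05),
    fc = list(window_ms = 1000, max_lag_ms = 250, threshold = 0.6),
    stimulation = list(amplitude = 1.25),
    seeds = list(network = 1L, simulation = 1L),
    verbosity = 1L
  )
}

check_unknown_keys <- function(user, defaults, path = character()) {
  if (!is.list(user)) return(invisible())
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    where <- if (length(path)) paste0(" under '", paste(path, collapse = "."), "'") else ""
    stop("unknown config key(s)", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      check_unknown_keys(user[[k]], defaults[[k]], c(path, k))
    }
  }
  invisible()
}

#' Validate a run configuration file
#'
#' Reads a YAML configuration, rejects unknown keys (naming them) and
#' out-of-range values (with the violated bound), and fills every missing
#' setting with the package default: the standard Wilson-Cowan constants,
#' dt = 0.1 ms, the coupling sweep grid 1.0 to 1.5 in steps of 0.05, a 1 s
#' correlation window with 250 ms maximum lag, activation threshold 0.6,
#' and stimulation amplitude 1.25. An empty (or absent) file therefore
#' yields the full default configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return validated configuration list of class `netstim_config`.
#' @export
validate_config <- function(path = NULL) {
  defaults <- default_config_tree()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path) %||% list()
  }
  check_unknown_keys(user, defaults)
  cfg <- modifyList(defaults, user)

  must <- function(ok, what) if (!ok) stop("config error: ", what, call. = FALSE)
  p <- cfg$params
  must(p$tau > 0, "params.tau must be > 0")
  must(p$a_e > 0 && p$a_i > 0, "sigmoid slopes must be > 0")
  must(p$sigma >= 0, "params.sigma must be >= 0")
  must(p$c5 >= 0, "params.c5 must be >= 0")
  must(cfg$simulation$dt_ms > 0, "simulation.dt_ms must be > 0")
  must(cfg$simulation$duration_ms > 0, "simulation.duration_ms must be > 0")
  must(cfg$sweep$c5_step > 0, "sweep.c5_step must be > 0")
  must(cfg$sweep$c5_max > cfg$sweep$c5_min,
       "sweep.c5_max must exceed sweep.c5_min")
  must(cfg$sweep$jump_factor > 1, "sweep.jump_factor must be > 1")
  must(cfg$sweep$rate_floor >= 0, "sweep.rate_floor must be >= 0")
  must(cfg$fc$window_ms > 0, "fc.window_ms must be > 0")
  must(cfg$fc$max_lag_ms >= 0 && cfg$fc$max_lag_ms < cfg$fc$window_ms,
       "fc.max_lag_ms must be in [0, window_ms)")
  must(cfg$fc$threshold >= 0, "fc.threshold must be >= 0 (got negative)")
  must(is.finite(cfg$stimulation$amplitude), "stimulation.amplitude must be finite")
  for (s in names(cfg$seeds)) {
    must(is.numeric(cfg$seeds[[s]]) && cfg$seeds[[s]] == round(cfg$seeds[[s]]),
         paste0("seeds.", s, " must be an integer"))
  }
  for (pp in c("network", "regions")) {
    if (!is.null(cfg$paths[[pp]])) {
      must(file.exists(cfg$paths[[pp]]),
           paste0("paths.", pp, " does not exist: ", cfg$paths[[pp]]))
    }
  }
  cfg$params <- do.call(wc_params, p[!vapply(p, is.null, logical(1))])
  class(cfg) <- "netstim_config"
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the full
#' validated configuration, its MD5 hash, the seeds, the package version,
#' and the R version, as YAML.
#'
#' @param config a `netstim_config`.
#' @param path output file.
#' @param extra optional named list of additional fields (e.g. the
#'   subcommand and its outputs).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  cfg_plain <- unclass(config)
  cfg_plain$params <- unclass(cfg_plain$params)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg_plain, tmp)
  manifest <- c(list(
    tool = "netstim",
    version = as.character(utils::packageVersion("netstim")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(tmp)),
    config = cfg_plain
  ), extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
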