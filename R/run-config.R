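#' Run configuration for the torpor/energetics pipeline
#'
#' Bundles the clock-time analysis window, the calendar restriction used for
#' roost thermal summaries, MCMC settings, torpor-detection thresholds, and
#' the metabolic calibration into a single validated object. Times are local
#' clock time expressed as minutes since midnight (0-based); dates are
#' ISO-8601. The defaults encode the study conditions: bats occupy roosts
#' between 4:45 AM (285 min) and 9:00 PM (1260 min), thermal summaries are
#' restricted to 28 July-30 September, and samplers run 3 chains of 12,000
#' iterations with 2,000 warm-up.
#'
#' @param window_start,window_end analysis window, minutes since midnight;
#'   must satisfy `0 <= window_start < window_end < 1440`.
#' @param date_range_start,date_range_end ISO dates bounding roost thermal
#'   summaries.
#' @param rng_seed integer seed recorded with every run.
#' @param n_chains,n_iter,n_warmup MCMC settings (`n_warmup < n_iter`).
#' @param rise_rate sustained warming rate (degC/min) that ends a torpor bout.
#' @param rise_sustain minutes over which `rise_rate` must be sustained.
#' @param onset_reference_min length (min) of the homeothermic reference
#'   window, starting at `window_start`, used to estimate the torpor-onset
#'   threshold when none is supplied.
#' @param metabolic a [metabolic_config()] object.
#' @return an object of class `run_config` (a validated list).
#' @seealso [read_run_config()], [write_run_config()]
#' @export
run_config <- function(window_start = 285L,
                       window_end = 1260L,
                       date_range_start = "2018-07-28",
                       date_range_end = "2018-09-30",
                       rng_seed = 1L,
                       n_chains = 3L,
                       n_iter = 12000L,
                       n_warmup = 2000L,
                       rise_rate = 0.5,
                       rise_sustain = 5,
                       onset_reference_min = 30,
                       metabolic = metabolic_config()) {
  cfg <- list(
    window_start = as.numeric(window_start),
    window_end = as.numeric(window_end),
    date_range_start = as.character(date_range_start),
    date_range_end = as.character(date_range_end),
    rng_seed = as.integer(rng_seed),
    n_chains = as.integer(n_chains),
    n_iter = as.integer(n_iter),
    n_warmup = as.integer(n_warmup),
    rise_rate = as.numeric(rise_rate),
    rise_sustain = as.numeric(rise_sustain),
    onset_reference_min = as.numeric(onset_reference_min),
    metabolic = metabolic
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (window_start >= window_end) {
      stop_fmt("window_start (%s) must be < window_end (%s)", window_start, window_end)
    }
    if (window_start < 0 || window_end >= 1440) {
      stop_fmt("analysis window must lie within [0, 1440) minutes")
    }
    if (n_warmup >= n_iter) stop_fmt("n_warmup (%d) must be < n_iter (%d)", n_warmup, n_iter)
    if (n_chains < 1L) stop_fmt("n_chains must be >= 1")
    if (rise_rate <= 0) stop_fmt("rise_rate must be > 0")
    d1 <- as.Date(date_range_start); d2 <- as.Date(date_range_end)
    if (is.na(d1) || is.na(d2)) stop_fmt("date_range bounds must be valid ISO dates")
    if (d1 > d2) stop_fmt("date_range_start must be <= date_range_end")
  })
  if (!inherits(cfg$metabolic, "metabolic_config")) {
    stop_fmt("`metabolic` must be a metabolic_config object")
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  window: %s-%s (%g min)\n",
              minutes_to_clock(as.integer(x$window_start)),
              minutes_to_clock(as.integer(x$window_end)),
              x$window_end - x$window_start))
  cat(sprintf("  dates:  %s to %s\n", x$date_range_start, x$date_range_end))
  cat(sprintf("  mcmc:   %d chains x %d iter (%d warmup), seed %d\n",
              x$n_chains, x$n_iter, x$n_warmup, x$rng_seed))
  cat(sprintf("  detect: rise >= %g degC/min sustained %g min\n",
              x$rise_rate, x$rise_sustain))
  invisible(x)
}

#' Length of the analysis window in minutes
#' @param config a [run_config()].
#' @return minutes (975 at the defaults).
#' @export
window_length <- function(config) config$window_end - config$window_start

#' Read / write a run configuration file
#'
#' Configurations are stored as a flat human-editable YAML mapping; unknown
#' keys are rejected so that typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @param config a [run_config()] object.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_fmt("unknown config key(s): %s", paste(extra, collapse = ", "))
  if (!is.null(raw$metabolic)) raw$metabolic <- do.call(metabolic_config, raw$metabolic)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$metabolic <- unclass(out$metabolic)
  yaml::write_yaml(out, path)
  invisible(path)
}
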