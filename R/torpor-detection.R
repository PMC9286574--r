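#' Estimate the torpor-onset threshold from a homeothermic reference window
#'
#' Torpor is taken to begin when skin temperature drops below the lowest
#' skin temperature recorded while the bat (or, in pooled mode, any bat that
#' day) was still maintaining homeothermy. This returns that minimum over a
#' reference window, by default the first half hour after roost entry, when
#' bats are reliably normothermic.
#'
#' @param trace a [skin_trace()].
#' @param reference_window `c(start, end)` in minutes since midnight; must
#'   overlap the trace.
#' @return the onset threshold, degC.
#' @export
estimate_onset_threshold <- function(trace, reference_window) {
  stopifnot(inherits(trace, "skin_trace"))
  sel <- in_window(trace$t, reference_window)
  if (!any(sel)) {
    stop_fmt(paste("reference window [%g, %g) does not overlap trace %s/%s;",
                   "supply the onset threshold explicitly"),
             reference_window[1], reference_window[2], trace$bat_id, trace$date)
  }
  min(trace$skin_temp[sel])
}

#' Delineate torpor bouts in a skin-temperature trace
#'
#' A bout opens at the first sample with skin temperature below `t_on` while
#' no bout is open, and closes at the first sample that begins a sustained
#' steep rise: the average warming rate over the next `rise_sustain` minutes
#' is at least `rise_rate` and the immediate next step also warms at
#' `rise_rate` or more (so the close lands where the rise actually starts,
#' not where a look-ahead average first senses it). A bout still open at the
#' trace end closes at the last sample, which covers bats that left the
#' microhabitat while torpid. After a close, scanning resumes once the steep
#' rise has slackened, so an arousal ramp cannot re-open the bout it ended.
#' Bouts shorter than one sampling interval are discarded.
#'
#' @param trace a [skin_trace()].
#' @param t_on onset threshold, degC (see [estimate_onset_threshold()]).
#' @param rise_rate minimum sustained warming rate, degC/min (> 0).
#' @param rise_sustain minutes over which the rise must be sustained
#'   (>= the trace's sampling interval).
#' @return a data frame with columns `start_min`, `end_min`, `duration_min`;
#'   zero rows when the trace never drops below `t_on`.
#' @export
delineate_bouts <- function(trace, t_on, rise_rate = 0.5, rise_sustain = 5) {
  stopifnot(inherits(trace, "skin_trace"))
  if (!is.finite(t_on)) stop_fmt("t_on must be finite")
  if (rise_rate <= 0) stop_fmt("rise_rate must be > 0")
  if (rise_sustain < trace$dt) stop_fmt("rise_sustain must be >= sampling interval")
  x <- trace$skin_temp
  t <- trace$t
  n <- length(x)
  k <- max(1L, ceiling(rise_sustain / trace$dt))

  rise_begins <- function(i) {
    if (i >= n) return(FALSE)
    j <- min(i + k, n)
    step_ok <- (x[i + 1L] - x[i]) / (t[i + 1L] - t[i]) >= rise_rate
    avg_ok <- (x[j] - x[i]) / (t[j] - t[i]) >= rise_rate
    step_ok && avg_ok
  }

  starts <- numeric(0); ends <- numeric(0)
  open_at <- NA_real_
  i <- 1L
  while (i <= n) {
    if (is.na(open_at)) {
      if (x[i] < t_on) open_at <- t[i]
      i <- i + 1L
    } else if (rise_begins(i)) {
      starts <- c(starts, open_at); ends <- c(ends, t[i])
      open_at <- NA_real_
      # skip forward past the steep portion of this arousal/departure rise
      i <- i + 1L
      while (i < n && (x[i + 1L] - x[i]) / (t[i + 1L] - t[i]) >= rise_rate / 2) {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (!is.na(open_at)) { starts <- c(starts, open_at); ends <- c(ends, t[n]) }

  keep <- (ends - starts) >= trace$dt
  data.frame(start_min = starts[keep], end_min = ends[keep],
             duration_min = ends[keep] - starts[keep])
}

#' Total torpor and daily ambient temperature for one bat-day
#'
#' Produces the response/covariate row consumed by the hierarchical
#' torpor-duration model: total bout minutes clipped to the analysis window,
#' the mean ambient temperature over the window, and the bat's body mass.
#'
#' @param trace the [skin_trace()] the bouts came from.
#' @param bouts data frame from [delineate_bouts()].
#' @param ambient ambient temperature series aligned with `trace$t`;
#'   defaults to the trace's own `ambient` field. At most 10% of window
#'   samples may be missing.
#' @param config a [run_config()] supplying the analysis window.
#' @return one-row data frame: `bat_id`, `date`, `torpor_min`, `t_mean_day`,
#'   `body_mass`.
#' @export
summarize_torpor_day <- function(trace, bouts, ambient = NULL,
                                 config = run_config()) {
  stopifnot(inherits(trace, "skin_trace"))
  window <- c(config$window_start, config$window_end)
  ambient <- ambient %||% trace$ambient
  if (is.null(ambient)) stop_fmt("no ambient series supplied for %s/%s",
                                 trace$bat_id, trace$date)
  sel <- in_window(trace$t, window)
  amb <- ambient[sel]
  expected <- window_length(config) / trace$dt
  if (sum(is.finite(amb)) < 0.9 * expected) {
    stop_fmt("ambient series covers < 90%% of the analysis window for %s/%s",
             trace$bat_id, trace$date)
  }
  torpor_min <- 0
  if (nrow(bouts)) {
    torpor_min <- sum(pmax(0, pmin(bouts$end_min, window[2]) -
                              pmax(bouts$start_min, window[1])))
  }
  data.frame(bat_id = trace$bat_id, date = trace$date,
             torpor_min = torpor_min,
             t_mean_day = mean(amb, na.rm = TRUE),
             body_mass = trace$body_mass)
}

#' Run torpor detection over a collection of traces
#'
#' Convenience wrapper for the `detect` stage: estimates per-day onset
#' thresholds (pooled across the bats present each day, the default, or per
#' bat-day), delineates bouts, and assembles the model-ready daily records.
#' Traces with internal gaps longer than one sampling interval are dropped
#' (only full days enter the model) and reported in the `dropped` element.
#'
#' @param traces list of [skin_trace()] objects.
#' @param config a [run_config()].
#' @param t_on optional scalar onset threshold overriding estimation.
#' @param threshold_mode `"pooled"` (per-day minimum across bats) or
#'   `"per-bat"`.
#' @return list with `bouts` (one data frame, bat_id/date/start_min/end_min),
#'   `records` (rbind of [summarize_torpor_day()] rows) and `dropped`
#'   (character vector of bat-day keys excluded for gaps).
#' @export
detect_torpor_days <- function(traces, config = run_config(), t_on = NULL,
                               threshold_mode = c("pooled", "per-bat")) {
  threshold_mode <- match.arg(threshold_mode)
  gaps <- vapply(traces, function(tr) tr$has_gaps, logical(1))
  dropped <- vapply(traces[gaps], function(tr) paste(tr$bat_id, tr$date, sep = "/"),
                    character(1))
  traces <- traces[!gaps]
  ref <- c(config$window_start, config$window_start + config$onset_reference_min)
  day_min <- vapply(traces, estimate_onset_threshold, numeric(1),
                    reference_window = ref)
  dates <- vapply(traces, function(tr) tr$date, character(1))
  pooled <- tapply(day_min, dates, min)

  bouts_all <- list(); records <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    thr <- t_on %||% switch(threshold_mode,
                            "pooled" = pooled[[tr$date]],
                            "per-bat" = day_min[[i]])
    b <- delineate_bouts(tr, thr, config$rise_rate, config$rise_sustain)
    if (nrow(b)) {
      bouts_all[[length(bouts_all) + 1L]] <-
        cbind(data.frame(bat_id = tr$bat_id, date = tr$date), b)
    }
    records[[i]] <- summarize_torpor_day(tr, b, config = config)
  }
  list(bouts = if (length(bouts_all)) do.call(rbind, bouts_all) else
         data.frame(bat_id = character(), date = character(),
                    start_min = numeric(), end_min = numeric(),
                    duration_min = numeric()),
       records = do.call(rbind, records),
       dropped = unname(dropped))
}
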