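#' Metabolic calibration for the energy-expenditure simulator
#'
#' Physiological constants of the Scholander-type metabolic model: below the
#' lower critical temperature `t_lc` the homeothermic mass-specific rate
#' rises linearly with conductance slope `k_h` above the basal rate `bmr`;
#' the torpid mass-specific rate follows a Q10 curve anchored at `tmr_ref`
#' (measured at `t_ref`) and is capped at the homeothermic rate so torpor
#' can never cost more than homeothermy at the same temperature. Oxygen
#' consumption converts to energy at `oxyjoule` J per mL O2.
#'
#' The default values are calibration placeholders in the right range for a
#' small vespertilionid bat; they are deliberately user-settable because
#' species-specific laboratory measurements should replace them whenever
#' available, and the package's structural results (dominance, monotonicity,
#' flatness of the heterotherm energy curve) do not depend on their exact
#' values.
#'
#' @param t_lc lower critical temperature, degC.
#' @param bmr basal mass-specific metabolic rate, mL O2 g-1 h-1.
#' @param k_h thermal-conductance slope below `t_lc`, mL O2 g-1 h-1 degC-1.
#' @param tmr_ref torpid mass-specific rate at `t_ref`, mL O2 g-1 h-1.
#' @param t_ref reference temperature for `tmr_ref`, degC.
#' @param q10 factor by which the torpid rate changes per 10 degC (> 1).
#' @param oxyjoule J per mL O2 (default 20.1).
#' @param mass body mass, g.
#' @return a list of class `metabolic_config`.
#' @export
metabolic_config <- function(t_lc = 33.0, bmr = 1.5, k_h = 0.18,
                             tmr_ref = 0.05, t_ref = 20.0, q10 = 2.5,
                             oxyjoule = 20.1, mass = 8.0) {
  cfg <- list(t_lc = t_lc, bmr = bmr, k_h = k_h, tmr_ref = tmr_ref,
              t_ref = t_ref, q10 = q10, oxyjoule = oxyjoule, mass = mass)
  rates <- c(bmr = bmr, k_h = k_h, tmr_ref = tmr_ref, oxyjoule = oxyjoule,
             mass = mass)
  if (any(rates <= 0)) stop_fmt("all metabolic rates and mass must be > 0")
  if (q10 <= 1) stop_fmt("q10 must be > 1")
  structure(cfg, class = "metabolic_config")
}

#' Whole-animal metabolic rate at a given ambient temperature
#'
#' Homeothermy: per-gram rate `bmr` within the thermoneutral zone
#' (`t_a >= t_lc`), else `bmr + k_h * (t_lc - t_a)`. Torpor:
#' `min(tmr_ref * q10^((t_a - t_ref)/10), homeothermic rate)`. Whole-animal
#' output is `per-gram rate * mass * oxyjoule / 60` J per minute.
#'
#' @param state `"torpor"` or `"homeothermy"`.
#' @param t_a ambient temperature, degC (vectorised).
#' @param cfg a [metabolic_config()].
#' @return J/min, whole animal, same length as `t_a`.
#' @export
metabolic_rate <- function(state = c("homeothermy", "torpor"), t_a,
                           cfg = metabolic_config()) {
  state <- match.arg(state)
  homeo <- cfg$bmr + cfg$k_h * pmax(cfg$t_lc - t_a, 0)
  pg <- if (state == "homeothermy") homeo else {
    pmin(cfg$tmr_ref * cfg$q10^((t_a - cfg$t_ref) / 10), homeo)
  }
  pg * cfg$mass * cfg$oxyjoule / 60
}

#' Baseline anchoring of the torpor-duration rule
#'
#' The simulator anchors simulated torpor to what was observed: a day in
#' the baseline "average" microhabitat (window-mean temperature `t_bar`)
#' receives the observed mean torpor duration `d_bar`, and other
#' microhabitats shift that duration along the fitted temperature slope.
#' `frac_morning` of the total goes to the morning bout unless the
#' remaining afternoon bout would fall below `min_afternoon` minutes, in
#' which case all torpor happens in the morning.
#'
#' @param d_bar mean observed daily torpor duration, minutes.
#' @param t_bar baseline microhabitat window-mean temperature, degC.
#' @param frac_morning fraction of torpor allocated to the morning bout
#'   (default 0.869; the afternoon takes the complement, 0.131).
#' @param min_afternoon minimum viable afternoon bout, minutes (default 30).
#' @param window_len analysis-window length used for validation, minutes.
#' @return a list of class `simulation_baseline`.
#' @export
simulation_baseline <- function(d_bar, t_bar, frac_morning = 0.869,
                                min_afternoon = 30, window_len = 975) {
  assert_scalar_num(d_bar, "d_bar"); assert_scalar_num(t_bar, "t_bar")
  if (d_bar < 0 || d_bar > window_len) {
    stop_fmt("d_bar must lie in [0, window length = %g]", window_len)
  }
  if (frac_morning <= 0 || frac_morning >= 1) stop_fmt("frac_morning must be in (0, 1)")
  structure(list(d_bar = d_bar, t_bar = t_bar, frac_morning = frac_morning,
                 min_afternoon = min_afternoon),
            class = "simulation_baseline")
}

#' Baseline from observed records and used-roost temperatures
#'
#' @param records torpor-day records (see [summarize_torpor_day()]).
#' @param used_mean_temps window-mean temperatures of used roosts, degC.
#' @param ... passed to [simulation_baseline()].
#' @return a [simulation_baseline()].
#' @export
simulation_baseline_from <- function(records, used_mean_temps, ...) {
  simulation_baseline(mean(records$torpor_min), mean(used_mean_temps), ...)
}

#' Daily torpor duration implied by a microhabitat's temperature
#'
#' Shifts the baseline duration along a posterior slope draw:
#' `D = clamp(d_bar + beta_draw * (t_mean - t_bar), 0, window_len)`.
#'
#' @param t_mean the microhabitat-day's window-mean temperature, degC.
#' @param base a [simulation_baseline()].
#' @param beta_draw torpor-duration slope, min/degC (posterior draw).
#' @param window_len analysis-window length, minutes.
#' @return minutes of torpor, in [0, window_len].
#' @export
torpor_duration_for_day <- function(t_mean, base, beta_draw, window_len = 975) {
  stopifnot(window_len > 0)
  pmin(pmax(base$d_bar + beta_draw * (t_mean - base$t_bar), 0), window_len)
}

#' Lay out a day's torpor/homeothermy schedule
#'
#' Bats enter torpor immediately on entering the roost, so the morning bout
#' starts at the window start; the evening bout is anchored to end at the
#' window exit. `frac_morning` of the total duration goes to the morning
#' unless the evening share would be shorter than `min_afternoon` minutes,
#' in which case the whole duration is a single morning bout. Segment
#' boundaries are kept continuous (fractional minutes), so scheduled torpor
#' minutes equal `d` exactly.
#'
#' @param d total torpor, minutes, in [0, window length].
#' @param window `c(start, end)` minutes since midnight.
#' @param base a [simulation_baseline()] (supplies the split rule).
#' @return data frame of contiguous segments tiling the window:
#'   `start_min`, `end_min`, `state` ("torpor"/"homeothermy").
#' @export
allocate_bouts <- function(d, window = c(285, 1260),
                           base = simulation_baseline(400, 20.3)) {
  len <- window[2] - window[1]
  if (d < 0) stop_fmt("torpor duration must be >= 0")
  if (d > len + 1e-9) stop_fmt("torpor duration %g exceeds window length %g; clamp first",
                               d, len)
  morning <- base$frac_morning * d
  evening <- d - morning
  if (evening < base$min_afternoon) { morning <- d; evening <- 0 }
  seg <- data.frame(
    start_min = c(window[1], window[1] + morning, window[2] - evening),
    end_min = c(window[1] + morning, window[2] - evening, window[2]),
    state = c("torpor", "homeothermy", "torpor"))
  seg <- seg[seg$end_min - seg$start_min > 1e-9, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# minute-grid state labels for a schedule: minute m covers [m, m+1) and takes
# the state of the segment containing its midpoint
schedule_states <- function(schedule, window) {
  mins <- seq(window[1], window[2] - 1)
  mid <- mins + 0.5
  idx <- findInterval(mid, schedule$start_min)
  schedule$state[idx]
}

# roost temperatures on the window's 1-min grid; errors when more than 10%
# of window minutes fall outside the logger's coverage for that date
roost_window_temps <- function(trace, date, window) {
  if (is.numeric(trace)) {
    if (length(trace) == 1L) return(rep(trace, window[2] - window[1]))
    if (length(trace) != window[2] - window[1]) {
      stop_fmt("numeric temperature vector must have one value per window minute")
    }
    return(trace)
  }
  stopifnot(inherits(trace, "microhabitat_trace"))
  sel <- trace$date == as.character(date)
  if (!any(sel)) stop_fmt("roost %s has no data on %s", trace$roost_id, date)
  t <- trace$t[sel]; temp <- trace$temp[sel]
  mins <- seq(window[1], window[2] - 1)
  covered <- mins >= min(t) & mins <= max(t)
  if (mean(covered) < 0.9) {
    stop_fmt("roost %s on %s: logger covers < 90%% of the analysis window",
             trace$roost_id, date)
  }
  stats::approx(t, temp, xout = mins, rule = 2)$y
}

#' Minute-by-minute daily energy expenditure for one roost-day
#'
#' Integrates whole-animal metabolic rate over the analysis window on a
#' 1-minute grid (logger traces are linearly interpolated to that grid),
#' once under the supplied torpor/homeothermy schedule and once forcing
#' homeothermy throughout.
#'
#' @param trace a [microhabitat_trace()], a single temperature (degC), or a
#'   per-minute temperature vector for the window.
#' @param date ISO date (needed when `trace` is a logger trace).
#' @param schedule data frame from [allocate_bouts()].
#' @param cfg a [metabolic_config()].
#' @param window `c(start, end)` minutes since midnight.
#' @return named numeric: `ee_hetero`, `ee_homeo` (kJ/day).
#' @export
simulate_day <- function(trace, date = NULL, schedule, cfg = metabolic_config(),
                         window = c(285, 1260)) {
  temps <- roost_window_temps(trace, date, window)
  states <- schedule_states(schedule, window)
  rate_h <- metabolic_rate("homeothermy", temps, cfg)
  rate_t <- metabolic_rate("torpor", temps, cfg)
  hetero <- sum(ifelse(states == "torpor", rate_t, rate_h))
  c(ee_hetero = hetero / 1000, ee_homeo = sum(rate_h) / 1000)
}

#' Simulate daily energy expenditure across a roost-temperature study
#'
#' For every roost-day, draws a torpor-duration slope from the posterior
#' (one independent draw per roost-day, propagating model uncertainty),
#' converts the roost's window-mean temperature into a torpor duration via
#' [torpor_duration_for_day()], lays out the day with [allocate_bouts()],
#' and integrates heterothermic and forced-homeothermic energy expenditure
#' with [simulate_day()]. Roost-days are processed in sorted (roost, date)
#' order and all slope draws are taken up front, so results are
#' deterministic given `seed`.
#'
#' @param roosts list of [microhabitat_trace()] objects.
#' @param posterior a `torpor_fit`, or a numeric vector of slope draws
#'   (min/degC).
#' @param base a [simulation_baseline()].
#' @param cfg a [metabolic_config()].
#' @param dates optional character vector restricting the simulated dates.
#' @param window `c(start, end)` minutes since midnight.
#' @param seed integer seed for the per-roost-day slope draws.
#' @return data frame with one row per roost-day: `roost_id`, `date`,
#'   `ee_hetero`, `ee_homeo` (kJ/day), `torpor_min`, `beta_draw`,
#'   `mean_temp_day`.
#' @export
simulate_study <- function(roosts, posterior, base, cfg = metabolic_config(),
                           dates = NULL, window = c(285, 1260), seed = 1L) {
  betas <- if (is.numeric(posterior)) posterior else
    as.vector(draws_matrix(posterior, "beta_T"))
  if (!length(betas)) stop_fmt("posterior contains no slope draws")
  combos <- do.call(rbind, lapply(roosts, function(tr) {
    d <- unique(tr$date)
    if (!is.null(dates)) d <- intersect(d, as.character(dates))
    if (!length(d)) return(NULL)
    data.frame(roost_id = tr$roost_id, date = d)
  }))
  if (is.null(combos) || !nrow(combos)) stop_fmt("no roost-days to simulate")
  combos <- combos[order(combos$roost_id, combos$date), , drop = FALSE]
  by_id <- stats::setNames(roosts, vapply(roosts, `[[`, character(1), "roost_id"))

  set.seed(as.integer(seed))
  beta_draw <- sample(betas, nrow(combos), replace = TRUE)
  window_len <- window[2] - window[1]

  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- by_id[[combos$roost_id[i]]]
    temps <- roost_window_temps(tr, combos$date[i], window)
    t_mean <- mean(temps)
    d <- torpor_duration_for_day(t_mean, base, beta_draw[i], window_len)
    sched <- allocate_bouts(d, window, base)
    ee <- simulate_day(temps, schedule = sched, cfg = cfg, window = window)
    data.frame(roost_id = combos$roost_id[i], date = combos$date[i],
               ee_hetero = ee[["ee_hetero"]], ee_homeo = ee[["ee_homeo"]],
               torpor_min = d, beta_draw = beta_draw[i], mean_temp_day = t_mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
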