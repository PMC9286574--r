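#' Ground truth for the synthetic study generators
#'
#' Collects every parameter of the synthetic data-generating process in one
#' validated object, so all generators are pure functions of (truth, seed)
#' and recovery tests can compare estimates against known values. Defaults
#' mirror the study regime the pipeline targets: a torpor-duration slope of
#' -37.3 min/degC, roost window-mean temperatures spanning 16.9-23.6 degC,
#' an approximately 40:97 used:available split, 10-min logger and 1-min
#' skin-telemetry resolution.
#'
#' @param alpha,beta_T,beta_M fixed effects of the torpor-duration model
#'   (minutes; min/degC; min/g). The default `alpha` gives 400 min of
#'   torpor on a 20.3 degC day for an 8 g bat.
#' @param sigma_ind,sigma_res random-intercept and residual SDs, minutes.
#' @param sel_intercept,b_mean,b_peak,b_sd selection-model truth (logit
#'   scale, on standardized thermal summaries).
#' @param roost_mean_range range of roost window-mean temperatures, degC.
#' @param amplitude diurnal sinusoid amplitude, degC.
#' @param peak_min clock time of the diurnal peak, minutes since midnight.
#' @param noise_sd stationary SD of the AR(1) logger noise, degC.
#' @param ar1 AR(1) coefficient, in (-1, 1).
#' @param logger_res logger sampling interval, minutes.
#' @param homeo_level,homeo_jitter homeothermic skin temperature and its
#'   jitter SD, degC (jitter is truncated at 3 SD).
#' @param torpid_offset torpid skin temperature above ambient, degC.
#' @param torpid_jitter torpid-phase jitter SD, degC.
#' @param arousal_rate arousal warming rate, degC/min.
#' @param mass_mean,mass_sd body-mass distribution, g.
#' @param ambient_mean,ambient_sd distribution of daily mean ambient
#'   temperature, degC.
#' @return a list of class `synth_truth`.
#' @export
synth_truth <- function(alpha = 400 + 37.3 * 20.3 + 15 * 8,
                        beta_T = -37.3, beta_M = -15,
                        sigma_ind = 40, sigma_res = 60,
                        sel_intercept = -0.9, b_mean = 0.29,
                        b_peak = -0.13, b_sd = -0.18,
                        roost_mean_range = c(16.9, 23.6),
                        amplitude = 5, peak_min = 870,
                        noise_sd = 0.5, ar1 = 0.6, logger_res = 10,
                        homeo_level = 35, homeo_jitter = 0.3,
                        torpid_offset = 2, torpid_jitter = 0.1,
                        arousal_rate = 1,
                        mass_mean = 8, mass_sd = 0.5,
                        ambient_mean = 20.3, ambient_sd = 2) {
  if (sigma_ind < 0 || sigma_res < 0 || noise_sd < 0) stop_fmt("SDs must be >= 0")
  if (abs(ar1) >= 1) stop_fmt("AR(1) coefficient must be in (-1, 1)")
  structure(as.list(environment()), class = "synth_truth")
}

# diurnal sinusoid shape, unit amplitude, peaking at peak_min
diurnal_sin <- function(t, peak_min) sin(2 * pi * (t - (peak_min - 360)) / 1440)

# sinusoid with its mean over the sampled analysis window removed, so that
# mu_r parameterises the *window-mean* temperature and thermal_summary
# recovers it exactly in the noise-free limit
centered_sin <- function(t, peak_min, window) {
  s <- diurnal_sin(t, peak_min)
  s - mean(s[in_window(t, window)])
}

#' Generate synthetic roost temperature-logger traces
#'
#' Each roost gets `days` days of `T(t) = mu_r + A * (diurnal sinusoid,
#' centred on the analysis window) + AR(1) noise`, sampled at the logger
#' resolution; `mu_r` (the roost's window-mean temperature) is drawn
#' uniformly over `truth$roost_mean_range` unless supplied. Deterministic
#' given `seed`.
#'
#' @param n_roosts number of roosts (>= 1).
#' @param days days of data per roost.
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param status,substrate recycled over roosts (defaults "used"/"rock").
#' @param mean_temps optional vector of roost window-mean temperatures.
#' @param start_date first ISO date.
#' @param window analysis window used for centring.
#' @return list of [microhabitat_trace()] objects, with the drawn window
#'   means attached as attribute `"mu"`.
#' @export
gen_microhabitat_traces <- function(n_roosts, days, truth = synth_truth(),
                                    seed = 1L, status = "used",
                                    substrate = "rock", mean_temps = NULL,
                                    start_date = "2018-07-28",
                                    window = c(285, 1260)) {
  stopifnot(n_roosts >= 1L, days >= 1L)
  set.seed(as.integer(seed))
  status <- rep_len(status, n_roosts)
  substrate <- rep_len(substrate, n_roosts)
  mu <- mean_temps %||% stats::runif(n_roosts, truth$roost_mean_range[1],
                                     truth$roost_mean_range[2])
  t_day <- seq(0, 1439, by = truth$logger_res)
  shape <- centered_sin(t_day, truth$peak_min, window)
  dates <- as.character(as.Date(start_date) + seq_len(days) - 1L)
  innov_sd <- truth$noise_sd * sqrt(1 - truth$ar1^2)
  traces <- lapply(seq_len(n_roosts), function(r) {
    n <- days * length(t_day)
    noise <- if (truth$noise_sd > 0) {
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), truth$ar1,
                               method = "recursive"))
    } else rep(0, n)
    microhabitat_trace(sprintf("roost%03d", r), substrate[r], status[r],
                       rep(dates, each = length(t_day)),
                       rep(t_day, days),
                       mu[r] + truth$amplitude * rep(shape, days) + noise)
  })
  attr(traces, "mu") <- mu
  traces
}

#' Generate torpor-day records from the hierarchical model truth
#'
#' Draws per-bat random intercepts and body masses, per-day ambient
#' temperatures, and responses from the hierarchical linear model, clamping
#' durations to the analysis window. The realized random intercepts are
#' returned for oracle checks.
#'
#' @param n_bats,days_per_bat design size.
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param window_len window length (clamp bound), minutes.
#' @param start_date first ISO date.
#' @param shared_days when TRUE, every bat is observed on the same calendar
#'   days and so shares the per-day ambient temperatures (a balanced panel,
#'   as when several tagged bats are tracked through one season); when
#'   FALSE (default) each bat-day draws its own ambient temperature.
#' @return list with `records` (bat_id, date, torpor_min, t_mean_day,
#'   body_mass) and `a` (named vector of realized random intercepts).
#' @export
gen_torpor_days <- function(n_bats, days_per_bat, truth = synth_truth(),
                            seed = 1L, window_len = 975,
                            start_date = "2018-07-28", shared_days = FALSE) {
  stopifnot(n_bats >= 1L)
  set.seed(as.integer(seed))
  bat_ids <- sprintf("bat%02d", seq_len(n_bats))
  a <- stats::rnorm(n_bats, 0, truth$sigma_ind)
  names(a) <- bat_ids
  mass <- stats::rnorm(n_bats, truth$mass_mean, truth$mass_sd)
  n <- n_bats * days_per_bat
  t_mean <- if (shared_days) {
    rep(stats::rnorm(days_per_bat, truth$ambient_mean, truth$ambient_sd), n_bats)
  } else {
    stats::rnorm(n, truth$ambient_mean, truth$ambient_sd)
  }
  eps <- stats::rnorm(n, 0, truth$sigma_res)
  bi <- rep(seq_len(n_bats), each = days_per_bat)
  y <- truth$alpha + a[bi] + truth$beta_T * t_mean + truth$beta_M * mass[bi] + eps
  records <- data.frame(
    bat_id = bat_ids[bi],
    date = as.character(as.Date(start_date) + rep(seq_len(days_per_bat), n_bats) - 1L),
    torpor_min = pmin(pmax(y, 0), window_len),
    t_mean_day = t_mean,
    body_mass = mass[bi])
  list(records = records, a = a)
}

#' Generate a skin-temperature trace from a programmed bout plan
#'
#' Homeothermic minutes sit at the homeothermic level plus truncated jitter;
#' torpid minutes track ambient plus a small offset; entry into torpor is an
#' exponential approach that closes most of the gap within the first minute
#' and all of it within 15 min; arousal rises at the configured rate until
#' homeothermy is regained. Skin temperature never exceeds the homeothermic
#' level + 3 jitter SD and never falls below ambient.
#'
#' @param bouts data frame with `start_min`, `end_min` (programmed torpor
#'   bouts, non-overlapping, within the ambient series' span).
#' @param ambient data frame with minute-resolution columns `t`, `temp`.
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param bat_id,date,body_mass trace metadata.
#' @return a [skin_trace()] with the ambient series attached.
#' @export
gen_skin_trace <- function(bouts, ambient, truth = synth_truth(), seed = 1L,
                           bat_id = "bat01", date = "2018-07-28",
                           body_mass = 8) {
  t <- ambient$t; amb <- ambient$temp
  n <- length(t)
  if (nrow(bouts)) {
    b <- bouts[order(bouts$start_min), , drop = FALSE]
    if (any(b$end_min[-nrow(b)] > b$start_min[-1])) stop_fmt("overlapping bouts")
    if (min(b$start_min) < t[1] || max(b$end_min) > t[n]) {
      stop_fmt("bout plan extends beyond the ambient series")
    }
  }
  set.seed(as.integer(seed))
  clamp <- function(x, s) pmin(pmax(x, -3 * s), 3 * s)
  jit_h <- clamp(stats::rnorm(n, 0, truth$homeo_jitter), truth$homeo_jitter)
  jit_t <- clamp(stats::rnorm(n, 0, truth$torpid_jitter), truth$torpid_jitter)
  in_bout <- rep(FALSE, n)
  if (nrow(bouts)) {
    for (k in seq_len(nrow(bouts))) {
      in_bout <- in_bout | (t >= bouts$start_min[k] & t < bouts$end_min[k])
    }
  }
  x <- numeric(n)
  x[1] <- if (in_bout[1]) amb[1] + truth$torpid_offset + jit_t[1] else
    truth$homeo_level + jit_h[1]
  decay <- exp(-1.2)  # entry closes ~70% of the gap per minute, < 15 min total
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    if (in_bout[i]) {
      target <- amb[i] + truth$torpid_offset + jit_t[i]
      x[i] <- target + (x[i - 1] - target) * decay^dt
    } else if (x[i - 1] < truth$homeo_level - 3 * truth$homeo_jitter) {
      x[i] <- min(x[i - 1] + truth$arousal_rate * dt, truth$homeo_level)
    } else {
      x[i] <- truth$homeo_level + jit_h[i]
    }
  }
  skin_trace(bat_id, date, t, pmax(x, amb), body_mass, ambient = amb)
}

#' Generate a used/available selection dataset with known truth
#'
#' Draws thermal summaries from their configured distributions and assigns
#' used/available labels by a Bernoulli draw with logit equal to the
#' selection truth applied to the standardized summaries.
#'
#' @param n_used,n_available expected class sizes; their ratio sets the
#'   baseline odds together with `truth$sel_intercept` (the default
#'   intercept, -0.9, corresponds to the 40:97 used:available regime).
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @return list with `summaries` (a thermal-summary data frame with
#'   `status` labels) and `truth` (the coefficients used, standardized
#'   scale).
#' @export
gen_selection_dataset <- function(n_used = 40, n_available = 97,
                                  truth = synth_truth(), seed = 1L) {
  stopifnot(n_used >= 1L, n_available >= 1L)
  n <- n_used + n_available
  set.seed(as.integer(seed))
  mean_temp <- stats::rnorm(n, 20, 2)
  peak_time <- stats::rnorm(n, 14.4, 1)
  sd_temp <- pmax(stats::rnorm(n, 7, 1.5), 0.5)
  Z <- scale(cbind(mean_temp, peak_time, sd_temp))
  eta <- truth$sel_intercept + truth$b_mean * Z[, 1] +
    truth$b_peak * Z[, 2] + truth$b_sd * Z[, 3]
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(summaries = data.frame(
         roost_id = sprintf("roost%03d", seq_len(n)),
         substrate = "rock",
         status = ifelse(y == 1L, "used", "available"),
         mean_temp = mean_temp, peak_time_mean = peak_time,
         sd_temp_mean = sd_temp, n_days = 30L),
       truth = c(intercept = truth$sel_intercept, b_mean = truth$b_mean,
                 b_peak = truth$b_peak, b_sd = truth$b_sd))
}

#' Generate a complete synthetic study
#'
#' Produces mutually consistent inputs for the whole pipeline: torpor-day
#' records from the hierarchical truth, a skin-temperature trace per bat-day
#' whose programmed bouts realize exactly the record's torpor duration (laid
#' out with the morning/evening split rule), an ambient minute series whose
#' window mean equals the record's `t_mean_day`, and roost logger traces.
#'
#' @param n_bats,days_per_bat telemetry design.
#' @param n_roosts_used,n_roosts_available logger design.
#' @param days_roost days of logger data per roost.
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param config a [run_config()].
#' @return list: `skin_traces`, `records` (programmed ground truth),
#'   `a` (random intercepts), `roost_traces`, `truth`.
#' @export
gen_study <- function(n_bats = 7, days_per_bat = 4,
                      n_roosts_used = 40, n_roosts_available = 97,
                      days_roost = 10, truth = synth_truth(), seed = 1L,
                      config = run_config()) {
  window <- c(config$window_start, config$window_end)
  td <- gen_torpor_days(n_bats, days_per_bat, truth, seed = seed,
                        window_len = window_length(config))
  base <- simulation_baseline(400, truth$ambient_mean,
                              window_len = window_length(config))
  t_min <- window[1]:window[2]
  shape <- centered_sin(t_min, truth$peak_min, window)
  skin_traces <- lapply(seq_len(nrow(td$records)), function(i) {
    rec <- td$records[i, ]
    sched <- allocate_bouts(rec$torpor_min, window, base)
    bouts <- sched[sched$state == "torpor", c("start_min", "end_min")]
    amb <- data.frame(t = t_min, temp = rec$t_mean_day + 3 * shape)
    gen_skin_trace(bouts, amb, truth, seed = seed + i,
                   bat_id = rec$bat_id, date = rec$date,
                   body_mass = rec$body_mass)
  })
  roost_traces <- gen_microhabitat_traces(
    n_roosts_used + n_roosts_available, days_roost, truth,
    seed = seed + 10000L,
    status = rep(c("used", "available"), c(n_roosts_used, n_roosts_available)),
    substrate = rep_len(c("rock", "rock", "tree"),
                        n_roosts_used + n_roosts_available),
    window = window)
  list(skin_traces = skin_traces, records = td$records, a = td$a,
       roost_traces = roost_traces, truth = truth)
}
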