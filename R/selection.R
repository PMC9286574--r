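#' Windowed thermal summary of a roost logger trace
#'
#' For every complete day inside the date range, computes the mean
#' temperature over the analysis window, the time of the daily maximum
#' (earliest sample attaining it, decimal hours), and the population
#' (divide-by-n) standard deviation over the window; these daily values are
#' then averaged across days. A day is complete when at least 90% of the
#' expected window samples (window length / logger resolution) are present.
#' The default date range runs 28 July-30 September.
#'
#' @param trace a [microhabitat_trace()].
#' @param window `c(start, end)` minutes since midnight.
#' @param date_range `c(first, last)` ISO dates, inclusive.
#' @param max_missing maximum tolerated fraction of missing window samples
#'   per day (default 0.1); days beyond it are excluded.
#' @return one-row data frame: `roost_id`, `substrate`, `status`,
#'   `mean_temp` (degC), `peak_time_mean` (decimal hours),
#'   `sd_temp_mean` (degC), `n_days`.
#' @export
thermal_summary <- function(trace, window = c(285, 1260),
                            date_range = c("2018-07-28", "2018-09-30"),
                            max_missing = 0.1) {
  stopifnot(inherits(trace, "microhabitat_trace"))
  d <- as.Date(trace$date)
  keep <- d >= as.Date(date_range[1]) & d <= as.Date(date_range[2]) &
    in_window(trace$t, window)
  if (!any(keep)) {
    stop_fmt("roost %s: no samples in the analysis window within %s..%s",
             trace$roost_id, date_range[1], date_range[2])
  }
  t <- trace$t[keep]; temp <- trace$temp[keep]; day <- trace$date[keep]
  res <- min(diff(sort(unique(t))))
  expected <- (window[2] - window[1]) / res
  per_day <- lapply(split(seq_along(t), day), function(i) {
    if (length(i) < (1 - max_missing) * expected) return(NULL)
    peak_i <- i[which.max(temp[i])]  # which.max takes the earliest tie
    data.frame(mean_temp = mean(temp[i]),
               peak_time = t[peak_i] / 60,
               sd_temp = sqrt(mean((temp[i] - mean(temp[i]))^2)))
  })
  per_day <- do.call(rbind, per_day)
  if (is.null(per_day)) {
    stop_fmt("roost %s: no complete days (>= %d%% window coverage) in range",
             trace$roost_id, as.integer((1 - max_missing) * 100))
  }
  data.frame(roost_id = trace$roost_id, substrate = trace$substrate,
             status = trace$status,
             mean_temp = mean(per_day$mean_temp),
             peak_time_mean = mean(per_day$peak_time),
             sd_temp_mean = mean(per_day$sd_temp),
             n_days = nrow(per_day))
}

#' @rdname thermal_summary
#' @param traces list of [microhabitat_trace()] objects.
#' @export
thermal_summaries <- function(traces, window = c(285, 1260),
                              date_range = c("2018-07-28", "2018-09-30"),
                              max_missing = 0.1) {
  out <- do.call(rbind, lapply(traces, thermal_summary, window = window,
                               date_range = date_range, max_missing = max_missing))
  rownames(out) <- NULL
  out
}

#' Per-day window-mean temperatures of a roost trace
#'
#' One row per day with any window samples: the mean logger temperature
#' over the analysis window. Used to drive the energetics simulation and
#' the daily ambient-vs-used-roost regression.
#'
#' @param trace a [microhabitat_trace()].
#' @param window `c(start, end)` minutes since midnight.
#' @return data frame: `roost_id`, `substrate`, `status`, `date`,
#'   `mean_temp`.
#' @export
roost_daily_means <- function(trace, window = c(285, 1260)) {
  stopifnot(inherits(trace, "microhabitat_trace"))
  keep <- in_window(trace$t, window)
  agg <- tapply(trace$temp[keep], trace$date[keep], mean)
  data.frame(roost_id = trace$roost_id, substrate = trace$substrate,
             status = trace$status, date = names(agg),
             mean_temp = as.numeric(agg), row.names = NULL)
}

#' Priors for the binomial selection model
#'
#' Independent Normal(0, `sd^2`) priors on the intercept and coefficients,
#' on the internally standardized predictor scale.
#'
#' @param sd prior standard deviation (default 5).
#' @return a list of class `selection_priors`.
#' @export
selection_priors <- function(sd = 5) {
  stopifnot(sd > 0)
  structure(list(sd = sd), class = "selection_priors")
}

#' Fit the Bayesian binomial microhabitat-selection model
#'
#' Bayesian logistic regression of roost status (used = 1, available = 0)
#' on three thermal summaries: window-mean temperature, mean timing of the
#' daily temperature peak, and mean daily temperature SD. Rock and tree
#' roosts are pooled. Predictors are standardized internally for sampler
#' stability; coefficients are reported on both scales (standardized draws
#' in `draws`, raw per-unit draws in `draws_raw`). Sampling is random-walk
#' Metropolis within Gibbs with per-coordinate proposal scales adapted
#' toward a 44% acceptance rate during warm-up only, so post-warmup chains
#' are valid MCMC; runs are deterministic given `seed`.
#'
#' @param summaries data frame from [thermal_summaries()] (needs columns
#'   `status`, `mean_temp`, `peak_time_mean`, `sd_temp_mean`); both statuses
#'   must be present and at least 10 roosts supplied. Complete separation
#'   triggers a warning (the priors keep estimates finite).
#' @param priors a [selection_priors()].
#' @param n_chains,n_iter,n_warmup MCMC settings; defaults 3 chains of
#'   12,000 iterations with 2,000 warm-up.
#' @param seed integer; chain `c` uses `seed + c`.
#' @return object of class `selection_fit`: `draws` (standardized scale;
#'   `intercept`, `b_mean`, `b_peak`, `b_sd` chains-by-draws matrices),
#'   `draws_raw` (per degC / per hour / per degC), `center`/`scale` used for
#'   standardization, the scored `data`, settings and `seed`.
#' @export
fit_selection_model <- function(summaries, priors = selection_priors(),
                                n_chains = 3L, n_iter = 12000L,
                                n_warmup = 2000L, seed = 1L) {
  req <- c("status", "mean_temp", "peak_time_mean", "sd_temp_mean")
  missing <- setdiff(req, names(summaries))
  if (length(missing)) stop_fmt("summaries lack column(s): %s",
                                paste(missing, collapse = ", "))
  if (nrow(summaries) < 10L) stop_fmt("need >= 10 roosts to fit the selection model")
  y <- as.integer(summaries$status == "used")
  if (all(y == 1L) || all(y == 0L)) {
    stop_fmt("both used and available roosts are required")
  }
  Xr <- as.matrix(summaries[, c("mean_temp", "peak_time_mean", "sd_temp_mean")])
  ctr <- colMeans(Xr)
  scl <- apply(Xr, 2L, stats::sd)
  if (any(scl == 0)) stop_fmt("a predictor has zero variance")
  X <- cbind(1, sweep(sweep(Xr, 2L, ctr), 2L, scl, "/"))
  p <- ncol(X)
  prior_prec <- 1 / priors$sd^2

  log_post <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * prior_prec * sum(b^2)
  }

  init <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients,
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warn_fmt("complete separation detected; priors regularize the fit")
      }
      invokeRestart("muffleWarning")
    })
  init[!is.finite(init)] <- 0
  init <- pmin(pmax(init, -10), 10)

  n_keep <- n_iter - n_warmup
  par_names <- c("intercept", "b_mean", "b_peak", "b_sd")
  draws <- lapply(par_names, function(.) matrix(NA_real_, n_chains, n_keep))
  names(draws) <- par_names

  for (chain in seq_len(n_chains)) {
    set.seed(as.integer(seed) + chain)
    b <- init
    lp <- log_post(b)
    step <- rep(0.3, p)
    acc <- rep(0L, p); tries <- rep(0L, p)
    for (it in seq_len(n_iter)) {
      for (j in seq_len(p)) {
        prop <- b
        prop[j] <- b[j] + stats::rnorm(1L, 0, step[j])
        lp_prop <- log_post(prop)
        tries[j] <- tries[j] + 1L
        if (log(stats::runif(1L)) < lp_prop - lp) {
          b <- prop; lp <- lp_prop; acc[j] <- acc[j] + 1L
        }
      }
      if (it <= n_warmup && it %% 50L == 0L) {
        rate <- acc / pmax(tries, 1L)
        step <- pmin(pmax(step * exp(rate - 0.44), 1e-3), 10)
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > n_warmup) {
        k <- it - n_warmup
        for (j in seq_len(p)) draws[[j]][chain, k] <- b[j]
      }
    }
  }

  # raw-scale draws: divide by predictor SDs; shift the intercept accordingly
  draws_raw <- list(
    intercept = draws$intercept -
      draws$b_mean * ctr[1] / scl[1] -
      draws$b_peak * ctr[2] / scl[2] -
      draws$b_sd * ctr[3] / scl[3],
    b_mean = draws$b_mean / scl[1],
    b_peak = draws$b_peak / scl[2],
    b_sd = draws$b_sd / scl[3])

  structure(
    list(draws = draws, draws_raw = draws_raw, center = ctr, scale = scl,
         data = summaries, n_chains = n_chains, n_iter = n_iter,
         n_warmup = n_warmup, seed = as.integer(seed), priors = priors),
    class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("<selection_fit> %d roosts (%d used); %d chains x %d iter\n",
              nrow(x$data), sum(x$data$status == "used"), x$n_chains, x$n_iter))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

# rank-sum AUC with ties counted half
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop_fmt("AUC needs both classes present")
  r <- rank(scores)  # average ranks give the ties-half convention
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the ROC curve of a fitted selection model
#'
#' Scores each roost with the posterior-mean linear predictor and computes
#' the rank-sum (Mann-Whitney) AUC, ties counted half: the probability that
#' a randomly chosen used roost outscores a randomly chosen available one.
#'
#' @param fit a `selection_fit`.
#' @param summaries data to score; defaults to the fitting data.
#' @return AUC in [0, 1].
#' @export
auc <- function(fit, summaries = NULL) {
  stopifnot(inherits(fit, "selection_fit"))
  summaries <- summaries %||% fit$data
  Xr <- as.matrix(summaries[, c("mean_temp", "peak_time_mean", "sd_temp_mean")])
  X <- cbind(1, sweep(sweep(Xr, 2L, fit$center), 2L, fit$scale, "/"))
  bhat <- vapply(fit$draws, mean, numeric(1))
  auc_rank(drop(X %*% bhat), summaries$status == "used")
}

#' Regression of used-roost temperature on daily ambient temperature
#'
#' Ordinary least squares of the window-mean temperature of the roost used
#' on a day against that day's ambient temperature, the test of whether
#' bats shift toward warmer roosts on warmer days.
#'
#' @param pairs data frame with columns `ambient` and `used_mean` (degC),
#'   one row per used roost-day; needs >= 3 rows and non-constant ambient.
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided test of zero slope, n-2 df).
#' @export
ambient_vs_used_regression <- function(pairs) {
  check_columns(pairs, c("ambient", "used_mean"), "pairs")
  if (nrow(pairs) < 3L) stop_fmt("need >= 3 ambient/used pairs")
  if (stats::sd(pairs$ambient) == 0) stop_fmt("ambient temperature has zero variance")
  if (stats::sd(pairs$used_mean) == 0) {
    # a constant response carries no relationship; avoid 0/0 in R^2
    return(structure(list(slope = 0, intercept = pairs$used_mean[1],
                          r_squared = 0, p_value = 1),
                     class = "regression_result"))
  }
  fit <- stats::lm(used_mean ~ ambient, data = pairs)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients["ambient", "Pr(>|t|)"]),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.3f, intercept %.2f, R^2 = %.3f, p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}
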