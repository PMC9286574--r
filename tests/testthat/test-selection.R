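test_that("thermal summaries of a constant trace are exact", {
  tr <- fun_logger_trace(function(t) rep(20, length(t)))
  s <- thermal_summary(tr, date_range = c("2018-08-01", "2018-08-01"))
  expect_equal(s$mean_temp, 20)
  expect_equal(s$sd_temp_mean, 0)
  # earliest-maximum tie rule puts the peak at the first window sample
  expect_equal(s$peak_time_mean, 290 / 60)
  expect_equal(s$n_days, 1L)
})

test_that("a diurnal sinusoid yields the closed-form window mean and 14:30 peak", {
  f <- function(t) 20 + 5 * sin(2 * pi * (t - 510) / 1440)
  tr <- fun_logger_trace(f, dates = c("2018-08-01", "2018-08-02"))
  s <- thermal_summary(tr, date_range = c("2018-08-01", "2018-08-02"))
  # oracle: average of the sinusoid over the sampled window
  t_win <- seq(290, 1250, by = 10)
  expect_equal(s$mean_temp, mean(f(t_win)), tolerance = 1e-9)
  expect_equal(s$peak_time_mean, 14.5)
  expect_equal(s$n_days, 2L)
  # population-SD oracle on the same samples
  expect_equal(s$sd_temp_mean, sqrt(mean((f(t_win) - mean(f(t_win)))^2)),
               tolerance = 1e-9)
})

test_that("summaries average daily values across days", {
  f <- function(t) rep(18, length(t))
  g <- function(t) rep(22, length(t))
  t_day <- seq(0, 1439, by = 10)
  tr <- microhabitat_trace("r1", "rock", "used",
                           rep(c("2018-08-01", "2018-08-02"), each = length(t_day)),
                           rep(t_day, 2), c(f(t_day), g(t_day)))
  s <- thermal_summary(tr, date_range = c("2018-08-01", "2018-08-02"))
  expect_equal(s$mean_temp, 20)
})

test_that("summaries are insensitive to sampling phase for band-limited input", {
  f <- function(t) 20 + 5 * sin(2 * pi * (t - 510) / 1440)
  t1 <- seq(0, 1439, by = 10)
  t2 <- seq(4, 1439, by = 10)
  tr1 <- microhabitat_trace("r1", "rock", "used", rep("2018-08-01", length(t1)), t1, f(t1))
  tr2 <- microhabitat_trace("r2", "rock", "used", rep("2018-08-01", length(t2)), t2, f(t2))
  s1 <- thermal_summary(tr1, date_range = c("2018-08-01", "2018-08-01"))
  s2 <- thermal_summary(tr2, date_range = c("2018-08-01", "2018-08-01"))
  expect_lt(abs(s1$mean_temp - s2$mean_temp), 0.05)
})

test_that("out-of-range or incomplete traces are rejected", {
  tr <- fun_logger_trace(function(t) rep(20, length(t)), dates = "2018-10-20")
  expect_error(thermal_summary(tr), "no samples")
  sparse <- microhabitat_trace("r1", "rock", "used",
                               rep("2018-08-01", 5), seq(300, 700, by = 100), rep(20, 5))
  expect_error(thermal_summary(sparse), "complete days")
})

test_that("AUC follows the rank-sum formulation with ties counted half", {
  sep <- data.frame(status = rep(c("used", "available"), each = 3),
                    mean_temp = c(25, 24, 23, 18, 17, 16),
                    peak_time_mean = 14, sd_temp_mean = 7)
  fit <- structure(list(draws = list(intercept = matrix(0, 1, 10),
                                     b_mean = matrix(1, 1, 10),
                                     b_peak = matrix(0, 1, 10),
                                     b_sd = matrix(0, 1, 10)),
                        center = c(20, 14, 7), scale = c(2, 1, 1),
                        data = sep),
                   class = "selection_fit")
  expect_equal(auc(fit), 1.0)

  tied <- sep; tied$mean_temp <- 20
  expect_equal(auc(fit, tied), 0.5)

  # used {0.9, 0.4} vs available {0.6, 0.2}: 3 of 4 concordant pairs
  four <- data.frame(status = c("used", "used", "available", "available"),
                     mean_temp = 20 + 2 * c(0.9, 0.4, 0.6, 0.2),
                     peak_time_mean = 14, sd_temp_mean = 7)
  expect_equal(auc(fit, four), 0.75)

  # anti-predictor symmetry
  anti <- fit
  anti$draws$b_mean <- -fit$draws$b_mean
  expect_equal(auc(anti, four), 1 - auc(fit, four))

  one_class <- four[four$status == "used", ]
  expect_error(auc(fit, one_class), "both classes")
})

test_that("our AUC agrees with the pROC reference on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  n <- 60
  d <- data.frame(status = sample(c("used", "available"), n, replace = TRUE),
                  mean_temp = rnorm(n, 20, 2), peak_time_mean = rnorm(n, 14, 1),
                  sd_temp_mean = rnorm(n, 7, 1))
  fit <- fit_selection_model(d, n_chains = 2, n_iter = 600, n_warmup = 200, seed = 3)
  scores <- {
    X <- cbind(1, scale(as.matrix(d[, c("mean_temp", "peak_time_mean", "sd_temp_mean")]),
                        center = fit$center, scale = fit$scale))
    drop(X %*% vapply(fit$draws, mean, numeric(1)))
  }
  ref <- as.numeric(pROC::auc(pROC::roc(d$status == "used", scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(fit), ref, tolerance = 1e-12)
})

test_that("the ambient vs used-roost regression matches hand OLS", {
  exact <- data.frame(ambient = 1:5, used_mean = 1:5)
  r <- ambient_vs_used_regression(exact)
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)

  flat <- data.frame(ambient = 1:5, used_mean = rep(3, 5))
  r2 <- ambient_vs_used_regression(flat)
  expect_equal(r2$slope, 0)
  expect_equal(r2$r_squared, 0)

  hand <- data.frame(ambient = c(1, 2, 3), used_mean = c(1, 3, 2))
  r3 <- ambient_vs_used_regression(hand)
  expect_equal(r3$slope, 0.5)
  expect_equal(r3$r_squared, 0.25)

  expect_error(ambient_vs_used_regression(hand[1:2, ]), ">= 3")
  expect_error(ambient_vs_used_regression(
    data.frame(ambient = c(2, 2, 2), used_mean = c(1, 2, 3))), "zero variance")
})

test_that("selection model input contracts are enforced", {
  gd <- gen_selection_dataset(10, 10, seed = 3)
  one <- gd$summaries; one$status <- "used"
  expect_error(fit_selection_model(one), "both used and available")
  expect_error(fit_selection_model(gd$summaries[1:5, ]), ">= 10")
})

test_that("identical used and available summaries center slopes at zero", {
  covs <- data.frame(mean_temp = rnorm(12, 20, 2),
                     peak_time_mean = rnorm(12, 14, 1),
                     sd_temp_mean = rnorm(12, 7, 1))
  mirror <- rbind(cbind(status = "used", covs), cbind(status = "available", covs))
  fit <- fit_selection_model(mirror, n_chains = 2, n_iter = 1500,
                             n_warmup = 500, seed = 8)
  for (p in c("b_mean", "b_peak", "b_sd")) {
    expect_lt(abs(mean(fit$draws[[p]])), 0.35)
  }
  expect_equal(auc(fit), 0.5, tolerance = 0.15)
})

test_that("a strong warm-selection signal is detected with CI excluding zero", {
  gd <- gen_selection_dataset(80, 120, synth_truth(b_mean = 2, b_peak = 0, b_sd = 0),
                              seed = 5)
  fit <- fit_selection_model(gd$summaries, n_chains = 2, n_iter = 2500,
                             n_warmup = 500, seed = 2)
  ci <- credible_interval(fit, "b_mean")
  expect_gt(mean(fit$draws$b_mean), 0)
  expect_gt(ci[["lo"]], 0)
  # raw-scale slope is the standardized slope divided by the predictor SD
  expect_equal(mean(fit$draws_raw$b_mean),
               mean(fit$draws$b_mean) / fit$scale[["mean_temp"]])
})
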