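test_that("skin traces survive a write/read round trip field-by-field", {
  tr1 <- const_skin_trace(35, bat_id = "batA", date = "2018-08-01")
  tr2 <- const_skin_trace(34, t = seq(285, 1255, by = 5), bat_id = "batB",
                          date = "2018-08-02", mass = 7.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_skin_traces(list(tr1, tr2), path)
  got <- read_skin_traces(path)

  expect_length(got, 2L)
  expect_equal(got[[1]]$bat_id, "batA")
  expect_equal(got[[2]]$bat_id, "batB")
  expect_equal(got[[2]]$date, "2018-08-02")
  for (i in 1:2) {
    orig <- list(tr1, tr2)[[i]]
    expect_equal(got[[i]]$t, orig$t)
    expect_equal(got[[i]]$skin_temp, orig$skin_temp)
    expect_equal(got[[i]]$body_mass, orig$body_mass)
    expect_equal(got[[i]]$dt, orig$dt)
  }
})

test_that("two bat-days in one file partition into two traces", {
  df <- data.frame(bat_id = rep("b1", 6), date = rep(c("2018-08-01", "2018-08-02"), each = 3),
                   time = rep(c(300, 301, 302), 2), skin_temp_c = 35, body_mass_g = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  got <- read_skin_traces(path)
  expect_length(got, 2L)
  expect_equal(vapply(got, function(x) x$date, character(1)),
               c("2018-08-01", "2018-08-02"))
  expect_equal(sum(vapply(got, function(x) length(x$t), integer(1))), nrow(df))
})

test_that("format and validation errors name the offending column or bat-day", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(bat_id = "b1", date = "2018-08-01", time = 1,
                              body_mass_g = 8), path, row.names = FALSE)
  expect_error(read_skin_traces(path), "skin_temp_c")

  df <- data.frame(bat_id = "b9", date = "2018-08-03", time = c(300, 299, 301),
                   skin_temp_c = 35, body_mass_g = 8)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_skin_traces(path), "b9.*2018-08-03")
})

test_that("logger traces round trip with substrate and status preserved", {
  f <- function(t) 20 + 0.01 * t
  tr1 <- fun_logger_trace(f, roost_id = "rock1", substrate = "rock", status = "used")
  tr2 <- fun_logger_trace(f, roost_id = "tree1", substrate = "tree", status = "available")
  path <- withr::local_tempfile(fileext = ".csv")
  write_logger_traces(list(tr1, tr2), path)
  got <- read_logger_traces(path)
  expect_length(got, 2L)
  expect_equal(got[[1]]$substrate, "rock")
  expect_equal(got[[2]]$substrate, "tree")
  expect_equal(got[[2]]$status, "available")
  expect_equal(got[[1]]$t, tr1$t)
  expect_equal(got[[2]]$temp, tr2$temp)
})

test_that("unknown status tokens are rejected and empty logger files warn", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(roost_id = "r1", substrate = "rock", status = "maybe",
                              timestamp = "2018-08-01 05:00", temp_c = 20),
                   path, row.names = FALSE)
  expect_error(read_logger_traces(path), "maybe")

  utils::write.csv(data.frame(roost_id = character(), substrate = character(),
                              status = character(), timestamp = character(),
                              temp_c = numeric()), path, row.names = FALSE)
  expect_warning(got <- read_logger_traces(path), "no data rows")
  expect_length(got, 0L)
})

test_that("results tables round trip losslessly, including an empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(a = numeric(), b = character())
  write_results_table(empty, path)
  expect_equal(readLines(path), "a,b")

  rows <- data.frame(id = c("x", "y", "z"),
                     value = c(1 / 3, pi * 1e4, -37.28913472918561))
  write_results_table(rows, path)
  got <- read_results_table(path)
  expect_equal(got$id, rows$id)
  expect_equal(got$value, rows$value, tolerance = 1e-12)
})

test_that("posterior draws round trip through the long draws table", {
  fit <- list(draws = list(beta_T = matrix(rnorm(20), 2), alpha = matrix(rnorm(20), 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_table(fit, path)
  got <- read_draws_table(path)
  expect_equal(names(got), c("beta_T", "alpha"))
  expect_equal(got$beta_T, fit$draws$beta_T, tolerance = 1e-12)
})

test_that("run configuration validates its invariants and round trips via yaml", {
  expect_error(run_config(window_start = 1300, window_end = 1260), "window_start")
  expect_error(run_config(window_end = 1500), "1440")
  expect_error(run_config(n_iter = 100, n_warmup = 100), "n_warmup")

  cfg <- run_config(rng_seed = 42, rise_rate = 0.7)
  path <- withr::local_tempfile(fileext = ".yml")
  write_run_config(cfg, path)
  got <- read_run_config(path)
  expect_equal(got$rise_rate, 0.7)
  expect_equal(got$rng_seed, 42L)
  expect_equal(window_length(got), 975)

  writeLines("winndow_start: 10", path)
  expect_error(read_run_config(path), "unknown config key")
})
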