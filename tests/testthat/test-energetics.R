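test_that("metabolic rates follow the Scholander/Q10 forms at the defaults", {
  cfg <- metabolic_config()
  # 23 degC, homeothermy: 1.5 + 0.18*10 = 3.3 mL/g/h -> 8.844 J/min at 8 g
  expect_equal(metabolic_rate("homeothermy", 23, cfg), 8.844)
  # continuity at the knee
  expect_equal(metabolic_rate("homeothermy", cfg$t_lc, cfg),
               cfg$bmr * cfg$mass * cfg$oxyjoule / 60)
  # torpor at the reference temperature: 0.05*8*20.1/60
  expect_equal(metabolic_rate("torpor", 20, cfg), 0.134)
  # torpid rate never exceeds the homeothermic rate at any temperature
  grid <- seq(-5, 45, by = 0.5)
  expect_true(all(metabolic_rate("torpor", grid, cfg) <=
                    metabolic_rate("homeothermy", grid, cfg) + 1e-12))
})

test_that("torpor duration shifts along the slope and clamps to the window", {
  base <- simulation_baseline(400, 20.3)
  expect_equal(torpor_duration_for_day(21.3, base, -37.3), 362.7)
  expect_equal(torpor_duration_for_day(20.3, base, -500), 400)
  expect_equal(torpor_duration_for_day(35, base, -37.3), 0)
  expect_equal(torpor_duration_for_day(2, base, -37.3), 975)
})

test_that("bout allocation applies the morning/evening split and 30-min rule", {
  base <- simulation_baseline(400, 20.3)
  s400 <- allocate_bouts(400, base = base)
  torp <- s400[s400$state == "torpor", ]
  expect_equal(nrow(torp), 2L)
  expect_equal(torp$start_min[1], 285)
  expect_equal(torp$end_min[1] - torp$start_min[1], 347.6)
  expect_equal(torp$end_min[2], 1260)
  expect_equal(torp$end_min[2] - torp$start_min[2], 52.4)

  # evening share 26.2 < 30 min: all torpor moves to the morning
  s200 <- allocate_bouts(200, base = base)
  torp200 <- s200[s200$state == "torpor", ]
  expect_equal(nrow(torp200), 1L)
  expect_equal(torp200$end_min - torp200$start_min, 200)

  s0 <- allocate_bouts(0, base = base)
  expect_equal(s0$state, "homeothermy")

  expect_error(allocate_bouts(1000, base = base), "clamp")
})

test_that("schedules tile the window exactly and conserve scheduled torpor", {
  base <- simulation_baseline(400, 20.3)
  for (d in c(0, 31, 200, 347, 400, 700, 975)) {
    s <- allocate_bouts(d, base = base)
    expect_equal(s$start_min[1], 285)
    expect_equal(s$end_min[nrow(s)], 1260)
    if (nrow(s) > 1L) expect_equal(s$start_min[-1], s$end_min[-nrow(s)])
    expect_equal(sum((s$end_min - s$start_min)[s$state == "torpor"]), d)
  }
})

test_that("hand-evaluated constant-temperature days match the formulas", {
  cfg <- metabolic_config()
  homeo_day <- simulate_day(20, schedule = allocate_bouts(0), cfg = cfg)
  # 3.84 mL/g/h * 8 g * 16.25 h * 20.1 J/mL = 10033.92 J
  expect_equal(homeo_day[["ee_homeo"]], 10.03392, tolerance = 1e-9)
  expect_equal(homeo_day[["ee_hetero"]], homeo_day[["ee_homeo"]])

  torpid_day <- simulate_day(20, schedule = allocate_bouts(975), cfg = cfg)
  expect_equal(torpid_day[["ee_hetero"]], 0.13065, tolerance = 1e-9)
})

test_that("simulate_day equals an independent brute-force minute loop", {
  cfg <- metabolic_config()
  set.seed(7)
  temps <- 20 + cumsum(rnorm(975, 0, 0.05))
  sched <- allocate_bouts(400)
  got <- simulate_day(temps, schedule = sched, cfg = cfg)

  # independent oracle: explicit loop over minutes and schedule segments
  e_het <- 0; e_hom <- 0
  for (i in seq_along(temps)) {
    t_mid <- 285 + i - 1 + 0.5
    seg <- which(sched$start_min <= t_mid & t_mid < sched$end_min)
    state <- sched$state[seg]
    pg_h <- cfg$bmr + cfg$k_h * max(cfg$t_lc - temps[i], 0)
    pg_t <- min(cfg$tmr_ref * cfg$q10^((temps[i] - cfg$t_ref) / 10), pg_h)
    e_hom <- e_hom + pg_h * cfg$mass * cfg$oxyjoule / 60
    e_het <- e_het + (if (state == "torpor") pg_t else pg_h) * cfg$mass * cfg$oxyjoule / 60
  }
  expect_equal(got[["ee_hetero"]], e_het / 1000)
  expect_equal(got[["ee_homeo"]], e_hom / 1000)
})

test_that("energy is additive over any partition of the window", {
  cfg <- metabolic_config()
  sched <- allocate_bouts(400)
  temps <- 18 + 2 * sin(seq(0, pi, length.out = 975))
  full <- simulate_day(temps, schedule = sched, cfg = cfg)
  # split the same day into two half-windows and re-integrate
  halves <- vapply(list(1:487, 488:975), function(idx) {
    states <- rep("homeothermy", 975)
    mids <- 285:1259 + 0.5
    seg <- findInterval(mids, sched$start_min)
    states <- sched$state[seg]
    sum(ifelse(states[idx] == "torpor",
               metabolic_rate("torpor", temps[idx], cfg),
               metabolic_rate("homeothermy", temps[idx], cfg))) / 1000
  }, numeric(1))
  expect_equal(sum(halves), full[["ee_hetero"]])
})

test_that("homeotherm cost strictly decreases with roost temperature below T_lc", {
  cfg <- metabolic_config()
  ee <- vapply(seq(15, 25, by = 1), function(temp) {
    simulate_day(temp, schedule = allocate_bouts(0), cfg = cfg)[["ee_homeo"]]
  }, numeric(1))
  expect_true(all(diff(ee) < 0))
})

test_that("simulate_study: row bookkeeping, point-mass posterior, determinism", {
  truth <- synth_truth(noise_sd = 0.2)
  roosts <- gen_microhabitat_traces(4, 3, truth, seed = 5)
  base <- simulation_baseline(400, 20.3)

  out <- simulate_study(roosts, posterior = rep(-37.3, 50), base = base, seed = 2)
  expect_equal(nrow(out), 4L * 3L)
  expect_true(all(out$beta_draw == -37.3))
  expect_true(all(out$ee_hetero <= out$ee_homeo + 1e-12))
  expect_true(all(out$ee_hetero >= 0))

  pool <- rnorm(200, -37, 6)
  out2 <- simulate_study(roosts, posterior = pool, base = base, seed = 9)
  out3 <- simulate_study(roosts, posterior = pool, base = base, seed = 9)
  expect_equal(out2, out3)
  expect_error(simulate_study(roosts, posterior = numeric(), base = base), "no slope draws")
})
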