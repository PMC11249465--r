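test_that("temperature generator has the configured trend and noise moments", {
  cfg <- sim_config(temp_ar1 = 0, diel_amp = 0, temp_innov_sd = 2, seed = 1)
  set.seed(1)
  ts <- simulate_temperature(cfg, 5000)
  trend <- cfg$temp_mean0 + cfg$cooling_per_day * (0:5000) / 24
  expect_lt(abs(sd(ts$temp - trend) / 2 - 1), 0.05)   # white noise SD within 5%
  # cooling: first-half mean exceeds second-half mean
  cfg2 <- sim_config(seed = 2)
  set.seed(2)
  ts2 <- simulate_temperature(cfg2, 4000)
  half <- floor(nrow(ts2) / 2)
  expect_gt(mean(ts2$temp[1:half]), mean(ts2$temp[-(1:half)]))
  # determinism
  set.seed(99); a <- simulate_temperature(cfg, 500)
  set.seed(99); b <- simulate_temperature(cfg, 500)
  expect_identical(a, b)
})

test_that("track generator honours the concentration limit and step moments", {
  # near-degenerate turning about zero: path is near-collinear
  cfg <- sim_config(n_steps = 400, vm_mean = c(0, 0),
                    vm_conc = c(1000, 1000), seed = 5)
  set.seed(5)
  temp <- simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  tr <- simulate_track(cfg, temp)
  turns <- tr$steps$turn_rad[-1]
  expect_gt(mean(abs(turns) < 0.1), 0.99)

  # state-2 step mean within 5% of 0.74 km at large n
  cfg2 <- sim_config(n_steps = 500, seed = 6)
  set.seed(6)
  temp2 <- simulate_temperature(cfg2, cfg2$n_steps * 4 + 48)
  s2 <- c()
  for (i in 1:25) {
    tr2 <- simulate_track(cfg2, temp2)
    s2 <- c(s2, tr2$steps$step_km[tr2$steps$state == 2])
  }
  expect_gt(length(s2), 2000)
  expect_lt(abs(mean(s2) - 0.74) / 0.74, 0.05)
})

test_that("long-run state occupancy matches the stationary distribution", {
  # constant temperature: compare chain occupancy to the analytic solution
  cfg <- sim_config(n_steps = 4000, temp_mean0 = 0, cooling_per_day = 0,
                    diel_amp = 0, temp_ar1 = 0, temp_innov_sd = 0, seed = 9)
  set.seed(9)
  temp <- simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  tr <- simulate_track(cfg, temp)
  occ <- tabulate(tr$steps$state, 2) / cfg$n_steps
  pi0 <- stationary_probs(cfg$params, 0)
  expect_lt(abs(occ[1] - pi0$state1), 0.04)
})

test_that("observation layer reproduces truth exactly when noise-free", {
  cfg <- sim_config_noise_free(n_bears = 1, n_steps = 120, seed = 12)
  set.seed(12)
  temp <- simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  tr <- simulate_track(cfg, temp)
  ob <- simulate_observation(tr, cfg, design = "ear")
  f <- ob$fixes
  # every duty-cycle time observed, positions equal to truth
  expect_equal(nrow(f), 121)
  expect_equal(as.numeric(diff(f$time)), rep(4, 120), ignore_attr = TRUE)
  idx <- match(f$time, tr$hourly$time)
  expect_equal(f$lon, tr$hourly$lon[idx], tolerance = 1e-12)
  expect_equal(f$lat, tr$hourly$lat[idx], tolerance = 1e-12)
  expect_true(all(f$activity == "active"))
})

test_that("Argos class mix is recovered from generated fixes at n = 10000", {
  cfg <- sim_config(n_bears = 1, n_steps = 100, seed = 31,
                    mean_retention_days = c(pentagon = 1e6, seatrkr = 1e6,
                                            tribrush = 1e6, ear = 1e6))
  set.seed(31)
  temp <- simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  tr <- simulate_track(cfg, temp)
  # accumulate many observation passes over the same track
  cls <- character(0)
  for (i in 1:100) {
    ob <- simulate_observation(tr, cfg, design = "pentagon")
    cls <- c(cls, ob$fixes$loc_class)
  }
  expect_gt(length(cls), 8000)
  got <- as.numeric(table(factor(cls, levels = names(cfg$class_mix)))) / length(cls)
  expect_equal(got, unname(cfg$class_mix), tolerance = 0.08)
})

test_that("detachment emits an inactivity run that the detector recovers", {
  cfg <- sim_config(n_bears = 1, n_steps = 300, seed = 20)
  cfg$mean_retention_days[["pentagon"]] <- 15   # force detachment mid-track
  cfg$fix_success <- 1
  found <- 0L
  set.seed(20)
  temp <- simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  for (i in 1:5) {
    tr <- simulate_track(cfg, temp)
    ob <- simulate_observation(tr, cfg, design = "pentagon")
    if (is.na(ob$truth$inactivity_start)) next
    det <- detect_detachment(ob$fixes)
    expect_equal(det$status, "detached")
    # recovered within one duty cycle of the tag entering inactivity mode
    expect_lte(abs(as.numeric(difftime(det$event_time, ob$truth$inactivity_start,
                                       units = "hours"))), 4)
    found <- found + 1L
  }
  expect_gt(found, 0L)
})

test_that("a full study is deterministic under its seed and round-trips files", {
  cfg <- sim_config(n_bears = 3, n_steps = 120, seed = 77,
                    designs = c("seatrkr", "ear", "pentagon"))
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$deployments, b$deployments)

  out <- withr::local_tempdir()
  simulate_study(cfg, out_dir = out)
  f <- read_fixes(file.path(out, "fixes.csv"))
  d <- read_deployments(file.path(out, "deployments.csv"))
  tm <- read_temperature(file.path(out, "temperature.csv"))
  expect_equal(nrow(d), 3)
  expect_gt(nrow(f), 0)
  expect_gt(nrow(tm), 400)
  expect_true(file.exists(file.path(out, "config_echo.txt")))
  # files parse with zero schema errors and carry both sources
  expect_setequal(unique(f$source), c("gps", "argos"))
})
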