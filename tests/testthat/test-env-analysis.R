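test_that("nightly differential: self-difference, constants, antisymmetry", {
  log <- make_const_log(22, n = 120)
  expect_equal(nightly_differential(log, log)$mean_diff_C, 0)
  lo <- make_const_log(18, n = 120)
  nd <- nightly_differential(log, lo)
  expect_equal(nd$mean_diff_C, 4)
  expect_equal(nightly_differential(lo, log)$mean_diff_C, -nd$mean_diff_C)
})

test_that("differential pairing excludes missing aggregates and checks overlap", {
  hi <- make_const_log(22, n = 60)
  lo <- make_const_log(18, n = 60)
  hi$tent_avg[10:20] <- NA
  nd <- nightly_differential(hi, lo)
  expect_identical(nd$n_minutes, 49L)
  expect_equal(nd$mean_diff_C, 4)
  far <- make_const_log(18, n = 60, start = "2020-01-01 22:00")
  expect_error(nightly_differential(hi, far), "no timestamps")
  day <- make_const_log(22, n = 60, start = "2019-05-26 10:00")
  expect_error(nightly_differential(day, make_const_log(18, 60, "2019-05-26 10:00")),
               "stress window")
})

test_that("uniformity: trivial cases", {
  log <- make_const_log(20, n = 50)
  rep0 <- sensor_uniformity(log)
  expect_equal(rep0$mean_pairwise_abs_diff_C, 0)
  expect_equal(rep0$mean_range_C, 0)
  expect_equal(unname(rep0$per_sensor_bias_C), rep(0, 6))
  ## two constant sensors 20 and 21
  two <- make_noisy_log(c(0, 1), sd = 0, n = 30, temp = 20)
  rep2 <- sensor_uniformity(two)
  expect_equal(rep2$mean_pairwise_abs_diff_C, 1)
  expect_equal(rep2$mean_range_C, 1)
})

test_that("uniformity matches the closed-form Monte-Carlo oracle within 3 SE", {
  set.seed(31)
  biases <- c(0, 0.2, -0.2, 0.4, -0.4, 0.6)
  sd <- 0.1
  n <- 2e4
  log <- make_noisy_log(biases, sd, n)
  rep <- sensor_uniformity(log)
  ## oracle: E|N(delta_ij, 2 sd^2)| averaged over the 15 pairs
  pairs <- combn(6, 2)
  exp_pair <- mean(apply(pairs, 2, function(ij)
    expected_abs_norm(abs(biases[ij[1]] - biases[ij[2]]), sd * sqrt(2))))
  ## SE of the time-averaged statistic, estimated from the per-minute values
  x <- as.matrix(log[, paste0("sensor_", 1:6)])
  per_t <- apply(x, 1, function(r)
    mean(abs(outer(r, r, "-"))[lower.tri(diag(6))]))
  se <- sd(per_t) / sqrt(n)
  expect_lt(abs(rep$mean_pairwise_abs_diff_C - exp_pair), 3 * se)
  expect_gte(rep$mean_range_C, rep$mean_pairwise_abs_diff_C)
})

test_that("uniformity is invariant under a common offset and needs 2 sensors", {
  set.seed(12)
  log <- make_noisy_log(c(0, 0.3, -0.3, 0.1, -0.1, 0.2), 0.1, 200)
  shifted <- log
  sens <- paste0("sensor_", 1:6)
  shifted[sens] <- shifted[sens] + 5
  a <- sensor_uniformity(log); b <- sensor_uniformity(shifted)
  expect_equal(a$mean_pairwise_abs_diff_C, b$mean_pairwise_abs_diff_C)
  expect_equal(a$mean_range_C, b$mean_range_C)
  broken <- log
  broken[sens[2:6]] <- NA_real_
  expect_error(sensor_uniformity(broken), "fewer than 2")
})

test_that("VPD: saturation, anchor values, monotonicity, domain", {
  expect_equal(vpd_kPa(20, 100), 0)
  expect_equal(vpd_kPa(25, 50), 0.6108 * exp(17.27 * 25 / 262.3) * 0.5,
               tolerance = 1e-12)
  expect_equal(vpd_kPa(25, 50), 1.584, tolerance = 1e-3)
  expect_equal(vpd_kPa(0, 0), 0.6108)
  rh <- seq(0, 100, by = 5)
  expect_true(all(diff(vpd_kPa(20, rh)) < 0))         # decreasing in RH
  tt <- seq(0, 40, by = 2)
  expect_true(all(diff(vpd_kPa(tt, 50)) > 0))         # increasing in T
  expect_error(vpd_kPa(20, 101), "rh_pct")
})

test_that("hourly profile: constants, forced offset, empty bins", {
  log <- make_const_log(20, n = 120, start = "2019-05-26 13:00")
  prof <- hourly_profile(log)
  expect_equal(prof$mean_T_C[prof$hour %in% 13:14], c(20, 20))
  expect_true(all(is.na(prof$mean_T_C[!prof$hour %in% 13:14])))
  ## tent == ambient + 0.4 by construction -> day offset 0.4
  amb <- generate_ambient(ambient_params(noise_sd_C = 0),
                          "2019-05-26 07:00", 11 * 60, seed = 1)
  tent <- data.frame(time = amb$time, temp_C = amb$temp_C + 0.4)
  prof2 <- hourly_profile(tent, ambient = amb)
  expect_equal(attr(prof2, "day_offset_C"), 0.4)
})

test_that("simulated day: open tent hourly means track ambient within 1 degC", {
  run <- run_paired_night(sim_config(seed = 21))
  prof <- hourly_profile(run$truth$stress, ambient = run$ambient)
  afternoon <- prof$hour %in% 13:17
  expect_true(all(abs(prof$mean_T_C[afternoon] -
                        prof$mean_ambient_C[afternoon]) < 1))
  ## open-vent daytime offset is the configured bias
  expect_equal(attr(prof, "day_offset_C"), 0.4, tolerance = 0.25)
})

test_that("cross-module audit: heater minutes had differential below setpoint", {
  run <- run_paired_night(sim_config(seed = 22))
  m <- merge(run$log_stress[, c("time", "tent_avg", "heater_on")],
             run$log_control[, c("time", "tent_avg")], by = "time",
             suffixes = c("_s", "_c"))
  on <- m$heater_on
  expect_gt(sum(on), 0)
  expect_true(all(m$tent_avg_s[on] - m$tent_avg_c[on] < 4))
})

test_that("env_summary ties its pieces together", {
  run <- run_paired_night(sim_config(seed = 23))
  es <- env_summary(run$log_stress, run$log_control,
                    truth_stress = run$truth$stress,
                    truth_control = run$truth$control)
  expect_equal(es$mean_diff_C, es$mean_T_stress_C - es$mean_T_control_C,
               tolerance = 1e-10)
  expect_true(es$co2_stats["max"] > es$co2_stats["min"])
  expect_gt(es$rh_diff_pct, 5)      # closed stress tent runs moister at night
  expect_lt(es$vpd_stress_kPa, 1)   # humid night air: low VPD
})
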