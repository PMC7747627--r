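cfg <- controller_config()

test_that("aggregate_array averages the ok subset", {
  expect_equal(aggregate_array(make_readings(rep(20, 6))),
               list(avg_C = 20, n_ok = 6L))
  expect_equal(aggregate_array(make_readings(c(21.0, 21.5, NA, 20.5, NA, 21.0))),
               list(avg_C = 21.0, n_ok = 4L))
  expect_equal(aggregate_array(make_readings(rep(NA_real_, 6))),
               list(avg_C = NA_real_, n_ok = 0L))
})

test_that("heater decision follows the single-threshold rule with its boundary", {
  now <- tent_time("2019-05-26 22:00")
  msg <- control_message("control", now, 18.0)
  expect_true(decide_heater(21.0, msg, cfg, now))    # diff 3.0 < 4.0
  expect_false(decide_heater(22.0, msg, cfg, now))   # diff exactly 4.0 -> off
  expect_false(decide_heater(22.5, msg, cfg, now))   # diff above setpoint
})

test_that("stale or missing paired message is a fail-safe off", {
  now <- tent_time("2019-05-26 22:00")
  old <- control_message("control", tent_time("2019-05-26 21:50"), 18.0)
  expect_false(decide_heater(19.0, old, cfg, now))   # 10 min old > 5
  expect_false(decide_heater(19.0, NULL, cfg, now))
  edge <- control_message("control", tent_time("2019-05-26 21:55"), 18.0)
  expect_true(decide_heater(19.0, edge, cfg, now))   # exactly max age is usable
})

test_that("relay is forced off outside the active window", {
  msg_at <- function(t) control_message("control", tent_time(t), 18.0)
  expect_false(decide_heater(19.0, msg_at("2019-05-26 12:00"), cfg,
                             "2019-05-26 12:00"))
  expect_true(decide_heater(19.0, msg_at("2019-05-26 19:00"), cfg,
                            "2019-05-26 19:00"))    # window start is inside
  expect_false(decide_heater(19.0, msg_at("2019-05-27 06:00"), cfg,
                             "2019-05-27 06:00"))   # window end is outside
  expect_true(decide_heater(19.0, msg_at("2019-05-27 01:00"), cfg,
                            "2019-05-27 01:00"))    # past midnight
})

test_that("reboot fires on the max_consec_errors-th failed cycle", {
  st <- controller_state()
  t0 <- tent_time("2019-05-26 22:00")
  healths <- character(5)
  for (i in 1:5) {
    out <- control_cycle(st, make_readings(rep(NA_real_, 6)),
                         control_message("control", t0 + 60 * (i - 1), 18),
                         cfg, t0 + 60 * (i - 1))
    st <- out$state
    healths[i] <- out$record$health
  }
  expect_identical(healths, c(rep("sensor_error", 4), "rebooted"))
  expect_identical(st$reboot_count, 1L)
  expect_false(st$degraded)
  expect_false(st$heater_on)
})

test_that("after max_reboots the controller degrades but keeps looping", {
  st <- controller_state()
  t0 <- tent_time("2019-05-26 22:00")
  healths <- character(18)
  for (i in 1:18) {
    out <- control_cycle(st, make_readings(rep(NA_real_, 6)), NULL, cfg,
                         t0 + 60 * (i - 1))
    st <- out$state
    healths[i] <- out$record$health
  }
  expect_identical(which(healths == "rebooted"), c(5L, 10L, 15L))
  expect_true(st$degraded)
  expect_identical(st$reboot_count, 3L)          # no further reboot attempts
  expect_identical(healths[16:18], rep("degraded", 3))
})

test_that("healthy cycle inside the window engages the heater below setpoint", {
  st <- controller_state()
  now <- tent_time("2019-05-26 22:00")
  out <- control_cycle(st, make_readings(rep(20.5, 6)),
                       control_message("control", now, 18.0), cfg, now)
  expect_true(out$record$heater_on)              # diff 2.5 < 4
  expect_identical(out$record$health, "ok")
  expect_true(out$state$relay_channels[1])
})

test_that("a silent radio link coasts on the cache, then goes stale", {
  st <- controller_state()
  t0 <- tent_time("2019-05-26 22:00")
  out <- control_cycle(st, make_readings(rep(19, 6)),
                       control_message("control", t0, 18.0), cfg, t0)
  st <- out$state
  expect_true(out$record$heater_on)
  healths <- character(7); heaters <- logical(7)
  for (i in 1:7) {                               # minutes +1 .. +7, no message
    out <- control_cycle(st, make_readings(rep(19, 6)), NULL, cfg, t0 + 60 * i)
    st <- out$state
    healths[i] <- out$record$health; heaters[i] <- out$record$heater_on
  }
  expect_true(all(heaters[1:5]))                 # cache within 5 min is fresh
  expect_identical(healths[1:5], rep("ok", 5))
  expect_false(any(heaters[6:7]))                # stale -> fail-safe off
  expect_identical(healths[6:7], rep("stale_msg", 2))
})

test_that("run_controller: empty session, determinism, rule saturation", {
  expect_identical(nrow(run_controller(list(), cfg)), 0L)
  sess <- make_session(c(22.2, 22.5, 23.0, 22.1), control_temp = 18)
  log1 <- run_controller(sess, cfg)
  log2 <- run_controller(sess, cfg)
  expect_identical(log1, log2)
  expect_false(any(log1$heater_on))              # diff always >= setpoint
  sess_bad <- sess[c(2, 1, 3, 4)]
  expect_error(run_controller(sess_bad, cfg), "increasing")
})

test_that("fault state machine replays a failure pattern identically", {
  set.seed(9)
  fail_pattern <- runif(120) < 0.4
  build <- function() {
    t0 <- tent_time("2019-05-26 21:00")
    lapply(seq_along(fail_pattern), function(i) {
      vals <- if (fail_pattern[i]) rep(NA_real_, 6) else rep(20, 6)
      list(time = t0 + 60 * (i - 1), readings = make_readings(vals, t0 + 60 * (i - 1)),
           msg = control_message("control", t0 + 60 * (i - 1), 18))
    })
  }
  a <- run_controller(build(), cfg)
  b <- run_controller(build(), cfg)
  expect_identical(a$health, b$health)
  expect_identical(attr(a, "final_state"), attr(b, "final_state"))
  ## relay safety: heater never on in a cycle with no aggregate
  expect_false(any(a$heater_on & is.na(a$tent_avg)))
})
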