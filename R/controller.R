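#' Thermostat controller configuration
#'
#' The stress-tent controller reads its six-sensor array once per minute,
#' averages the successful reads, compares the average against the paired
#' control tent's wirelessly transmitted average, and engages the propane
#' heater while the stress tent is less than `setpoint_diff_C` warmer than
#' the control tent. A differential at or above the setpoint leaves the
#' heater off (single-threshold bang-bang, no hysteresis; the one-minute
#' cadence prevents short-cycling). A cycle whose reads all fail feeds a
#' consecutive-error counter; at `max_consec_errors` the controller reboots
#' itself (state reset, heater forced off for that cycle) and after
#' `max_reboots` reboots it stays online in a degraded state rather than
#' abandoning the experiment.
#'
#' @param setpoint_diff_C target stress-minus-control differential, degC.
#' @param read_interval_s sensing/logging cadence, seconds.
#' @param n_sensors sensors per tent.
#' @param max_consec_errors consecutive failed cycles before a reboot.
#' @param max_reboots reboot attempts before degraded-continue.
#' @param stale_msg_max_min maximum age (minutes) of the paired-tent
#'   message before the fail-safe forces the heater off.
#' @param active_window `c(start, end)` clock interval ("HH:MM") during
#'   which the relay may be driven; outside it the heater is forced off.
#' @param stress_window `c(start, end)` clock interval defining the stress
#'   period for reporting.
#' @param relay_enabled `FALSE` for control-tent loggers, which sense and
#'   log but drive no heater.
#' @return object of class `controller_config`.
#' @export
controller_config <- function(setpoint_diff_C = 4.0, read_interval_s = 60,
                              n_sensors = 6, max_consec_errors = 5,
                              max_reboots = 3, stale_msg_max_min = 5,
                              active_window = c("19:00", "06:00"),
                              stress_window = c("20:00", "06:00"),
                              relay_enabled = TRUE) {
  assert_that(setpoint_diff_C > 0, "setpoint_diff_C must be > 0")
  assert_that(read_interval_s > 0, "read_interval_s must be > 0")
  assert_that(max_consec_errors >= 1 && max_reboots >= 0,
              "fault-policy counters must be positive")
  parse_clock(active_window[1]); parse_clock(active_window[2])
  parse_clock(stress_window[1]); parse_clock(stress_window[2])
  structure(list(setpoint_diff_C = setpoint_diff_C,
                 read_interval_s = read_interval_s, n_sensors = n_sensors,
                 max_consec_errors = max_consec_errors,
                 max_reboots = max_reboots,
                 stale_msg_max_min = stale_msg_max_min,
                 active_window = active_window,
                 stress_window = stress_window,
                 relay_enabled = isTRUE(relay_enabled)),
            class = "controller_config")
}

#' Fresh controller state (as after power-on or reboot)
#' @return object of class `controller_state`.
#' @export
controller_state <- function() {
  structure(list(heater_on = FALSE, consec_errors = 0L, reboot_count = 0L,
                 degraded = FALSE, last_msg = NULL,
                 relay_channels = rep(FALSE, 4)),
            class = "controller_state")
}

#' Paired-tent wireless message
#'
#' @param source_tent label of the sending (control) tent.
#' @param time timestamp of the aggregate.
#' @param avg_temp_C control-tent sensor-array average, degC (finite).
#' @return object of class `control_message`.
#' @export
control_message <- function(source_tent, time, avg_temp_C) {
  if (is.character(time)) time <- tent_time(time)
  assert_that(is.finite(avg_temp_C), "avg_temp_C must be finite")
  structure(list(source_tent = source_tent, time = time,
                 avg_temp_C = avg_temp_C),
            class = "control_message")
}

#' Aggregate one cycle of array readings
#'
#' Arithmetic mean over `status == "ok"` readings; a cycle with no
#' successful read yields `avg_C = NA` and `n_ok = 0`, which feeds the
#' fault policy rather than raising.
#'
#' @param readings data.frame as returned by [sample_sensors()].
#' @return list with `avg_C` (`NA_real_` if none ok) and `n_ok`.
#' @export
aggregate_array <- function(readings) {
  ok <- readings$status == "ok"
  n_ok <- sum(ok)
  list(avg_C = if (n_ok > 0L) mean(readings$value_C[ok]) else NA_real_,
       n_ok = as.integer(n_ok))
}

## is the paired message usable at time `now`?
msg_is_fresh <- function(msg, cfg, now) {
  !is.null(msg) &&
    as.numeric(difftime(now, msg$time, units = "mins")) <= cfg$stale_msg_max_min
}

#' The bang-bang heater decision
#'
#' `TRUE` iff the stress tent is less than the setpoint above the paired
#' control tent AND the paired message is fresh AND `now` lies inside the
#' active window. A differential exactly equal to the setpoint ("4 degC or
#' more above") leaves the heater off; a stale or missing message is a
#' fail-safe off.
#'
#' @param stress_avg_C stress-tent array average, degC.
#' @param control_msg a [control_message()] or `NULL`.
#' @param cfg a [controller_config()].
#' @param now current timestamp.
#' @return logical.
#' @export
decide_heater <- function(stress_avg_C, control_msg, cfg, now) {
  if (is.character(now)) now <- tent_time(now)
  if (is.na(stress_avg_C)) return(FALSE)
  if (!in_clock_window(now, cfg$active_window[1], cfg$active_window[2]))
    return(FALSE)
  if (!msg_is_fresh(control_msg, cfg, now)) return(FALSE)
  (stress_avg_C - control_msg$avg_temp_C) < cfg$setpoint_diff_C
}

HEALTH_LEVELS <- c("ok", "sensor_error", "rebooted", "degraded", "stale_msg")

#' One per-minute controller cycle
#'
#' Aggregates the readings, applies the fault policy, decides the heater,
#' and emits exactly one log record. Sensor failure never raises: an empty
#' aggregate increments `consec_errors`; reaching `max_consec_errors`
#' triggers a simulated reboot (counters reset, `reboot_count + 1`, heater
#' forced off for the cycle, health `"rebooted"`); once `reboot_count`
#' reaches `max_reboots` the controller is `degraded` but keeps looping.
#'
#' @param state a [controller_state()].
#' @param readings data.frame from [sample_sensors()] (one cycle).
#' @param msg a [control_message()] or `NULL`; a fresh message is cached in
#'   the state so a briefly silent radio link coasts on the last value
#'   until it goes stale.
#' @param cfg a [controller_config()].
#' @param now cycle timestamp.
#' @param co2_ppm optional CO2 reading to log.
#' @return list with the updated `state` and a one-row `record` data.frame.
#' @export
control_cycle <- function(state, readings, msg, cfg, now, co2_ppm = NA_real_) {
  if (is.character(now)) now <- tent_time(now)
  agg <- aggregate_array(readings)
  if (!is.null(msg)) state$last_msg <- msg

  health <- "ok"
  heater <- FALSE
  if (agg$n_ok == 0L) {
    state$consec_errors <- state$consec_errors + 1L
    if (state$consec_errors >= cfg$max_consec_errors &&
        state$reboot_count < cfg$max_reboots) {
      state$reboot_count <- state$reboot_count + 1L
      state$consec_errors <- 0L
      state$last_msg <- NULL          # caches do not survive the reboot
      if (state$reboot_count >= cfg$max_reboots) state$degraded <- TRUE
      health <- "rebooted"
    } else {
      health <- if (state$degraded) "degraded" else "sensor_error"
    }
  } else {
    state$consec_errors <- 0L
    if (cfg$relay_enabled) {
      fresh <- msg_is_fresh(state$last_msg, cfg, now)
      active <- in_clock_window(now, cfg$active_window[1], cfg$active_window[2])
      heater <- decide_heater(agg$avg_C, state$last_msg, cfg, now)
      if (!fresh && active) health <- "stale_msg"
    }
  }
  state$heater_on <- heater
  state$relay_channels[1] <- heater

  vals <- rep(NA_real_, cfg$n_sensors)
  ok <- readings$status == "ok"
  take <- seq_len(min(nrow(readings), cfg$n_sensors))
  vals[take] <- ifelse(ok, readings$value_C, NA_real_)[take]
  rec <- structure(
    c(list(time = now), as.list(vals),
      list(tent_avg = agg$avg_C, co2_ppm = co2_ppm, heater_on = heater,
           health = health)),
    names = c("time", paste0("sensor_", seq_len(cfg$n_sensors)),
              "tent_avg", "co2_ppm", "heater_on", "health"),
    class = "data.frame", row.names = 1L)
  list(state = state, record = rec)
}

#' Drive a controller over a recorded session
#'
#' Replays a time-ordered sequence of per-minute cycles (each a list with
#' `time`, `readings`, optional `msg`, optional `co2_ppm`) through
#' [control_cycle()] and collects the log. Deterministic: identical input
#' yields identical output.
#'
#' @param session list of cycles in time order.
#' @param cfg a [controller_config()].
#' @return an `env_log` data.frame (see [write_envlog()] for the schema).
#' @export
run_controller <- function(session, cfg) {
  state <- controller_state()
  n <- length(session)
  recs <- vector("list", n)
  last_t <- NULL
  for (i in seq_len(n)) {
    cyc <- session[[i]]
    now <- if (is.character(cyc$time)) tent_time(cyc$time) else cyc$time
    if (!is.null(last_t) && now <= last_t)
      stop("session timestamps must be strictly increasing (cycle ", i, ")",
           call. = FALSE)
    last_t <- now
    out <- control_cycle(state, cyc$readings, cyc$msg, cfg, now,
                         co2_ppm = if (is.null(cyc$co2_ppm)) NA_real_ else cyc$co2_ppm)
    state <- out$state
    recs[[i]] <- out$record
  }
  log <- if (n == 0L) empty_env_log(cfg$n_sensors) else do.call(rbind, recs)
  structure(log, class = c("env_log", "data.frame"),
            final_state = state)
}

empty_env_log <- function(n_sensors = 6) {
  cols <- c(list(time = as.POSIXct(character(), tz = "UTC")),
            stats::setNames(rep(list(numeric()), n_sensors),
                            paste0("sensor_", seq_len(n_sensors))),
            list(tent_avg = numeric(), co2_ppm = numeric(),
                 heater_on = logical(), health = character()))
  structure(as.data.frame(cols, stringsAsFactors = FALSE),
            class = c("env_log", "data.frame"))
}
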