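#' Paired-tent simulation configuration
#'
#' Bundles everything one seeded, bit-reproducible closed-loop run needs:
#' per-role thermal parameters, the two six-sensor arrays, the ambient
#' driver, the nightly schedule and the number of nights.
#'
#' The schedule mirrors field operation: stress tents are rolled down at
#' 18:30; control tents then close to the 20-cm gap setting (18:45); the
#' generator powers the controllers from 19:00; the stress window proper is
#' 20:00-06:00; at 06:00 power is removed and every tent opens to its day
#' setting.
#'
#' @param thermal_stress,thermal_control [thermal_params()] per tent role.
#' @param sensors_stress,sensors_control lists of [sensor_spec()] (default
#'   six per tent).
#' @param ambient an [ambient_params()] driver.
#' @param n_nights number of nights to simulate.
#' @param seed integer RNG seed; a fixed seed gives byte-identical traces.
#' @param close_stress,close_control,power_on,open_all clock times ("HH:MM")
#'   of the schedule state machine.
#' @param co2_noise_sd_ppm read noise of the logged CO2 sensor, ppm.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(thermal_stress = thermal_params(),
                       thermal_control = thermal_params(),
                       sensors_stress = default_sensor_array(),
                       sensors_control = default_sensor_array(),
                       ambient = ambient_params(),
                       n_nights = 1, seed = 1,
                       close_stress = "18:30", close_control = "18:45",
                       power_on = "19:00", open_all = "06:00",
                       co2_noise_sd_ppm = 10) {
  assert_that(n_nights >= 1, "n_nights must be >= 1")
  structure(list(thermal_stress = thermal_stress,
                 thermal_control = thermal_control,
                 sensors_stress = sensors_stress,
                 sensors_control = sensors_control,
                 ambient = ambient, n_nights = as.integer(n_nights),
                 seed = as.integer(seed),
                 close_stress = close_stress, close_control = close_control,
                 power_on = power_on, open_all = open_all,
                 co2_noise_sd_ppm = co2_noise_sd_ppm),
            class = "sim_config")
}

## fast one-row log record (same columns as control_cycle emits)
fast_row <- function(...) {
  structure(list(...), class = "data.frame", row.names = 1L)
}

#' Run the closed-loop paired-tent simulation
#'
#' Advances a control tent and its paired stress tent minute by minute from
#' noon of the first day to 06:00 after the last night. Every powered
#' minute the control-tent logger samples its array and transmits its
#' aggregate; the stress-tent controller samples its own array, applies the
#' bang-bang rule against the paired message, and its relay command drives
#' the stress tent's heater in the next physics step. A controller error
#' never stops the run: the cycle is logged as failed and the simulation
#' continues, mirroring the stay-online field policy.
#'
#' @param sim a [sim_config()].
#' @param controller_cfg a [controller_config()] for the stress tent; the
#'   control-tent logger uses the same config with the relay disabled.
#' @param start_evening date or timestamp of the first day; simulation
#'   starts at 12:00 local on that day.
#' @return list of class `paired_run` with elements `log_stress`,
#'   `log_control` (`env_log` data.frames covering powered minutes),
#'   `truth` (list of ground-truth minute traces `stress`, `control`), and
#'   `ambient` (the driving `ambient_trace`).
#' @export
run_paired_nights <- function(sim, controller_cfg = controller_config(),
                              start_evening = "2019-05-26") {
  assert_that(inherits(sim, "sim_config"), "sim must be a sim_config")
  set.seed(sim$seed)
  day1 <- substr(as.character(start_evening), 1, 10)
  start <- tent_time(paste(day1, "12:00"))
  n_min <- (sim$n_nights - 1L) * 1440L + 1080L   # noon day 1 -> 06:00 last+1
  amb <- generate_ambient(sim$ambient, start, n_min)

  cfg_s <- controller_cfg
  cfg_c <- controller_cfg; cfg_c$relay_enabled <- FALSE
  st_state <- controller_state(); ct_state <- controller_state()

  t0 <- amb$temp_C[1]
  stress <- tent_state(start, t0 + sim$thermal_stress$day_bias_C, amb$rh_pct[1],
                       sim$thermal_stress$co2_base_ppm, "open")
  control <- tent_state(start, t0 + sim$thermal_control$day_bias_C, amb$rh_pct[1],
                        sim$thermal_control$co2_base_ppm, "open")

  ns <- length(sim$sensors_stress)
  truth_cols <- function(n) list(temp_C = numeric(n), rh_pct = numeric(n),
                                 co2_ppm = numeric(n),
                                 vent_state = character(n), heater_on = logical(n))
  tr_s <- truth_cols(n_min); tr_c <- truth_cols(n_min)
  recs_s <- vector("list", n_min); recs_c <- vector("list", n_min)

  powered_prev <- FALSE
  for (i in seq_len(n_min)) {
    now <- amb$time[i]
    stress$vent_state <-
      if (in_clock_window(now, sim$close_stress, sim$open_all)) "closed" else "open"
    control$vent_state <-
      if (in_clock_window(now, sim$close_control, sim$open_all)) "control_gap" else "open"
    powered <- in_clock_window(now, sim$power_on, sim$open_all)
    if (powered && !powered_prev) {       # fresh boot each evening
      st_state <- controller_state(); ct_state <- controller_state()
    }
    powered_prev <- powered

    heater_cmd <- FALSE
    if (powered) {
      rd_c <- sample_sensors(control, sim$sensors_control)
      out_c <- tryCatch(
        control_cycle(ct_state, rd_c, NULL, cfg_c, now),
        error = function(e) NULL)
      msg <- NULL
      if (!is.null(out_c)) {
        ct_state <- out_c$state
        recs_c[[i]] <- out_c$record
        if (!is.na(out_c$record$tent_avg))
          msg <- control_message("control", now, out_c$record$tent_avg)
      }
      rd_s <- sample_sensors(stress, sim$sensors_stress)
      co2_read <- stress$co2_ppm + stats::rnorm(1, 0, sim$co2_noise_sd_ppm)
      out_s <- tryCatch(
        control_cycle(st_state, rd_s, msg, cfg_s, now, co2_ppm = co2_read),
        error = function(e) NULL)
      if (!is.null(out_s)) {
        st_state <- out_s$state
        recs_s[[i]] <- out_s$record
        heater_cmd <- out_s$record$heater_on
      }
    }

    ## record truth at this minute, then step the physics
    tr_s$temp_C[i] <- stress$temp_C; tr_s$rh_pct[i] <- stress$rh_pct
    tr_s$co2_ppm[i] <- stress$co2_ppm; tr_s$vent_state[i] <- stress$vent_state
    tr_s$heater_on[i] <- heater_cmd && stress$vent_state == "closed"
    tr_c$temp_C[i] <- control$temp_C; tr_c$rh_pct[i] <- control$rh_pct
    tr_c$co2_ppm[i] <- control$co2_ppm; tr_c$vent_state[i] <- control$vent_state
    tr_c$heater_on[i] <- FALSE

    ambi <- c(temp_C = amb$temp_C[i], rh_pct = amb$rh_pct[i])
    stress <- step_tent(stress, ambi, sim$thermal_stress, heater_cmd)
    control <- step_tent(control, ambi, sim$thermal_control, FALSE)
  }

  bind_log <- function(recs) {
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (!length(recs)) return(empty_env_log(ns))
    cols <- names(recs[[1]])
    out <- lapply(cols, function(cn) {
      v <- lapply(recs, `[[`, cn)
      if (cn == "time") .POSIXct(vapply(v, as.numeric, numeric(1)), tz = "UTC")
      else unlist(v, use.names = FALSE)
    })
    names(out) <- cols
    structure(out, class = c("env_log", "data.frame"),
              row.names = seq_along(recs))
  }
  truth_df <- function(tr) data.frame(time = amb$time, tr, stringsAsFactors = FALSE)
  structure(list(log_stress = bind_log(recs_s), log_control = bind_log(recs_c),
                 truth = list(stress = truth_df(tr_s), control = truth_df(tr_c)),
                 ambient = amb),
            class = "paired_run")
}

#' Run a single simulated night
#'
#' Convenience wrapper around [run_paired_nights()] with `n_nights = 1`.
#'
#' @inheritParams run_paired_nights
#' @return see [run_paired_nights()].
#' @export
run_paired_night <- function(sim, controller_cfg = controller_config(),
                             start_evening = "2019-05-26") {
  sim$n_nights <- 1L
  run_paired_nights(sim, controller_cfg, start_evening)
}
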