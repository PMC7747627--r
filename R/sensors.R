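#' One temperature sensor of a tent's array
#'
#' Models an MCP9808-class digital sensor: a fixed spatial bias (where it
#' hangs in the tent), Gaussian read noise (the +/- 0.25 degC sensitivity
#' envelope), and two failure modes — an independent per-read failure
#' probability and a "stuck" failure after a given time (shorted leads).
#'
#' @param sensor_id label.
#' @param bias_C fixed spatial offset, degC.
#' @param noise_sd_C Gaussian read-noise SD, degC (>= 0).
#' @param fail_prob per-read independent failure probability in [0, 1].
#' @param stuck_fail_from optional timestamp after which every read fails.
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(sensor_id, bias_C = 0, noise_sd_C = 0.25,
                        fail_prob = 0, stuck_fail_from = NULL) {
  assert_that(noise_sd_C >= 0, "noise_sd_C must be >= 0")
  assert_that(fail_prob >= 0 && fail_prob <= 1, "fail_prob must lie in [0, 1]")
  if (is.character(stuck_fail_from)) stuck_fail_from <- tent_time(stuck_fail_from)
  structure(list(sensor_id = as.character(sensor_id), bias_C = bias_C,
                 noise_sd_C = noise_sd_C, fail_prob = fail_prob,
                 stuck_fail_from = stuck_fail_from),
            class = "sensor_spec")
}

#' Default six-sensor array
#'
#' Six sensors with evenly spread spatial biases and the +/- 0.25 degC
#' read-noise envelope; the bias spread is sized so the time-averaged mean
#' absolute pairwise inter-sensor difference is a few tenths of a degC,
#' matching the uniformity a well-mixed tent achieves in the field.
#'
#' @param n number of sensors (default 6).
#' @param bias_spread_C total spread of the evenly spaced biases, degC.
#' @param noise_sd_C per-read noise SD, degC.
#' @param fail_prob per-read failure probability applied to every sensor.
#' @param prefix sensor id prefix.
#' @return list of [sensor_spec()] objects.
#' @export
default_sensor_array <- function(n = 6, bias_spread_C = 1.0, noise_sd_C = 0.25,
                                 fail_prob = 0, prefix = "sensor") {
  biases <- if (n == 1L) 0 else seq(-bias_spread_C / 2, bias_spread_C / 2,
                                    length.out = n)
  lapply(seq_len(n), function(i)
    sensor_spec(paste0(prefix, "_", i), bias_C = biases[i],
                noise_sd_C = noise_sd_C, fail_prob = fail_prob))
}

#' Read the sensor array once
#'
#' One reading per sensor: `value_C = temp_C + bias_C + noise`. A read
#' fails (status `"failed"`, no value) independently with `fail_prob`, or
#' always once past `stuck_fail_from`. Failures are data, not exceptions,
#' and never alter the true state. Uses the current RNG stream.
#'
#' @param state a [tent_state()].
#' @param sensors list of [sensor_spec()] objects.
#' @return data.frame with columns `sensor_id`, `time`, `value_C`
#'   (`NA` when failed), `status` (`"ok"`/`"failed"`).
#' @export
sample_sensors <- function(state, sensors) {
  assert_that(inherits(state, "tent_state"), "state must be a tent_state")
  n <- length(sensors)
  bias <- vapply(sensors, `[[`, numeric(1), "bias_C")
  sd <- vapply(sensors, `[[`, numeric(1), "noise_sd_C")
  pfail <- vapply(sensors, `[[`, numeric(1), "fail_prob")
  stuck <- vapply(sensors, function(s) {
    !is.null(s$stuck_fail_from) && state$time >= s$stuck_fail_from
  }, logical(1))
  ## draw noise and failure uniformly for every sensor so the RNG stream
  ## advances identically whatever the failure pattern
  noise <- stats::rnorm(n, 0, sd)
  failed <- stuck | (stats::runif(n) < pfail)
  value <- state$temp_C + bias + noise
  value[failed] <- NA_real_
  structure(list(sensor_id = vapply(sensors, `[[`, character(1), "sensor_id"),
                 time = rep(state$time, n),
                 value_C = value,
                 status = ifelse(failed, "failed", "ok")),
            class = "data.frame", row.names = seq_len(n))
}
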