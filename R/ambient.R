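#' Ambient weather driver parameters
#'
#' The simulator's ambient conditions follow a diurnal sinusoid (daily
#' maximum mid-afternoon, minimum pre-dawn) plus stationary AR(1) noise.
#' Relative humidity runs in anti-phase with temperature. Defaults emulate a
#' late-May night in the central Great Plains: ambient nights around 18 degC
#' so that an unheated control tent sits near the reported 18.4 degC
#' stress-period mean.
#'
#' @param mean_C daily mean air temperature, degC.
#' @param amplitude_C semi-amplitude of the diurnal cycle, degC.
#' @param peak_hour clock hour of the daily maximum (decimal hours).
#' @param noise_sd_C stationary SD of the AR(1) temperature noise, degC.
#' @param ar1 AR(1) coefficient of the noise (per minute), in [0, 1).
#' @param rh_mean_pct daily mean relative humidity, %.
#' @param rh_amplitude_pct semi-amplitude of the RH cycle, % (anti-phase).
#' @param rh_noise_sd_pct stationary SD of the RH noise, %.
#' @return object of class `ambient_params`.
#' @export
ambient_params <- function(mean_C = 18, amplitude_C = 6, peak_hour = 15.5,
                           noise_sd_C = 0.3, ar1 = 0.8,
                           rh_mean_pct = 65, rh_amplitude_pct = 18,
                           rh_noise_sd_pct = 1.5) {
  assert_that(amplitude_C >= 0, "amplitude_C must be >= 0")
  assert_that(noise_sd_C >= 0, "noise_sd_C must be >= 0")
  assert_that(ar1 >= 0 && ar1 < 1, "ar1 must be in [0, 1)")
  assert_that(rh_mean_pct >= 0 && rh_mean_pct <= 100, "rh_mean_pct must be in [0, 100]")
  structure(list(mean_C = mean_C, amplitude_C = amplitude_C,
                 peak_hour = peak_hour, noise_sd_C = noise_sd_C, ar1 = ar1,
                 rh_mean_pct = rh_mean_pct, rh_amplitude_pct = rh_amplitude_pct,
                 rh_noise_sd_pct = rh_noise_sd_pct),
            class = "ambient_params")
}

## stationary AR(1) sample of length n with marginal SD sd
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1L] + innov[i - 1L]
  }
  x
}

#' Generate an ambient trace
#'
#' Minute-resolution ambient temperature and relative humidity: diurnal
#' sinusoid plus AR(1) noise, deterministic under a fixed seed.
#'
#' @param params an [ambient_params()] object.
#' @param start_time start timestamp (`POSIXct` or `"YYYY-MM-DD HH:MM"`).
#' @param n_minutes number of one-minute samples (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside the closed-loop simulator).
#' @return data.frame of class `ambient_trace` with columns `time`,
#'   `temp_C`, `rh_pct`; attribute `step_s = 60`.
#' @export
generate_ambient <- function(params, start_time, n_minutes, seed = NULL) {
  assert_that(inherits(params, "ambient_params"), "params must be ambient_params")
  assert_that(is.numeric(n_minutes) && length(n_minutes) == 1L && n_minutes >= 1,
              "n_minutes must be a positive count")
  n_minutes <- as.integer(n_minutes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.character(start_time)) start_time <- tent_time(start_time)
  time <- start_time + 60 * (seq_len(n_minutes) - 1L)
  h <- minute_of_day(time) / 60
  phase <- 2 * pi * (h - params$peak_hour) / 24
  temp <- params$mean_C + params$amplitude_C * cos(phase) +
    ar1_noise(n_minutes, params$noise_sd_C, params$ar1)
  rh <- params$rh_mean_pct - params$rh_amplitude_pct * cos(phase) +
    ar1_noise(n_minutes, params$rh_noise_sd_pct, params$ar1)
  rh <- pmin(100, pmax(0, rh))
  structure(data.frame(time = time, temp_C = temp, rh_pct = rh),
            step_s = 60, class = c("ambient_trace", "data.frame"))
}

#' Read an ambient trace from CSV
#'
#' Accepts the same schema [generate_ambient()] emits (`time`, `temp_C`,
#' `rh_pct`), so recorded weather can replace the synthetic driver.
#'
#' @param path CSV file path.
#' @return `ambient_trace` data.frame.
#' @export
read_ambient <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "temp_C", "rh_pct")
  assert_that(all(need %in% names(df)),
              paste("ambient CSV must have columns:", paste(need, collapse = ", ")))
  df$time <- tent_time(df$time)
  assert_that(all(df$rh_pct >= 0 & df$rh_pct <= 100), "rh_pct must lie in [0, 100]")
  structure(df[need], step_s = 60, class = c("ambient_trace", "data.frame"))
}
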