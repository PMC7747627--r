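## shared fixture builders (everything generated in code; no stored data)

## one cycle of array readings with explicit values; NA = failed read
make_readings <- function(values, time = "2019-05-26 22:00",
                          ids = paste0("sensor_", seq_along(values))) {
  if (is.character(time)) time <- tent_time(time)
  data.frame(sensor_id = ids, time = time, value_C = values,
             status = ifelse(is.na(values), "failed", "ok"),
             stringsAsFactors = FALSE)
}

## constant-temperature env log covering one night's stress window
make_const_log <- function(temp, n = 60, start = "2019-05-26 22:00",
                           co2 = NA_real_) {
  t0 <- tent_time(start)
  time <- t0 + 60 * (seq_len(n) - 1L)
  vals <- matrix(temp, nrow = n, ncol = 6)
  df <- data.frame(time = time, vals, tent_avg = temp, co2_ppm = co2,
                   heater_on = FALSE, health = "ok",
                   stringsAsFactors = FALSE)
  names(df)[2:7] <- paste0("sensor_", 1:6)
  structure(df, class = c("env_log", "data.frame"))
}

## env log whose sensor columns are temp + bias + N(0, sd), for uniformity
make_noisy_log <- function(biases, sd, n, temp = 20,
                           start = "2019-05-26 22:00") {
  t0 <- tent_time(start)
  time <- t0 + 60 * (seq_len(n) - 1L)
  vals <- sapply(seq_along(biases), function(i)
    temp + biases[i] + stats::rnorm(n, 0, sd))
  df <- data.frame(time = time, vals, tent_avg = rowMeans(vals),
                   co2_ppm = NA_real_, heater_on = FALSE, health = "ok",
                   stringsAsFactors = FALSE)
  names(df)[1 + seq_along(biases)] <- paste0("sensor_", seq_along(biases))
  structure(df, class = c("env_log", "data.frame"))
}

## a small controller session: per-minute cycles with given stress temps
## and a fresh control message at each minute
make_session <- function(stress_temps, control_temp = 18,
                         start = "2019-05-26 22:00") {
  t0 <- tent_time(start)
  lapply(seq_along(stress_temps), function(i) {
    now <- t0 + 60 * (i - 1L)
    list(time = now,
         readings = make_readings(rep(stress_temps[i], 6), now),
         msg = control_message("control", now, control_temp))
  })
}

## closed form E|X| for X ~ N(mu, sd^2): oracle for uniformity expectations
expected_abs_norm <- function(mu, sd) {
  mu * (1 - 2 * stats::pnorm(-mu / sd)) + 2 * sd * stats::dnorm(mu / sd)
}
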