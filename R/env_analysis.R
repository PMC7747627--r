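#' Vapor pressure deficit
#'
#' `VPD = es(T) * (1 - RH/100)` with the Magnus saturation curve
#' ([svp_kPa()], FAO-56 constants), evaluated at air temperature.
#'
#' @param temp_C air temperature, degC.
#' @param rh_pct relative humidity, % in [0, 100].
#' @return VPD, kPa (>= 0).
#' @export
vpd_kPa <- function(temp_C, rh_pct) {
  assert_that(all(rh_pct >= 0 & rh_pct <= 100, na.rm = TRUE),
              "rh_pct must lie in [0, 100]")
  svp_kPa(temp_C) * (1 - rh_pct / 100)
}

## night label: minutes before noon belong to the previous calendar day,
## so one 20:00-06:00 stress window gets a single label
night_of <- function(t) {
  as.Date(t - 12 * 3600, tz = "UTC")
}

#' Stress-window temperature differential between paired tents
#'
#' Pairs the two logs by exact timestamp (both streams are minute-aligned;
#' no interpolation), restricts to the stress window, and averages
#' `stress_avg - control_avg`. Minutes where either aggregate is missing
#' are excluded pairwise.
#'
#' @param log_stress,log_control `env_log` data.frames.
#' @param stress_window `c(start, end)` clock interval, default
#'   `c("20:00", "06:00")`.
#' @return list with `mean_diff_C`, `n_minutes`, `per_night` (data.frame
#'   `night`, `mean_diff_C`, `n`), and `series` (time, diff_C).
#' @export
nightly_differential <- function(log_stress, log_control,
                                 stress_window = c("20:00", "06:00")) {
  m <- merge(log_stress[, c("time", "tent_avg")],
             log_control[, c("time", "tent_avg")],
             by = "time", suffixes = c("_stress", "_control"))
  if (nrow(m) == 0L) stop("logs share no timestamps", call. = FALSE)
  m <- m[in_clock_window(m$time, stress_window[1], stress_window[2]), ]
  m <- m[!is.na(m$tent_avg_stress) & !is.na(m$tent_avg_control), ]
  if (nrow(m) == 0L) stop("no paired aggregates inside the stress window",
                          call. = FALSE)
  d <- m$tent_avg_stress - m$tent_avg_control
  night <- night_of(m$time)
  per_night <- aggregate(d, list(night = night), mean)
  names(per_night)[2] <- "mean_diff_C"
  per_night$n <- as.vector(table(night)[as.character(per_night$night)])
  list(mean_diff_C = mean(d), n_minutes = nrow(m), per_night = per_night,
       series = data.frame(time = m$time, diff_C = d))
}

#' Inter-sensor uniformity of one tent's log
#'
#' At each timestamp with at least two successful reads, computes the mean
#' absolute pairwise difference and the range (max - min) across sensors,
#' then averages over time. Per-sensor bias is each sensor's mean minus the
#' tent mean over the timestamps where it read successfully. Both spread
#' statistics are reported because a printed "differential between the
#' sensors" could be either.
#'
#' @param log an `env_log` data.frame.
#' @return list of class `uniformity_report`: `mean_pairwise_abs_diff_C`,
#'   `mean_range_C`, `per_sensor_bias_C` (named numeric), `n_timestamps`.
#' @export
sensor_uniformity <- function(log) {
  sens_cols <- grep("^sensor_", names(log), value = TRUE)
  assert_that(length(sens_cols) >= 2, "need >= 2 sensor columns")
  x <- as.matrix(log[, sens_cols])
  n_ok <- rowSums(!is.na(x))
  use <- n_ok >= 2
  if (!any(use)) stop("fewer than 2 ok sensors at every timestamp", call. = FALSE)
  xu <- x[use, , drop = FALSE]
  pair_mean <- apply(xu, 1, function(r) {
    r <- r[!is.na(r)]
    mean(abs(outer(r, r, "-"))[lower.tri(diag(length(r)))])
  })
  rng <- apply(xu, 1, function(r) diff(range(r, na.rm = TRUE)))
  tent_mean <- rowMeans(x, na.rm = TRUE)
  bias <- colMeans(x - tent_mean, na.rm = TRUE)
  names(bias) <- sens_cols
  structure(list(mean_pairwise_abs_diff_C = mean(pair_mean),
                 mean_range_C = mean(rng),
                 per_sensor_bias_C = bias,
                 n_timestamps = sum(use)),
            class = "uniformity_report")
}

#' Clock-hour temperature profile
#'
#' Bins a temperature series by clock hour and reports per-hour means,
#' optionally alongside an ambient trace, plus the day-period
#' tent-minus-ambient offset (07:00-18:00). Empty bins are `NA`, not zero.
#'
#' @param x an `env_log` (its `tent_avg` is used), a ground-truth trace
#'   (`time` + `temp_C`), or any data.frame with `time` and one of those
#'   columns.
#' @param ambient optional `ambient_trace` covering the same times.
#' @param day_window clock window for the daytime-offset summary.
#' @return data.frame `hour` (0-23), `mean_T_C`, and when `ambient` is
#'   given `mean_ambient_C`; attribute `day_offset_C`.
#' @export
hourly_profile <- function(x, ambient = NULL,
                           day_window = c("07:00", "18:00")) {
  temp <- if ("tent_avg" %in% names(x)) x$tent_avg else x$temp_C
  assert_that(!is.null(temp), "x must carry tent_avg or temp_C")
  hr <- factor(minute_of_day(x$time) %/% 60L, levels = 0:23)
  out <- data.frame(hour = 0:23,
                    mean_T_C = as.numeric(tapply(temp, hr, mean, na.rm = TRUE)))
  out$mean_T_C[is.nan(out$mean_T_C)] <- NA_real_
  if (!is.null(ambient)) {
    ahr <- factor(minute_of_day(ambient$time) %/% 60L, levels = 0:23)
    out$mean_ambient_C <- as.numeric(tapply(ambient$temp_C, ahr, mean, na.rm = TRUE))
    out$mean_ambient_C[is.nan(out$mean_ambient_C)] <- NA_real_
    m <- merge(data.frame(time = x$time, temp = temp),
               ambient[, c("time", "temp_C")], by = "time")
    m <- m[in_clock_window(m$time, day_window[1], day_window[2]), ]
    attr(out, "day_offset_C") <- if (nrow(m)) mean(m$temp - m$temp_C, na.rm = TRUE)
      else NA_real_
  }
  out
}

#' Stress-window environment summary for a paired run
#'
#' The headline reductions behind a season's environmental reporting: the
#' stress-window means of each tent and their differential (from the
#' controller logs), CO2 statistics (stress-tent log), and - when ground
#' truth or HOBO-style RH traces are supplied - the stress-window RH
#' difference and VPD of both tents.
#'
#' @param log_stress,log_control `env_log` data.frames.
#' @param truth_stress,truth_control optional traces with `time`, `temp_C`,
#'   `rh_pct` for RH/VPD summaries.
#' @param stress_window `c(start, end)` clock interval.
#' @return list of class `env_summary`.
#' @export
env_summary <- function(log_stress, log_control,
                        truth_stress = NULL, truth_control = NULL,
                        stress_window = c("20:00", "06:00")) {
  nd <- nightly_differential(log_stress, log_control, stress_window)
  in_win <- function(df) df[in_clock_window(df$time, stress_window[1],
                                            stress_window[2]), ]
  ls <- in_win(log_stress); lc <- in_win(log_control)
  co2 <- ls$co2_ppm[!is.na(ls$co2_ppm)]
  out <- list(mean_diff_C = nd$mean_diff_C,
              mean_T_stress_C = mean(ls$tent_avg, na.rm = TRUE),
              mean_T_control_C = mean(lc$tent_avg, na.rm = TRUE),
              per_night = nd$per_night,
              co2_stats = if (length(co2))
                c(mean = mean(co2), min = min(co2), max = max(co2))
              else c(mean = NA_real_, min = NA_real_, max = NA_real_))
  if (!is.null(truth_stress) && !is.null(truth_control)) {
    ts <- in_win(truth_stress); tc <- in_win(truth_control)
    out$rh_diff_pct <- mean(ts$rh_pct) - mean(tc$rh_pct)
    out$vpd_stress_kPa <- mean(vpd_kPa(ts$temp_C, ts$rh_pct))
    out$vpd_control_kPa <- mean(vpd_kPa(tc$temp_C, tc$rh_pct))
  }
  structure(out, class = "env_summary")
}
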