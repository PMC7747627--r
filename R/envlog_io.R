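ENVLOG_HEADER <- c("timestamp", paste0("sensor_", 1:6), "tent_avg",
                   "co2_ppm", "heater_on", "health")

#' Write a controller log to CSV
#'
#' Canonical schema (header exact): `timestamp` (ISO-8601 minute
#' resolution, no offset), `sensor_1`..`sensor_6` (degC or the literal
#' `NA` for a failed read - the token, never an empty field, so the column
#' count is fixed), `tent_avg`, `co2_ppm`, `heater_on` (0/1), `health`.
#' Temperatures are written with 3 decimals and CO2 with 1, so a file
#' written by this function round-trips byte-identically through
#' [read_envlog()].
#'
#' @param log an `env_log` data.frame ([run_controller()] /
#'   [run_paired_nights()] output).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_envlog <- function(log, path) {
  sens <- grep("^sensor_", names(log), value = TRUE)
  assert_that(length(sens) == 6, "env log must carry sensor_1..sensor_6")
  fmt <- function(x, d) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = d))
  lines <- paste(
    format_tent_time(log$time),
    apply(vapply(sens, function(s) fmt(log[[s]], 3), character(nrow(log))),
          1, paste, collapse = ","),
    fmt(log$tent_avg, 3), fmt(log$co2_ppm, 1),
    as.integer(log$heater_on), log$health, sep = ",")
  writeLines(c(paste(ENVLOG_HEADER, collapse = ","), lines), path)
  invisible(path)
}

#' Read a controller log from CSV
#'
#' Validates the exact header, a fixed field count on every row (malformed
#' rows are rejected with their line numbers), and strictly increasing
#' timestamps.
#'
#' @param path CSV file path.
#' @return an `env_log` data.frame.
#' @export
read_envlog <- function(path) {
  raw <- readLines(path)
  assert_that(length(raw) >= 1, "empty file")
  hdr <- strsplit(raw[1], ",", fixed = TRUE)[[1]]
  if (!identical(hdr, ENVLOG_HEADER))
    stop("bad env log header; expected: ",
         paste(ENVLOG_HEADER, collapse = ","), call. = FALSE)
  nf <- lengths(strsplit(raw[-1], ",", fixed = TRUE))
  bad <- which(nf != length(ENVLOG_HEADER))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  if (length(raw) == 1L) return(empty_env_log(6))
  df <- utils::read.csv(text = raw, stringsAsFactors = FALSE,
                        na.strings = "NA",
                        colClasses = c("character", rep("numeric", 8),
                                       "integer", "character"))
  time <- tent_time(df$timestamp)
  if (any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  out <- data.frame(time = time, df[, paste0("sensor_", 1:6)],
                    tent_avg = df$tent_avg, co2_ppm = df$co2_ppm,
                    heater_on = df$heater_on == 1L, health = df$health,
                    stringsAsFactors = FALSE)
  structure(out, class = c("env_log", "data.frame"))
}

#' Write a trait observation table to CSV
#'
#' Schema: `genotype`, `treatment` (`control`/`HNT`), `tent`, `block`,
#' `trait`, `value`.
#'
#' @param obs trait observations data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(obs, path) {
  need <- c("genotype", "treatment", "tent", "block", "trait", "value")
  assert_that(all(need %in% names(obs)), "trait table is missing columns")
  utils::write.csv(obs[, need], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a trait observation table from CSV
#' @param path CSV file path.
#' @return trait observations data.frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "treatment", "tent", "block", "trait", "value")
  assert_that(all(need %in% names(df)),
              paste("trait table must have columns:", paste(need, collapse = ", ")))
  assert_that(all(df$treatment %in% c("control", "HNT")),
              "treatment must be 'control' or 'HNT'")
  assert_that(is.numeric(df$value) && all(is.finite(df$value)),
              "value must be finite numeric")
  df[need]
}
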