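#' Lumped thermal/moisture/CO2 parameters for one tent
#'
#' Each tent is a single well-mixed air node. Temperature relaxes toward
#' ambient at a first-order rate that depends on the vent state, and the
#' propane heater adds a constant warming rate while engaged, so with the
#' heater held on the steady-state elevation above ambient is
#' `q_heat / k_closed`. Defaults are calibrated so that (i) the heater is
#' non-limiting for a +4 degC setpoint (`q_heat / k_closed` >= 6 degC,
#' consistent with an 82,000 BTU/h unit in a 9.1 x 14.6 m tent), (ii) an
#' open tent tracks ambient within a small daytime bias, and (iii) closed
#' stress-tent CO2 drifts from ~457 ppm at closing toward a ~565 ppm
#' respiration/leak equilibrium.
#'
#' @param k_closed per-minute relaxation rate toward ambient, vents closed.
#' @param k_open per-minute relaxation rate, vents open (also used for the
#'   20-cm `control_gap` night setting, which circulates ambient air).
#' @param q_heat heater warming rate while engaged, degC/min.
#' @param day_bias_C mean daytime tent-minus-ambient offset with vents open,
#'   degC (greenhouse effect of the plastic skin).
#' @param rh_gain night RH elevation of a closed stress tent over ambient RH,
#'   percentage points (canopy transpiration source, lumped).
#' @param co2_base_ppm CO2 at tent closing / ambient reference, ppm.
#' @param co2_resp_ppm_per_min night respiration source, ppm/min.
#' @param co2_leak_per_min per-minute CO2 leak rate toward `co2_base_ppm`
#'   with vents closed (scaled up for gap/open states).
#' @return object of class `thermal_params`.
#' @export
thermal_params <- function(k_closed = 0.07, k_open = 0.5, q_heat = 0.5,
                           day_bias_C = 0.4, rh_gain = 15,
                           co2_base_ppm = 457, co2_resp_ppm_per_min = 1.08,
                           co2_leak_per_min = 0.01) {
  assert_that(k_closed >= 0 && k_open >= 0 && q_heat >= 0 &&
                co2_resp_ppm_per_min >= 0 && co2_leak_per_min >= 0,
              "all rates must be >= 0")
  assert_that(k_open > k_closed, "k_open must exceed k_closed")
  structure(list(k_closed = k_closed, k_open = k_open, q_heat = q_heat,
                 day_bias_C = day_bias_C, rh_gain = rh_gain,
                 co2_base_ppm = co2_base_ppm,
                 co2_resp_ppm_per_min = co2_resp_ppm_per_min,
                 co2_leak_per_min = co2_leak_per_min),
            class = "thermal_params")
}

VENT_STATES <- c("open", "control_gap", "closed")

#' Instantaneous simulated tent environment
#'
#' @param time timestamp (`POSIXct` or string).
#' @param temp_C true air temperature, degC.
#' @param rh_pct relative humidity, % in [0, 100].
#' @param co2_ppm CO2 concentration, ppm (> 0).
#' @param vent_state one of `"open"` (day setting), `"control_gap"` (night
#'   control tent: walls 20 cm above the baseboard), `"closed"` (night
#'   stress tent).
#' @param heater_on logical; only a closed tent may have the heater engaged.
#' @return object of class `tent_state`.
#' @export
tent_state <- function(time, temp_C, rh_pct, co2_ppm = 457,
                       vent_state = "open", heater_on = FALSE) {
  if (is.character(time)) time <- tent_time(time)
  assert_that(vent_state %in% VENT_STATES,
              paste("vent_state must be one of:", paste(VENT_STATES, collapse = ", ")))
  assert_that(rh_pct >= 0 && rh_pct <= 100, "rh_pct must lie in [0, 100]")
  assert_that(co2_ppm > 0, "co2_ppm must be > 0")
  assert_that(!(heater_on && vent_state != "closed"),
              "heater_on requires vent_state == 'closed'")
  structure(list(time = time, temp_C = temp_C, rh_pct = rh_pct,
                 co2_ppm = co2_ppm, vent_state = vent_state,
                 heater_on = heater_on),
            class = "tent_state")
}

#' Saturation vapor pressure (Magnus form, FAO-56 constants)
#'
#' `es(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa over liquid water.
#'
#' @param temp_C air temperature, degC.
#' @return saturation vapor pressure, kPa.
#' @export
svp_kPa <- function(temp_C) 0.6108 * exp(17.27 * temp_C / (temp_C + 237.3))

#' Advance one tent by one time step
#'
#' Explicit Euler update of the lumped model at the controller's one-minute
#' cadence: temperature relaxes toward ambient (+ daytime bias when open)
#' and gains `q_heat * dt` while the heater is engaged; vapor pressure
#' relaxes toward the ambient vapor pressure, or — in a closed tent — toward
#' ambient RH plus `rh_gain` points evaluated at tent temperature
#' (transpiration source); CO2 relaxes toward a respiration/leak
#' equilibrium at night and toward `co2_base_ppm` when open.
#'
#' @param state a [tent_state()].
#' @param ambient ambient conditions: numeric `c(temp_C =, rh_pct =)` or a
#'   list with those elements.
#' @param params a [thermal_params()].
#' @param heater_on logical command from the controller; physically
#'   effective only while `vent_state == "closed"`.
#' @param dt_min time step, minutes (> 0).
#' @return the updated [tent_state()] at `time + dt_min`.
#' @export
step_tent <- function(state, ambient, params, heater_on = state$heater_on,
                      dt_min = 1) {
  assert_that(inherits(state, "tent_state"), "state must be a tent_state")
  assert_that(inherits(params, "thermal_params"), "params must be thermal_params")
  assert_that(dt_min > 0, "dt_min must be > 0")
  if (!state$vent_state %in% VENT_STATES)
    stop("invalid vent_state: ", state$vent_state, call. = FALSE)
  t_amb <- as.numeric(ambient[["temp_C"]])
  rh_amb <- as.numeric(ambient[["rh_pct"]])

  closed <- state$vent_state == "closed"
  heat_eff <- isTRUE(heater_on) && closed
  k <- if (closed) params$k_closed else params$k_open
  bias <- if (state$vent_state == "open") params$day_bias_C else 0

  t_new <- state$temp_C +
    dt_min * (k * (t_amb + bias - state$temp_C) + params$q_heat * heat_eff)

  ## moisture: actual vapor pressure relaxes toward its target
  e <- svp_kPa(state$temp_C) * state$rh_pct / 100
  e_amb <- svp_kPa(t_amb) * rh_amb / 100
  e_target <- if (closed) {
    svp_kPa(state$temp_C) * min(100, rh_amb + params$rh_gain) / 100
  } else e_amb
  e_new <- e + dt_min * k * (e_target - e)
  rh_new <- min(100, max(0, 100 * e_new / svp_kPa(t_new)))

  ## CO2: respiration source at night, leak toward base
  leak <- params$co2_leak_per_min *
    switch(state$vent_state, closed = 1, control_gap = 3, open = 10)
  resp <- if (closed || state$vent_state == "control_gap")
    params$co2_resp_ppm_per_min else 0
  co2_new <- state$co2_ppm +
    dt_min * (resp - leak * (state$co2_ppm - params$co2_base_ppm))
  co2_new <- max(co2_new, 1)

  tent_state(time = state$time + 60 * dt_min, temp_C = t_new, rh_pct = rh_new,
             co2_ppm = co2_new, vent_state = state$vent_state,
             heater_on = heat_eff)
}
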