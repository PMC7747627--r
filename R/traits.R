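#' Percent difference of a treatment mean vs its control mean
#'
#' `100 * (mean_hnt - mean_control) / mean_control`, rounded half away from
#' zero to `digits` decimals (the convention of printed agronomy tables).
#'
#' @param mean_control control mean (non-zero).
#' @param mean_hnt treatment (HNT) mean.
#' @param digits decimals to round to; `NULL` for unrounded.
#' @return percent difference (negative = reduction under HNT).
#' @export
pct_difference <- function(mean_control, mean_hnt, digits = 2) {
  assert_that(all(mean_control != 0), "mean_control must be non-zero")
  out <- 100 * (mean_hnt - mean_control) / mean_control
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Normalize a percent reduction by the imposed temperature differential
#'
#' Converts a whole-treatment percent response into %/degC given the mean
#' stress-minus-control differential actually achieved. The differential is
#' a required explicit argument - it is never inferred from data silently.
#'
#' @param pct_reduction percent reduction (or response), %.
#' @param delta_T_C mean imposed differential, degC (> 0).
#' @param digits decimals to round to; `NULL` for unrounded.
#' @return %/degC.
#' @export
per_degC <- function(pct_reduction, delta_T_C, digits = 2) {
  assert_that(all(delta_T_C > 0), "delta_T_C must be > 0")
  out <- pct_reduction / delta_T_C
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Grain protein concentration from combustion nitrogen
#'
#' The standard cereal conversion: protein % = 5.7 x nitrogen %.
#'
#' @param n_pct nitrogen concentration, % by weight (>= 0).
#' @return protein concentration, %.
#' @export
protein_from_nitrogen <- function(n_pct) {
  assert_that(all(n_pct >= 0), "n_pct must be >= 0")
  5.7 * n_pct
}

#' A threshed seed sample split by Fusarium infection status
#'
#' @param n_infected,n_noninfected seed counts (>= 0).
#' @param wt_infected_g,wt_noninfected_g sample weights, g (>= 0).
#' @return object of class `seed_sample`.
#' @export
seed_sample <- function(n_infected, n_noninfected, wt_infected_g = 0,
                        wt_noninfected_g = 0) {
  assert_that(n_infected >= 0 && n_noninfected >= 0, "counts must be >= 0")
  assert_that(wt_infected_g >= 0 && wt_noninfected_g >= 0, "weights must be >= 0")
  structure(list(n_infected = n_infected, n_noninfected = n_noninfected,
                 wt_infected_g = wt_infected_g,
                 wt_noninfected_g = wt_noninfected_g),
            class = "seed_sample")
}

#' Extrapolate whole-sample weight from non-infected seed
#'
#' Average single-seed weight of the healthy (non-infected) fraction times
#' the total seed count - the correction that removes the weight penalty of
#' Fusarium-shriveled grain from yield-component estimates.
#'
#' @param sample a [seed_sample()] with `n_noninfected > 0`.
#' @param total_count total seeds in the harvested sample; defaults to
#'   `n_infected + n_noninfected` and must equal it when supplied.
#' @return extrapolated sample weight, g.
#' @export
extrapolate_noninfected <- function(sample,
                                    total_count = sample$n_infected +
                                      sample$n_noninfected) {
  assert_that(inherits(sample, "seed_sample"), "sample must be a seed_sample")
  if (sample$n_noninfected == 0)
    stop("extrapolation undefined: no non-infected seeds", call. = FALSE)
  assert_that(total_count == sample$n_infected + sample$n_noninfected,
              "total_count must equal n_infected + n_noninfected")
  (sample$wt_noninfected_g / sample$n_noninfected) * total_count
}

#' Harvest index
#'
#' Grain yield divided by total aboveground biomass (grain included).
#'
#' @param yield grain yield (any consistent unit, e.g. g/m^2).
#' @param biomass_total total aboveground biomass, same unit (> 0).
#' @return harvest index (dimensionless; in [0, 1] for consistent inputs).
#' @export
harvest_index <- function(yield, biomass_total) {
  assert_that(all(biomass_total > 0), "biomass_total must be > 0")
  yield / biomass_total
}

#' Grain-filling duration in days
#'
#' Days from 50% anthesis to physiological maturity (thumbnail-dent stage).
#'
#' @param anthesis_date,maturity_date `Date`s or `"YYYY-MM-DD"` strings.
#' @return duration, days.
#' @export
grain_filling_duration <- function(anthesis_date, maturity_date) {
  a <- as.Date(anthesis_date); m <- as.Date(maturity_date)
  assert_that(all(m >= a), "maturity must not precede anthesis")
  as.numeric(m - a)
}

#' Emergence percentage and emergence index
#'
#' From daily counts of newly emerged seedlings: total emergence % is the
#' final cumulative count over seeds planted; the emergence index defaults
#' to the speed-of-emergence form `sum(new_d / d)` over days after
#' planting, which weights early emergence more heavily (the commonly used
#' index when none is specified). The form is recorded in the output so
#' downstream tables are self-describing.
#'
#' @param daily_counts newly emerged seedlings per day (day 1, 2, ...).
#' @param n_planted seeds planted (> 0); 24 in a 3-row x 8-cell tray.
#' @param days day-after-planting of each count (default `1:length`).
#' @param index_form only `"speed"` is implemented; the argument exists so
#'   alternative index definitions slot in without schema changes.
#' @return list: `emergence_pct`, `emergence_index`, `index_form`.
#' @export
emergence_metrics <- function(daily_counts, n_planted,
                              days = seq_along(daily_counts),
                              index_form = "speed") {
  assert_that(n_planted > 0, "n_planted must be > 0")
  assert_that(all(daily_counts >= 0), "daily counts must be >= 0")
  assert_that(length(days) == length(daily_counts), "days/counts length mismatch")
  index_form <- match.arg(index_form)
  total <- sum(daily_counts)
  if (total > n_planted)
    stop("cumulative emergence exceeds seeds planted", call. = FALSE)
  list(emergence_pct = 100 * total / n_planted,
       emergence_index = sum(daily_counts / days),
       index_form = index_form)
}

#' Per-genotype and overall treatment summary of a trait table
#'
#' For one trait: per-genotype control and HNT means, their percent
#' difference, and - given the imposed differential - the %/degC statistic.
#' The overall row uses the mean of the per-genotype treatment means
#' (mean-of-means), matching how printed overall rows are computed; the
#' mean of the per-genotype percent differences is also reported as a
#' secondary statistic (`pct_diff_mean_of_pcts`).
#'
#' @param obs trait observations: data.frame with `genotype`, `treatment`
#'   (`"control"`/`"HNT"`), `trait`, `value` (replicates are averaged).
#' @param trait trait label to summarize.
#' @param delta_T_C optional mean imposed differential for %/degC.
#' @param digits decimals for the percent columns.
#' @return list of class `treatment_summary`: `by_genotype` data.frame,
#'   `overall` (means + `pct_diff`), `pct_diff_mean_of_pcts`, `per_degC`.
#' @export
treatment_summary <- function(obs, trait, delta_T_C = NULL, digits = 2) {
  d <- obs[obs$trait == trait, ]
  assert_that(nrow(d) > 0, paste("no observations for trait", trait))
  assert_that(all(d$treatment %in% c("control", "HNT")),
              "treatment must be 'control' or 'HNT'")
  gm <- aggregate(value ~ genotype + treatment, d, mean)
  wide <- merge(gm[gm$treatment == "control", c("genotype", "value")],
                gm[gm$treatment == "HNT", c("genotype", "value")],
                by = "genotype", suffixes = c("_control", "_hnt"))
  names(wide) <- c("genotype", "mean_control", "mean_hnt")
  wide$pct_diff <- pct_difference(wide$mean_control, wide$mean_hnt, digits)
  mc <- mean(wide$mean_control); mh <- mean(wide$mean_hnt)
  overall_pct <- pct_difference(mc, mh, digits)
  out <- list(trait = trait,
              by_genotype = wide,
              overall = c(mean_control = round_half_up(mc, digits),
                          mean_hnt = round_half_up(mh, digits),
                          pct_diff = overall_pct),
              pct_diff_mean_of_pcts = round_half_up(mean(
                pct_difference(wide$mean_control, wide$mean_hnt, NULL)), digits))
  if (!is.null(delta_T_C))
    out$per_degC <- per_degC(abs(overall_pct), delta_T_C)
  structure(out, class = "treatment_summary")
}
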