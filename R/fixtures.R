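## Packaged fixtures: the published per-genotype starch/protein table and
## the main-effect means table, transcribed once and checksummed so any
## accidental edit fails loudly.

FIXTURE_MD5 <- c(
  "table3_starch_protein.csv" = "369112b796e16432e31fd75f52bcf020",
  "table3_overall.csv"        = "630407c0016e0c0379aec6bfbb2e1cb0",
  "table2_means.csv"          = "33550eae511fa995b3ba41655fc7e982")

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "heattent")
  if (p == "") p <- file.path("inst", "extdata", file)   # pre-install use
  assert_that(file.exists(p), paste("fixture not found:", file))
  got <- unname(tools::md5sum(p))
  assert_that(identical(got, unname(FIXTURE_MD5[[file]])),
              paste0("fixture ", file, " fails its checksum (edited?)"))
  p
}

#' Per-genotype grain starch and protein fixture
#'
#' Starch and protein concentration (%) of mature seed for the 12-genotype
#' panel under control and HNT conditions, with the percent-difference
#' column as printed.
#'
#' @return data.frame: `genotype`, `trait` (`starch_pct`/`protein_pct`),
#'   `control`, `hnt`, `printed_pct_diff`.
#' @export
load_table3 <- function() {
  utils::read.csv(fixture_path("table3_starch_protein.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Printed overall-average row of the starch/protein table
#' @return data.frame with the overall control/HNT means, percent
#'   difference and Tukey letters for both traits.
#' @export
load_table3_overall <- function() {
  utils::read.csv(fixture_path("table3_overall.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Main-effect means and ANOVA p-values fixture
#'
#' Season main-effect means (control vs HNT) with Tukey letters and the
#' printed p-values for temperature, genotype and their interaction, for
#' the eight reported traits. p-value columns are kept as printed strings
#' (some are `"<0.001"`).
#'
#' @return data.frame: `trait`, `unit`, `p_T`, `p_G`, `p_TxG`,
#'   `mean_control`, `mean_hnt`, `letter_control`, `letter_hnt`.
#' @export
load_table2 <- function() {
  utils::read.csv(fixture_path("table2_means.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(p_T = "character", p_G = "character",
                                 p_TxG = "character"))
}

#' Recompute the starch/protein percent differences from the fixture
#'
#' Runs [pct_difference()] on every genotype row and on the overall
#' (mean-of-means) row of both traits and compares against the printed
#' values. Rows whose printed value matches the 2-decimal recomputation
#' exactly get status `"exact"`; rows where the published table evidently
#' used unrounded raw means (printed value within `approx_tol` of the
#' recomputation) get `"approx"`; anything further is `"fail"`.
#'
#' @param approx_tol tolerance for the `"approx"` status.
#' @return list of class `table3_reproduction`: `by_genotype` (computed vs
#'   printed with `status`), `overall` (same for the overall rows, plus
#'   recomputed means), `all_pass` (no `"fail"` anywhere).
#' @export
reproduce_table3 <- function(approx_tol = 0.1) {
  t3 <- load_table3()
  ov <- load_table3_overall()
  t3$computed_pct_diff <- pct_difference(t3$control, t3$hnt)
  t3$abs_err <- abs(t3$computed_pct_diff - t3$printed_pct_diff)
  t3$status <- ifelse(t3$abs_err == 0, "exact",
                      ifelse(t3$abs_err <= approx_tol, "approx", "fail"))

  ov_rows <- lapply(seq_len(nrow(ov)), function(i) {
    rows <- t3[t3$trait == ov$trait[i], ]
    mc <- round_half_up(mean(rows$control), 2)
    mh <- round_half_up(mean(rows$hnt), 2)
    pd <- pct_difference(mean(rows$control), mean(rows$hnt))
    data.frame(trait = ov$trait[i],
               computed_control = mc, printed_control = ov$control[i],
               computed_hnt = mh, printed_hnt = ov$hnt[i],
               computed_pct_diff = pd, printed_pct_diff = ov$printed_pct_diff[i],
               stringsAsFactors = FALSE)
  })
  overall <- do.call(rbind, ov_rows)
  overall$abs_err <- abs(overall$computed_pct_diff - overall$printed_pct_diff)
  overall$means_match <- overall$computed_control == overall$printed_control &
    overall$computed_hnt == overall$printed_hnt
  overall$status <- ifelse(overall$abs_err == 0 & overall$means_match, "exact",
                           ifelse(overall$abs_err <= approx_tol, "approx", "fail"))
  structure(list(by_genotype = t3, overall = overall,
                 all_pass = !any(c(t3$status, overall$status) == "fail")),
            class = "table3_reproduction")
}
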