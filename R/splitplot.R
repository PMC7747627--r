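#' Split-plot ANOVA for the paired-tent trait design
#'
#' Temperature is the whole-plot factor (applied to entire tents) and
#' genotype the sub-plot factor randomized within tents, so temperature is
#' tested against the tent-within-treatment stratum and genotype and the
#' interaction against the sub-plot residual. Observations are first
#' averaged to one value per genotype x treatment x tent (check-line
#' genotypes contribute their tent mean), and the design must then be
#' balanced. Main-effect means carry compact Tukey HSD letters at
#' `alpha`: temperature letters use the whole-plot error, genotype letters
#' the residual.
#'
#' Implemented from the balanced sums of squares directly (not via
#' [stats::aov()]) so thousands of simulated fits stay cheap; the aov
#' route is used as an independent cross-check in the test suite.
#'
#' @param obs trait observations: data.frame with `genotype`, `treatment`
#'   (`"control"`/`"HNT"`), `tent` (pair id, 1..r), `trait`, `value`.
#' @param trait trait label to analyze.
#' @param alpha significance level for the Tukey letters.
#' @return list of class `anova_result`: `p_T`, `p_G`, `p_TxG`, F values,
#'   the ANOVA table, and `means_T`, `means_G` data.frames with `letter`.
#' @export
splitplot_anova <- function(obs, trait, alpha = 0.05) {
  d <- obs[obs$trait == trait, c("genotype", "treatment", "tent", "value")]
  assert_that(nrow(d) > 0, paste("no observations for trait", trait))
  d <- aggregate(value ~ genotype + treatment + tent, d, mean)
  d$treatment <- factor(d$treatment, levels = c("control", "HNT"))
  d$genotype <- factor(d$genotype)
  d$tent <- factor(d$tent)
  g <- nlevels(d$genotype); r <- nlevels(d$tent); ntr <- nlevels(d$treatment)
  if (r < 2) stop("main-plot test undefined with a single tent per treatment",
                  call. = FALSE)
  assert_that(nrow(d) == g * r * ntr,
              "design must be balanced: one mean per genotype x treatment x tent")

  y <- d$value
  grand <- mean(y)
  mt <- tapply(y, d$treatment, mean)                     # treatment means
  mg <- tapply(y, d$genotype, mean)                      # genotype means
  mtg <- tapply(y, list(d$treatment, d$genotype), mean)  # cell means
  mwp <- tapply(y, list(d$treatment, d$tent), mean)      # whole-plot means

  ss_total <- sum((y - grand)^2)
  ss_T <- r * g * sum((mt - grand)^2)
  ss_wp <- g * sum((mwp - grand)^2)                      # among whole plots
  ss_wpe <- ss_wp - ss_T
  ss_G <- ntr * r * sum((mg - grand)^2)
  inter <- sweep(sweep(mtg, 1, mt), 2, mg) + grand
  ss_TxG <- r * sum(inter^2)
  ss_res <- ss_total - ss_wp - ss_G - ss_TxG

  df_T <- ntr - 1L
  df_wpe <- ntr * (r - 1L)
  df_G <- g - 1L
  df_TxG <- df_T * df_G
  df_res <- ntr * (r - 1L) * (g - 1L)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_wpe <- ms(ss_wpe, df_wpe); ms_res <- ms(ss_res, df_res)
  f_T <- ms(ss_T, df_T) / ms_wpe
  f_G <- ms(ss_G, df_G) / ms_res
  f_TxG <- ms(ss_TxG, df_TxG) / ms_res
  p_T <- stats::pf(f_T, df_T, df_wpe, lower.tail = FALSE)
  p_G <- stats::pf(f_G, df_G, df_res, lower.tail = FALSE)
  p_TxG <- stats::pf(f_TxG, df_TxG, df_res, lower.tail = FALSE)

  tab <- data.frame(
    term = c("temperature", "tent(temperature)", "genotype",
             "temperature:genotype", "residual"),
    df = c(df_T, df_wpe, df_G, df_TxG, df_res),
    ss = c(ss_T, ss_wpe, ss_G, ss_TxG, ss_res),
    F = c(f_T, NA, f_G, f_TxG, NA),
    p = c(p_T, NA, p_G, p_TxG, NA))

  means_T <- data.frame(level = names(mt), mean = as.numeric(mt))
  means_T$letter <- tukey_letters(means_T$mean, ms_wpe, df_wpe, n_per = r * g,
                                  alpha = alpha)
  means_G <- data.frame(level = names(mg), mean = as.numeric(mg))
  means_G$letter <- tukey_letters(means_G$mean, ms_res, df_res, n_per = ntr * r,
                                  alpha = alpha)

  structure(list(trait = trait, p_T = p_T, p_G = p_G, p_TxG = p_TxG,
                 F_T = f_T, F_G = f_G, F_TxG = f_TxG, table = tab,
                 means_T = means_T, means_G = means_G, alpha = alpha),
            class = "anova_result")
}

#' Compact letter display from Tukey HSD on balanced means
#'
#' With a common error mean square and equal replication, two means differ
#' at level `alpha` iff their absolute difference exceeds
#' `HSD = qtukey(1 - alpha, k, df) * sqrt(MSE / n_per)`. Because the
#' threshold is a single constant, letter groups are exactly the maximal
#' windows of the sorted means whose span is below the HSD; groups are
#' lettered `a`, `b`, ... from the largest mean downward (ties broken by
#' the sorted order, i.e. alphabetically within equal means).
#'
#' @param means numeric vector of level means.
#' @param mse error mean square of the appropriate stratum.
#' @param df its degrees of freedom.
#' @param n_per replicates behind each mean.
#' @param alpha significance level.
#' @return character vector of letter groups, parallel to `means`.
#' @export
tukey_letters <- function(means, mse, df, n_per, alpha = 0.05) {
  k <- length(means)
  if (k == 1L) return("a")
  if (!is.finite(mse) || df <= 0) return(rep(NA_character_, k))
  hsd <- stats::qtukey(1 - alpha, k, df) * sqrt(mse / n_per)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  ## j_end[i]: furthest sorted index still not separated from mean i; the
  ## letter groups are the maximal windows [i, j_end[i]]
  j_end <- vapply(seq_len(k), function(i) max(which(m[i] - m < hsd)), integer(1))
  starts <- which(c(TRUE, diff(j_end) > 0))
  lab <- rep("", k)
  for (w in seq_along(starts)) {
    rng <- starts[w]:j_end[starts[w]]
    lab[rng] <- paste0(lab[rng], letters[w])
  }
  out <- character(k)
  out[ord] <- lab
  out
}

#' Check-line spatial uniformity test
#'
#' Within each tent, rows of the check genotype are grouped by position
#' (blocks 1-4 vs 5-8) and a one-way ANOVA between the two groups is run
#' per trait. A non-significant p-value at `alpha` in every tent supports
#' spatially uniform stress imposition.
#'
#' @param obs trait observations including the check genotype in all 8
#'   blocks of each tent (`genotype`, `treatment`, `tent`, `block`,
#'   `trait`, `value`).
#' @param check_genotype label of the check line.
#' @param traits traits to test; default all traits present for the check.
#' @param alpha significance level of the verdict.
#' @return data.frame of class `checkline_report`: `treatment`, `tent`,
#'   `trait`, `F`, `p`, `uniform` (logical). Tents with missing blocks are
#'   skipped with a warning.
#' @export
checkline_uniformity <- function(obs, check_genotype = "Everest",
                                 traits = NULL, alpha = 0.05) {
  d <- obs[obs$genotype == check_genotype, ]
  assert_that(nrow(d) > 0, paste("no observations for check genotype",
                                 check_genotype))
  if (is.null(traits)) traits <- unique(d$trait)
  out <- list()
  for (tr in traits) {
    dt <- d[d$trait == tr, ]
    for (trt in unique(dt$treatment)) for (tent in sort(unique(dt$tent))) {
      cell <- dt[dt$treatment == trt & dt$tent == tent, ]
      if (!all(1:8 %in% cell$block)) {
        warning(sprintf("skipping %s tent %s (%s): blocks missing",
                        trt, tent, tr), call. = FALSE)
        next
      }
      grp <- cell$block <= 4
      f <- oneway_F(cell$value, grp)
      out[[length(out) + 1L]] <-
        data.frame(treatment = trt, tent = tent, trait = tr,
                   F = f$F, p = f$p, uniform = f$p >= alpha,
                   stringsAsFactors = FALSE)
    }
  }
  assert_that(length(out) > 0, "no testable tents")
  structure(do.call(rbind, out), class = c("checkline_report", "data.frame"))
}

## one-way ANOVA F test for a two-level grouping
oneway_F <- function(y, grp) {
  m1 <- mean(y[grp]); m2 <- mean(y[!grp]); grand <- mean(y)
  n1 <- sum(grp); n2 <- sum(!grp)
  ss_b <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ss_w <- sum((y[grp] - m1)^2) + sum((y[!grp] - m2)^2)
  df_b <- 1L; df_w <- n1 + n2 - 2L
  F <- (ss_b / df_b) / (ss_w / df_w)
  list(F = F, p = stats::pf(F, df_b, df_w, lower.tail = FALSE))
}
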