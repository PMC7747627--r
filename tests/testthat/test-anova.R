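## one-trait effect config for fast simulated datasets
eff1 <- function(effect = 0, control_mean = 500, genotype_cv = 0.10,
                 tent_cv = 0.03, resid_cv = 0.08, trait = "yield") {
  data.frame(trait = trait, control_mean = control_mean, effect_pct = effect,
             genotype_cv = genotype_cv, tent_cv = tent_cv,
             resid_cv = resid_cv, stringsAsFactors = FALSE)
}

test_that("split-plot strata match the aov oracle", {
  obs <- generate_trait_data(eff1(effect = -15), seed = 101)
  a <- splitplot_anova(obs, "yield")
  d <- aggregate(value ~ genotype + treatment + tent,
                 obs[obs$trait == "yield", ], mean)
  d$wp <- interaction(d$treatment, d$tent)
  fit <- summary(stats::aov(value ~ treatment * genotype + Error(wp), data = d))
  wp_tab <- fit[["Error: wp"]][[1]]
  wi_tab <- fit[["Error: Within"]][[1]]
  expect_equal(a$p_T, wp_tab["treatment", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(a$p_G, wi_tab["genotype", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(a$p_TxG, wi_tab["treatment:genotype", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(a$F_T, wp_tab["treatment", "F value"], tolerance = 1e-10)
})

test_that("identical treatment groups share a Tukey letter; strong effects split", {
  base <- generate_trait_data(eff1(effect = 0, tent_cv = 0.01, resid_cv = 0.02),
                              seed = 5)
  a0 <- splitplot_anova(base, "yield")
  expect_identical(a0$means_T$letter, c("a", "a"))
  big <- generate_trait_data(eff1(effect = -40, tent_cv = 0.01, resid_cv = 0.02),
                             seed = 5)
  a1 <- splitplot_anova(big, "yield")
  expect_identical(sort(a1$means_T$letter), c("a", "b"))
  expect_lt(a1$p_T, 0.05)
})

test_that("degenerate designs are rejected", {
  obs <- generate_trait_data(eff1(), seed = 1, n_tents = 1)
  expect_error(splitplot_anova(obs, "yield"), "single tent")
  expect_error(splitplot_anova(obs, "nope"), "no observations")
})

test_that("tukey_letters groups maximal non-significant windows", {
  ## HSD = qtukey(.95, 3, 10) * sqrt(1 / 5); means 10, 9.9, 0 -> top two share
  hsd <- qtukey(0.95, 3, 10) * sqrt(1 / 5)
  lt <- tukey_letters(c(10, 9.9, 0), mse = 1, df = 10, n_per = 5)
  expect_identical(lt, c("a", "a", "b"))
  ## chain a > b > c with all pairs separated
  lt2 <- tukey_letters(c(0, 2 * hsd + 0.2, 4 * hsd + 0.4), 1, 10, 5)
  expect_identical(lt2, c("c", "b", "a"))
  ## overlapping chain: middle shares with both ends
  lt3 <- tukey_letters(c(0, 0.8 * hsd, 1.6 * hsd), 1, 10, 5)
  expect_identical(lt3, c("b", "ab", "a"))
  expect_identical(tukey_letters(5, 1, 10, 5), "a")
})

test_that("check-line uniformity: null, forced separation, missing blocks", {
  ## both positional groups hold the same values -> F = 0, p = 1, uniform
  flat <- expand.grid(treatment = c("control", "HNT"), tent = 1:3,
                      block = 1:8, stringsAsFactors = FALSE)
  flat$genotype <- "Everest"; flat$trait <- "yield"
  flat$value <- rep_len(c(1, 2, 3, 4), nrow(flat))   # blocks 1-4 mirror 5-8
  rep0 <- checkline_uniformity(flat, "Everest")
  expect_identical(nrow(rep0), 6L)          # 2 treatments x 3 tents
  expect_true(all(rep0$uniform))
  expect_true(all(rep0$p > 0.99))
  ## group means 5 within-group SDs apart, n = 4 per group
  set.seed(33)
  sdw <- 1
  vals <- c(rnorm(4, 0, sdw), rnorm(4, 5 * sdw, sdw))
  one <- data.frame(genotype = "Everest", treatment = "control", tent = 1,
                    block = 1:8, trait = "yield", value = vals)
  rep1 <- checkline_uniformity(one, "Everest")
  expect_lt(rep1$p, 0.05)
  ## direct-F oracle
  g <- rep(c(TRUE, FALSE), each = 4)
  f_oracle <- anova(lm(vals ~ g))[1, c("F value", "Pr(>F)")]
  expect_equal(rep1$F, f_oracle[[1]], tolerance = 1e-10)
  expect_equal(rep1$p, f_oracle[[2]], tolerance = 1e-10)
  ## a tent with missing blocks is skipped with a warning, others survive
  two <- rbind(one, transform(one, tent = 2))
  expect_warning(rep2 <- checkline_uniformity(two[-1, ], "Everest"),
                 "blocks missing")
  expect_identical(rep2$tent, 2)
})

test_that("check-line false-alarm rate sits near alpha under the null", {
  reps <- 200
  hits <- 0L
  for (i in seq_len(reps)) {
    obs <- generate_trait_data(eff1(), seed = 1000 + i, n_tents = 1)
    rep <- checkline_uniformity(obs, "Everest", alpha = 0.05)
    hits <- hits + sum(!rep$uniform)
  }
  n_tests <- reps * 2L                      # 2 treatments x 1 tent each
  rate <- hits / n_tests
  ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(rate, ci[1]); expect_lt(rate, ci[2])
})
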