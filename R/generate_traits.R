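#' Default effect configuration for the synthetic trait generator
#'
#' One row per trait: the control-condition grand mean, the HNT treatment
#' effect as a percent change of the control mean, and the three variance
#' components as coefficients of variation relative to the control mean
#' (genotype spread of true genotype means, between-tent SD within a
#' treatment, and residual row-to-row SD). Control means and effects are
#' calibrated to the season's main-effect means (see the packaged
#' `table2_means` fixture); the CVs are fixed at values typical of
#' replicated wheat field trials: genotypes differ by ~10%, tents are a
#' well-controlled ~3%, and single 0.5-m row samples carry ~8% residual
#' noise.
#'
#' @return data.frame with columns `trait`, `control_mean`, `effect_pct`,
#'   `genotype_cv`, `tent_cv`, `resid_cv`.
#' @export
default_trait_effects <- function() {
  t2 <- load_table2()
  eff <- pct_difference(t2$mean_control, t2$mean_hnt, digits = NULL)
  data.frame(trait = t2$trait,
             control_mean = t2$mean_control,
             effect_pct = eff,
             genotype_cv = 0.10, tent_cv = 0.03, resid_cv = 0.08,
             stringsAsFactors = FALSE)
}

#' Panel genotype labels (12 winter wheat entries; Everest is the check)
#' @return character vector of length 12.
#' @export
panel_genotypes <- function() {
  c("Everest", "Jagger X060724", "KS 070736K-1", "KS 070729K-26",
    "KS 070717M-1", "Larry", "P1 X060725", "SY-Monument", "Tascosa",
    "Tx86A5606", "WB 4458", "WB-Cedar")
}

#' Generate replicate-level synthetic trait observations
#'
#' Emulates the field layout: 12 genotypes x 2 treatments (control, HNT) x
#' `n_tents` tent pairs. Eleven genotypes contribute one row per tent
#' (random block 1-8); the check genotype contributes one row in every one
#' of the 8 blocks of every tent, enabling the positional uniformity test.
#' The generative model per trait is
#' `value = control_mean * (1 + effect/100 * I(HNT)) * (1 + gamma_g) +
#'  tau_tent + eps`, with `gamma_g ~ N(0, genotype_cv)`,
#' `tau ~ N(0, tent_cv * control_mean)` drawn per tent x treatment, and
#' `eps ~ N(0, resid_cv * control_mean)` per row. Deterministic under
#' `seed`.
#'
#' @param effects effect configuration as from [default_trait_effects()]
#'   (any subset of rows / custom traits is fine).
#' @param seed integer RNG seed.
#' @param genotypes genotype labels; the first listed check is replicated.
#' @param check_genotype label replicated in all 8 blocks.
#' @param n_tents tent pairs per treatment.
#' @param n_blocks blocks per tent.
#' @return data.frame of trait observations (`genotype`, `treatment`,
#'   `tent`, `block`, `trait`, `value`) with attribute `effects`.
#' @export
generate_trait_data <- function(effects = default_trait_effects(), seed = 1,
                                genotypes = panel_genotypes(),
                                check_genotype = "Everest",
                                n_tents = 3, n_blocks = 8) {
  assert_that(all(c("trait", "control_mean", "effect_pct", "genotype_cv",
                    "tent_cv", "resid_cv") %in% names(effects)),
              "effects is missing required columns")
  assert_that(all(effects$genotype_cv >= 0 & effects$tent_cv >= 0 &
                    effects$resid_cv >= 0), "CVs must be >= 0")
  set.seed(as.integer(seed))
  treatments <- c("control", "HNT")
  is_check <- genotypes == check_genotype
  ## one row per genotype per tent, except the check line in every block
  reps <- ifelse(is_check, n_blocks, 1L)
  cell <- expand.grid(genotype = genotypes, tent = seq_len(n_tents),
                      treatment = treatments, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cell)), times = reps[match(cell$genotype, genotypes)])
  out <- vector("list", nrow(effects))
  for (k in seq_len(nrow(effects))) {
    cfg <- effects[k, ]
    gamma <- stats::rnorm(length(genotypes), 0, cfg$genotype_cv)
    tau <- stats::rnorm(2L * n_tents, 0, cfg$tent_cv * cfg$control_mean)
    d <- cell[idx, ]
    chk <- d$genotype == check_genotype
    d$block <- NA_integer_
    d$block[chk] <- rep_len(seq_len(n_blocks), sum(chk))
    d$block[!chk] <- sample.int(n_blocks, sum(!chk), replace = TRUE)
    mu <- cfg$control_mean * (1 + cfg$effect_pct / 100 * (d$treatment == "HNT"))
    tau_i <- tau[(match(d$treatment, treatments) - 1L) * n_tents + d$tent]
    eps <- stats::rnorm(nrow(d), 0, cfg$resid_cv * cfg$control_mean)
    d$trait <- cfg$trait
    d$value <- mu * (1 + gamma[match(d$genotype, genotypes)]) + tau_i + eps
    out[[k]] <- d[, c("genotype", "treatment", "tent", "block", "trait", "value")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "effects") <- effects
  res
}
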