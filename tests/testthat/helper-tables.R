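## deterministic balanced table built in code: value = base(trait) scaled by
## genotype and treatment multipliers plus a small replicate offset
balanced_table <- function(n_g = 5, traits = c("RL", "SL", "TDW"), reps = 3,
                           treatments = c("T0", "T1", "T2")) {
  base <- c(DSG = 6, NOL = 4, TFW = 0.6, TDW = 0.17, SR = 0.7, NSR = 18,
            RL = 6, SL = 8, RFW = 0.05, Chla = 4, Chlb = 3, TChl = 7,
            CAR = 2, Pro = 6, MDA = 2, H2O2 = 12)
  tr_mult <- c(T0 = 1, T1 = 0.9, T2 = 0.75)
  grid <- expand.grid(genotype = paste0("G", seq_len(n_g)),
                      treatment = treatments, replicate = seq_len(reps),
                      trait = traits, stringsAsFactors = FALSE)
  g_i <- as.integer(sub("G", "", grid$genotype))
  v <- base[grid$trait] * tr_mult[grid$treatment] *
    (1 + 0.1 * g_i) + 0.01 * grid$replicate
  grid$value <- ifelse(grid$trait %in% c("DSG", "NOL", "NSR"), round(v),
                       ifelse(grid$trait == "SR", pmin(v, 1), v))
  trait_table(grid)
}

## standard error of the per-treatment sample mean under the generator's
## variance components: genotype and interaction effects are shared within
## genotype, so the mean does not converge at the iid rate
se_cohort_mean <- function(sigma, n_g, reps,
                           vp = c(genotype = 0.4, interaction = 0.2,
                                  residual = 0.4)) {
  sigma * sqrt(vp[["genotype"]] / n_g + vp[["interaction"]] / n_g +
               vp[["residual"]] / (n_g * reps))
}

## small default synthetic cohort shared across tests
default_cohort <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config(), seed = seed)
    cache
  }
})
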