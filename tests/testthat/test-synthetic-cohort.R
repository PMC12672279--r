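test_that("configuration is validated", {
  expect_error(cohort_config(n_genotypes = 1), "n_genotypes")
  expect_error(cohort_config(variance_partition = c(genotype = 0.5,
                                                    interaction = 0.5,
                                                    residual = 0.5)),
               "summing to 1")
  expect_error(cohort_config(cross_trait_correlation = 1), "correlation")
  ## a trait without a summary row cannot be calibrated
  summ <- published_descriptives()
  expect_error(cohort_config(summaries = summ[summ$trait != "RL", ],
                             traits = c("RL", "SL")),
               "calibration error")
  cfg <- cohort_config()
  expect_error(inject_archetypes(cfg, c("G1", "G2"), c("G2", "G3"), 2),
               "overlap")
  expect_error(inject_archetypes(cfg, "G99", "G1", 2), "unknown genotype")
  expect_error(generate_cohort(cfg), "seed")
})

test_that("generation is deterministic and respects family constraints", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- generate_cohort(cfg, seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))

  for (tr in c("DSG", "NOL", "NSR")) {
    v <- a$value[a$trait == tr]
    expect_true(all(v >= 0 & v == round(v)))
  }
  expect_true(all(a$value[a$trait == "SR"] >= 0 & a$value[a$trait == "SR"] <= 1))
  expect_true(all(a$value >= 0))
  ## ratio trait equals generated RL / SL cell by cell
  key <- function(d) paste(d$genotype, d$treatment, d$replicate)
  rl <- a[a$trait == "RL", ]; sl <- a[a$trait == "SL", ]
  rs <- a[a$trait == "R/S", ]
  sl <- sl[match(key(rl), key(sl)), ]
  rs <- rs[match(key(rl), key(rs)), ]
  expect_equal(rs$value, rl$value / sl$value, tolerance = 1e-12)
})

test_that("degenerate variance partitions behave as specified", {
  summ <- published_descriptives()
  ## all variance between genotypes: replicates identical
  cfg1 <- cohort_config(summaries = summ, n_genotypes = 6, traits = "RL",
                        variance_partition = c(genotype = 1, interaction = 0,
                                               residual = 0))
  t1 <- generate_cohort(cfg1, seed = 1)
  spread <- tapply(t1$value, paste(t1$genotype, t1$treatment),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))

  ## pure-noise model: genotype effects vanish, so genotype means are
  ## exchangeable; their variance shrinks by ~1/replicates
  cfg2 <- cohort_config(summaries = summ, n_genotypes = 200, traits = "RL",
                        replicates = 4,
                        variance_partition = c(genotype = 0, interaction = 0,
                                               residual = 1))
  t2 <- generate_cohort(cfg2, seed = 2)
  gm <- tapply(t2$value[t2$treatment == "T0"],
               t2$genotype[t2$treatment == "T0"], mean)
  target_sd <- summ$sd[summ$trait == "RL" & summ$treatment == "T0"]
  expect_lt(sd(gm), target_sd * 0.75)   # far below the full between-genotype SD
})

test_that("marginal means and SDs are calibrated to the target table", {
  ## the published severe-stress germination target, default design
  tab <- generate_cohort(cohort_config(traits = c("DSG", "RL", "SL")), seed = 1)
  v <- tab$value[tab$trait == "DSG" & tab$treatment == "T2"]
  expect_equal(length(v), 111L)   # 37 genotypes x 3 replicates per treatment
  expect_lt(abs(mean(v) - 12.05), 3 * se_cohort_mean(1.736, 37, 3))

  ## large-replication check: n ~ 10^4 draws per treatment
  cfg <- cohort_config(traits = "DSG", replicates = 90)
  big <- generate_cohort(cfg, seed = 3)
  v2 <- big$value[big$treatment == "T2"]
  expect_equal(length(v2), 37L * 90L)
  expect_lt(abs(mean(v2) - 12.05), 3 * se_cohort_mean(1.736, 37, 90))
  expect_lt(abs(sd(v2) - 1.736), 0.25)

  ## a wide panel pins the mean much more tightly
  wide <- generate_cohort(cohort_config(traits = "DSG", n_genotypes = 1000),
                          seed = 4)
  v3 <- wide$value[wide$treatment == "T2"]
  expect_lt(abs(mean(v3) - 12.05), 3 * se_cohort_mean(1.736, 1000, 3))
})

test_that("cross-trait correlation of genotype means hits the target", {
  traits <- c("TFW", "TDW", "RL", "RFW")
  cfg <- cohort_config(n_genotypes = 1000, traits = traits)
  tab <- generate_cohort(cfg, seed = 11)
  cm <- correlation_by_treatment(tab, traits, "T0")
  off <- cm$r[upper.tri(cm$r)]
  expect_true(all(abs(off - 0.7) < 0.05))

  ## at the study's own panel size the estimate is noisier
  cfg2 <- cohort_config(n_genotypes = 37, traits = traits)
  tab2 <- generate_cohort(cfg2, seed = 12)
  off2 <- correlation_by_treatment(tab2, traits, "T0")$r
  expect_true(all(abs(off2[upper.tri(off2)] - 0.7) < 0.15))
})

test_that("archetype injection shifts stress means in the favourable direction", {
  tol <- c("G1", "G2"); sus <- c("G3", "G4")
  cfg0 <- cohort_config(n_genotypes = 12, traits = c("TDW", "DSG"))
  cfg <- inject_archetypes(cfg0, tol, sus, shift = 3)
  tab <- generate_cohort(cfg, seed = 5)

  m <- function(tr, lev, who) mean(tab$value[tab$trait == tr &
                                             tab$treatment == lev &
                                             tab$genotype %in% who])
  others <- paste0("G", 5:12)
  ## higher-is-better trait: tolerant up, susceptible down, under stress only
  expect_gt(m("TDW", "T2", tol), m("TDW", "T2", others))
  expect_lt(m("TDW", "T2", sus), m("TDW", "T2", others))
  ## lower-is-better trait shifts the other way for tolerant genotypes
  expect_lt(m("DSG", "T2", tol), m("DSG", "T2", others))

  ## shift 0 leaves the configuration's output unchanged
  cfg_zero <- inject_archetypes(cfg0, tol, sus, shift = 0)
  expect_identical(as.data.frame(generate_cohort(cfg_zero, seed = 6)),
                   as.data.frame(generate_cohort(cfg0, seed = 6)))
})

test_that("cross-trait correlation is what limits archetype recovery by scoring", {
  ## with independent traits, a 2-SD stress shift puts the injected
  ## tolerant genotypes into the top four overall scores almost always;
  ## with the default correlation, shared genotype factors create
  ## across-the-board-superior genotypes that defeat recovery
  tol_ids <- c("G2", "G7", "G20", "G30")
  sus_ids <- c("G5", "G11", "G25", "G33")
  rate <- function(rho, n_seeds = 30) {
    cfg <- inject_archetypes(cohort_config(cross_trait_correlation = rho),
                             tol_ids, sus_ids, shift = 2)
    hits <- vapply(seq_len(n_seeds), function(s) {
      rk <- rank_genotypes(score_card(generate_cohort(cfg, seed = 5000 + s)))
      all(tol_ids %in% rk$genotype[1:4])
    }, TRUE)
    mean(hits)
  }
  expect_gte(rate(0), 0.9)
  expect_lt(rate(0.7), 0.7)
})

test_that("the default generator produces the significance pattern the design assumes", {
  ## genotype and interaction terms highly significant in most seeds
  hits <- 0L
  for (s in 1:10) {
    tab <- generate_cohort(cohort_config(traits = "RL"), seed = 100 + s)
    a <- anova_trait(tab, "RL")
    hits <- hits + (a$p[1] < 0.001 && a$p[4] < 0.001)
  }
  expect_gte(hits, 9L)
})
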