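test_that("index definitions reduce correctly in degenerate cases", {
  v <- compute_indices(1, 1, xc = 1, xt = 0.5)
  expect_equal(unlist(v),
               c(ssi = 0, mpi = 1, gmpi = 1, hmi = 1, sti = 1, ti = 0, si = 1))

  z <- compute_indices(1, 0, xc = 1, xt = 0.5)
  expect_equal(unlist(z),
               c(ssi = 2, mpi = 0.5, gmpi = 0, hmi = 0, sti = 0, ti = 1, si = 0))

  expect_error(compute_indices(0, 1, 1, 0.5), "control dry weight")
  expect_warning(w <- compute_indices(1, 0.5, xc = 1, xt = 1), "SSI undefined")
  expect_true(is.na(w$ssi))
  expect_equal(w$mpi, 0.75)
})

test_that("indices match independent arithmetic on a five-genotype toy cohort", {
  c_ <- c(0.20, 0.15, 0.10, 0.25, 0.18)
  t_ <- c(0.15, 0.12, 0.02, 0.26, 0.09)
  xc <- mean(c_); xt <- mean(t_)
  got <- compute_indices(c_, t_, xc, xt)
  for (i in 1:5) {
    expect_identical(got$ssi[i], (1 - t_[i] / c_[i]) / (1 - xt / xc))
    expect_identical(got$mpi[i], (c_[i] + t_[i]) / 2)
    expect_identical(got$gmpi[i], sqrt(c_[i] * t_[i]))
    expect_identical(got$hmi[i], 2 * c_[i] * t_[i] / (c_[i] + t_[i]))
    expect_identical(got$sti[i], c_[i] * t_[i] / xc^2)
    expect_identical(got$ti[i], c_[i] - t_[i])
    expect_identical(got$si[i], t_[i] / c_[i])
  }
  pub <- compute_indices(c_, t_, xc, xt, gmpi_mode = "as_published")
  expect_identical(pub$gmpi, c_ * t_)
})

test_that("recovering dry weights from MPI and SI inverts the forward map", {
  r <- recover_c_t(1, 1)
  expect_equal(unlist(r), c(c_dw = 1, t_dw = 1))
  g1 <- recover_c_t(0.173, 0.891)
  expect_equal(g1$c_dw, 0.18297, tolerance = 1e-4)
  expect_equal(g1$t_dw, 0.16303, tolerance = 1e-4)
  g45 <- recover_c_t(0.142, 2.036)
  expect_equal(g45$c_dw, 0.0935, tolerance = 1e-3)
  expect_gt(g45$t_dw, g45$c_dw)   # stress exceeding control, negative TI

  set.seed(1)
  c_ <- runif(1000, 0.01, 0.4); t_ <- runif(1000, 0, 0.4)
  ind <- compute_indices(c_, t_, 0.17, 0.11)
  back <- recover_c_t(ind$mpi, ind$si)
  expect_lt(max(abs(back$c_dw - c_)), 1e-12)
  expect_lt(max(abs(back$t_dw - t_)), 1e-12)

  expect_error(recover_c_t(0, 0.5), "mpi")
  expect_error(recover_c_t(0.1, -1), "si = -1")
})

test_that("mean-ordering and scale identities hold over random pairs", {
  set.seed(7)
  c_ <- runif(500, 0.01, 1); t_ <- runif(500, 0, 1)
  v <- compute_indices(c_, t_, 0.5, 0.3)
  expect_true(all(v$hmi <= v$gmpi + 1e-12))
  expect_true(all(v$gmpi <= v$mpi + 1e-12))
  eq <- abs(c_ - t_) < 1e-12
  expect_true(all(abs(v$hmi - v$mpi)[!eq] > 0))
  expect_equal(v$sti, v$gmpi^2 / 0.5^2)
  expect_equal(v$mpi + v$ti / 2, c_)
  expect_equal(v$mpi - v$ti / 2, t_)

  k <- 3.7
  vk <- compute_indices(k * c_, k * t_, k * 0.5, k * 0.3)
  expect_equal(vk$si, v$si)
  expect_equal(vk$ssi, v$ssi)
  expect_equal(vk$sti, v$sti)
  expect_equal(vk$mpi, k * v$mpi)
  expect_equal(vk$gmpi, k * v$gmpi)
  expect_equal(vk$hmi, k * v$hmi)
  expect_equal(vk$ti, k * v$ti)
})

test_that("the composite score sums components and reproduces printed spot values", {
  zero <- data.frame(ssi = 0, mpi = 0, gmpi = 0, hmi = 0, sti = 0, ti = 0, si = 0)
  expect_equal(as.numeric(compute_sts(zero)), 0)

  t5 <- published_indices("T1")
  sts <- compute_sts(t5[c("SSI", "MPI", "GMPI", "HMI", "STI", "TI", "SI")])
  expect_equal(sts[t5$genotype == "G45"], 4.464, tolerance = 1e-3)
  expect_equal(sts[t5$genotype == "G51"], 4.107, tolerance = 1e-3)

  zs <- compute_sts(t5[c("SSI", "MPI", "GMPI", "HMI", "STI", "TI", "SI")],
                    mode = "standardized")
  expect_equal(mean(zs), 0, tolerance = 1e-12)
  expect_error(compute_sts(t5[c("SSI", "MPI")]), "missing index component")
})

test_that("index_matrix builds per-stress matrices with cohort means from the table", {
  tab <- generate_cohort(cohort_config(n_genotypes = 10, traits = "TDW"),
                         seed = 13)
  im <- index_matrix(tab, "T1")
  expect_equal(nrow(im), 10L)
  cmeans <- tapply(tab$value[tab$treatment == "T0"],
                   tab$genotype[tab$treatment == "T0"], mean)
  expect_equal(attr(im, "xc"), mean(cmeans))
  i <- which(im$genotype == "G4")
  expect_equal(im$mpi[i],
               (cmeans[["G4"]] + mean(tab$value[tab$treatment == "T1" &
                                                tab$genotype == "G4"])) / 2)
  expect_equal(im$sts, as.numeric(compute_sts(im[2:8])))
})

test_that("auditing a self-generated table yields zero deviations in either convention", {
  set.seed(5)
  c_ <- runif(12, 0.05, 0.3); t_ <- runif(12, 0.01, 0.25)
  xc <- mean(c_); xt <- mean(t_)
  for (mode in c("formula", "as_published")) {
    ind <- compute_indices(c_, t_, xc, xt, gmpi_mode = mode)
    m <- data.frame(genotype = paste0("G", 1:12),
                    SSI = ind$ssi, MPI = ind$mpi, GMPI = ind$gmpi,
                    HMI = ind$hmi, STI = ind$sti, TI = ind$ti, SI = ind$si,
                    STS = as.numeric(compute_sts(ind)))
    aud <- audit_published_table(m)
    expect_equal(aud$gmpi_mode_inferred, mode)
    expect_lt(max(aud$deviations), 1e-9)
    expect_equal(nrow(aud$flags), 0L)
    expect_true(all(aud$sts_rowsum$consistent))
    expect_equal(unname(aud$inferred_means[c("xc", "xt")]), c(xc, xt),
                 tolerance = 1e-9)
  }
})

test_that("auditing the published tables surfaces their internal inconsistencies", {
  for (stress in c("T1", "T2")) {
    aud <- audit_published_table(published_indices(stress))
    ## the printed geometric-mean column is the plain product
    expect_equal(aud$gmpi_mode_inferred, "as_published")
    expect_lt(aud$gmpi_max_dev[["as_published"]], 0.0015)
    expect_gt(aud$gmpi_max_dev[["formula"]], 0.1)
    ## TI and HMI are reproducible at printed precision; SSI is not
    expect_lt(max(aud$deviations[, "TI"]), 0.0015)
    expect_lt(max(aud$deviations[, "HMI"]), 0.0015)
    expect_gt(max(aud$deviations[, "SSI"]), 0.1)
    expect_true("SSI" %in% aud$flags$column)
    ## control cohort mean recovers the published dry-weight mean
    expect_equal(round(unname(aud$inferred_means["xc"]), 2), 0.17)
    expect_equal(round(unname(aud$inferred_means["mean_c"]), 2), 0.17)
    ## row sums: all within the worst-case rounding bound of seven
    ## 3-decimal columns, nearly all within the half-ULP band
    expect_lt(max(aud$sts_rowsum$deviation), 0.0035)
    expect_gte(sum(aud$sts_rowsum$consistent), 35L)
  }
})
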