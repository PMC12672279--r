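#' Calibrate a synthetic-cohort configuration from summary statistics
#'
#' Builds the configuration for [generate_cohort()] from a per-trait,
#' per-treatment table of target means and SDs (by default the packaged
#' published descriptives).  Treatment effects are absorbed into the
#' per-treatment target means (treatments are fixed effects); the target
#' variance is split into genotype, genotype x treatment and residual
#' components by `variance_partition`, so the implied marginal mean and SD
#' of every trait x treatment cell equal the calibration targets.
#'
#' The generator emulates a completely randomized design: each observation
#' is
#' \deqn{y_{gtr} = \mu_{t} + \gamma_g + \delta_{gt} + \epsilon_{gtr}}
#' with independent zero-mean Gaussian components scaled per the partition.
#' A single standardized genotype draw is scaled by each treatment's target
#' SD, so genotype effects are perfectly correlated across treatments while
#' per-treatment marginal SDs still match heteroscedastic targets.
#'
#' Traits in `correlated_traits` share common factors in every variance
#' component with pairwise weight `cross_trait_correlation`, so the realized
#' correlation of genotype means between those traits equals the target
#' (emulating the strong positive coupling of growth and root traits under
#' control conditions).
#'
#' The root-to-shoot ratio is never simulated: it is derived per replicate
#' from the generated root and shoot lengths.
#'
#' @param summaries data.frame with columns `trait`, `treatment`, `mean`,
#'   `sd` (default [published_descriptives()]).
#' @param n_genotypes number of genotypes (labels `G1..Gn`), >= 2.
#' @param replicates replicates per genotype x treatment.
#' @param variance_partition named fractions `genotype`, `interaction`,
#'   `residual`; each in \[0, 1\], summing to 1.
#' @param cross_trait_correlation pairwise correlation target for
#'   `correlated_traits`, in \[0, 1).
#' @param correlated_traits traits sharing the common factors (default: the
#'   growth/root set).
#' @param traits traits to generate; default every measured trait with a
#'   summary row (the ratio trait is always derived, never drawn).
#' @param schema trait metadata, see [trait_schema()].
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_genotypes = 10, traits = c("DSG", "RL", "SL"))
#' tab <- generate_cohort(cfg, seed = 1)
cohort_config <- function(summaries = published_descriptives(),
                          n_genotypes = 37,
                          replicates = 3,
                          variance_partition = c(genotype = 0.4,
                                                 interaction = 0.2,
                                                 residual = 0.4),
                          cross_trait_correlation = 0.7,
                          correlated_traits = c("NOL", "SL", "TFW", "TDW",
                                                "SR", "NSR", "RL", "RFW"),
                          traits = NULL,
                          schema = trait_schema()) {
  if (n_genotypes < 2) stop("n_genotypes must be >= 2")
  if (replicates < 1) stop("replicates must be >= 1")
  vp <- variance_partition[c("genotype", "interaction", "residual")]
  if (anyNA(vp) || any(vp < 0) || any(vp > 1) || abs(sum(vp) - 1) > 1e-8)
    stop("variance_partition must be named fractions in [0,1] summing to 1")
  if (cross_trait_correlation < 0 || cross_trait_correlation >= 1)
    stop("cross_trait_correlation must lie in [0, 1)")

  measured <- schema$trait[schema$kind == "measured"]
  if (is.null(traits))
    traits <- intersect(measured, unique(summaries$trait))
  else {
    bad <- setdiff(traits, measured)
    if (length(bad)) stop("not a measured trait: ", paste(bad, collapse = ", "))
    traits <- intersect(schema$trait, traits)  # schema order
  }
  if (!length(traits)) stop("no traits to generate")

  targets <- list()
  for (tr in traits) {
    for (lev in trait_treatments(tr, schema)) {
      row <- summaries[summaries$trait == tr & summaries$treatment == lev, ]
      if (nrow(row) != 1)
        stop("calibration error: missing summary row for ", tr, " / ", lev)
      if (row$sd < 0) stop("target sd must be >= 0")
      targets[[length(targets) + 1L]] <-
        data.frame(trait = tr, treatment = lev,
                   mean = row$mean, sd = row$sd, stringsAsFactors = FALSE)
    }
  }
  structure(list(targets = do.call(rbind, targets),
                 n_genotypes = n_genotypes,
                 replicates = replicates,
                 variance_partition = vp,
                 cross_trait_correlation = cross_trait_correlation,
                 correlated_traits = intersect(correlated_traits, traits),
                 traits = traits,
                 schema = schema,
                 archetypes = NULL),
            class = "cohort_config")
}

#' Inject tolerance archetypes into a cohort configuration
#'
#' Shifts the target means of designated genotypes under the stress
#' treatments (`T1`, `T2`) by `shift` target-SD units: tolerant genotypes
#' move towards the favourable side of every trait (up for
#' higher-is-better, down for lower-is-better), susceptible genotypes the
#' reverse.  Control means are untouched.  This creates known ground truth
#' for scoring-recovery simulations.
#'
#' @param config a [cohort_config()].
#' @param tolerant,susceptible disjoint sets of genotype labels.
#' @param shift effect size in SD units (>= 0; 0 leaves the config
#'   unchanged).
#' @return The modified `cohort_config`.
#' @export
inject_archetypes <- function(config, tolerant, susceptible, shift) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(intersect(tolerant, susceptible)))
    stop("config error: tolerant and susceptible sets overlap")
  labs <- paste0("G", seq_len(config$n_genotypes))
  bad <- setdiff(c(tolerant, susceptible), labs)
  if (length(bad)) stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  if (shift < 0) stop("shift must be >= 0")
  config$archetypes <- list(tolerant = tolerant, susceptible = susceptible,
                            shift = shift)
  config
}

#' Generate a balanced synthetic trait table
#'
#' Draws a complete genotype x treatment x replicate table from the latent
#' Gaussian model described in [cohort_config()], then applies
#' family-specific post-processing: count traits are rounded to the nearest
#' non-negative integer, proportions are clipped to \[0, 1\], and positive
#' continuous traits are truncated at zero by resampling the residual draw
#' of violating cells (avoiding a point mass at zero).  The ratio trait
#' `R/S` is derived per replicate from generated `RL` and `SL` when both
#' are present.  The same `(config, seed)` pair yields a bit-identical
#' table.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed (mandatory: runs must be reproducible).
#' @return A [trait_table()].
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory: refusing non-reproducible generation")
  set.seed(as.integer(seed))

  n_g <- config$n_genotypes
  n_r <- config$replicates
  vp <- config$variance_partition
  rho <- config$cross_trait_correlation
  labs <- paste0("G", seq_len(n_g))
  levs <- treatment_levels()$code
  fam <- stats::setNames(config$schema$family, config$schema$trait)
  pol <- stats::setNames(config$schema$polarity, config$schema$trait)

  ## shared factors across correlated traits, one per experimental unit
  zg_shared <- stats::rnorm(n_g)
  zi_shared <- matrix(stats::rnorm(n_g * 3), n_g, 3,
                      dimnames = list(labs, levs))
  zr_shared <- array(stats::rnorm(n_g * 3 * n_r), c(n_g, 3, n_r),
                     dimnames = list(labs, levs, NULL))

  mix <- function(shared, own, corr)
    if (corr) sqrt(rho) * shared + sqrt(1 - rho) * own else own

  arch <- config$archetypes
  out <- vector("list", length(config$traits))
  names(out) <- config$traits
  for (tr in config$traits) {
    corr <- tr %in% config$correlated_traits
    ug <- mix(zg_shared, stats::rnorm(n_g), corr)
    treats <- trait_treatments(tr, config$schema)
    rows <- list()
    for (lev in treats) {
      tg <- config$targets[config$targets$trait == tr &
                           config$targets$treatment == lev, ]
      mu <- rep(tg$mean, n_g)
      names(mu) <- labs
      if (!is.null(arch) && lev != "T0" && arch$shift > 0) {
        dir <- if (pol[[tr]] == "lower_is_better") -1 else 1
        mu[arch$tolerant] <- mu[arch$tolerant] + dir * arch$shift * tg$sd
        mu[arch$susceptible] <- mu[arch$susceptible] - dir * arch$shift * tg$sd
      }
      li <- match(lev, levs)
      wi <- mix(zi_shared[, li], stats::rnorm(n_g), corr)
      for (r in seq_len(n_r)) {
        er <- mix(zr_shared[, li, r], stats::rnorm(n_g), corr)
        val <- mu + tg$sd * (sqrt(vp[["genotype"]]) * ug +
                             sqrt(vp[["interaction"]]) * wi +
                             sqrt(vp[["residual"]]) * er)
        if (fam[[tr]] == "positive_continuous" && tg$sd > 0) {
          base <- mu + tg$sd * (sqrt(vp[["genotype"]]) * ug +
                                sqrt(vp[["interaction"]]) * wi)
          it <- 0L
          while (any(bad <- val < 0) && it < 1000L) {
            val[bad] <- base[bad] +
              tg$sd * sqrt(vp[["residual"]]) * stats::rnorm(sum(bad))
            it <- it + 1L
          }
          val <- pmax(val, 0)   # unreachable fallback when residual f = 0
        } else if (fam[[tr]] == "positive_continuous") {
          val <- pmax(val, 0)
        }
        if (fam[[tr]] == "count") val <- pmax(round(val), 0)
        if (fam[[tr]] == "proportion") val <- pmin(pmax(val, 0), 1)
        rows[[length(rows) + 1L]] <-
          data.frame(genotype = labs, treatment = lev, replicate = r,
                     trait = tr, value = as.numeric(val),
                     stringsAsFactors = FALSE)
      }
    }
    out[[tr]] <- do.call(rbind, rows)
  }
  obs <- do.call(rbind, out)

  ## derived ratio trait, per replicate
  if (all(c("RL", "SL") %in% config$traits)) {
    rl <- obs[obs$trait == "RL", ]
    sl <- obs[obs$trait == "SL", ]
    key <- function(d) paste(d$genotype, d$treatment, d$replicate)
    sl <- sl[match(key(rl), key(sl)), ]
    rs <- rl
    rs$trait <- "R/S"
    rs$value <- rs_ratio(rl$value, pmax(sl$value, .Machine$double.eps))
    obs <- rbind(obs, rs)
  }
  rownames(obs) <- NULL
  trait_table(obs, schema = config$schema)
}
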