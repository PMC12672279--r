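#' Root-to-shoot ratio
#'
#' Derived per replicate as root length divided by shoot length, before any
#' summarization (the mean of per-replicate ratios is not the ratio of trait
#' means; see the methods vignette).
#'
#' @param rl root length (cm), vector.
#' @param sl shoot length (cm), vector; must be strictly positive.
#' @return `rl / sl`.
#' @export
#' @examples
#' rs_ratio(6.14, 8.27)
rs_ratio <- function(rl, sl) {
  if (any(sl == 0)) stop("undefined ratio: shoot length is zero")
  rl / sl
}

#' Photosynthetic pigment concentrations from absorbance readings
#'
#' Applies the standard acetone-extract equations for chlorophyll a,
#' chlorophyll b and carotenoids from absorbances at 663.2, 646.8 and
#' 470 nm:
#' \deqn{Chla = 12.25 A_{663.2} - 2.79 A_{646.8}}
#' \deqn{Chlb = 21.21 A_{646.8} - 5.1 A_{663.2}}
#' \deqn{ChlT = Chla + Chlb}
#' \deqn{CAR = (1000 A_{470} - 1.82\,Chla - 85.02\,Chlb) / 198}
#'
#' Negative pigment results are returned as computed but flagged: they
#' indicate readings outside the calibration range of the equations.
#'
#' @param a663_2,a646_8,a470 absorbances (non-negative, recycled vectors).
#' @return data.frame with `chla`, `chlb` (mg/g), `tchl` (mg/g, exactly
#'   `chla + chlb`), `car` (ug/mL) and logical `flagged`.
#' @export
#' @examples
#' pigment_concentrations(0.8, 0.4, 0)
pigment_concentrations <- function(a663_2, a646_8, a470) {
  if (any(a663_2 < 0) || any(a646_8 < 0) || any(a470 < 0))
    stop("domain error: negative absorbance")
  chla <- 12.25 * a663_2 - 2.79 * a646_8
  chlb <- 21.21 * a646_8 - 5.1 * a663_2
  tchl <- chla + chlb
  car <- (1000 * a470 - 1.82 * chla - 85.02 * chlb) / 198
  data.frame(chla = chla, chlb = chlb, tchl = tchl, car = car,
             flagged = chla < 0 | chlb < 0 | car < 0)
}

#' Descriptive statistics for one trait under one treatment
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (100 sd / mean), minimum, maximum and n over all genotype x
#' replicate values in the treatment — one row of the descriptive table.
#'
#' @param table a [trait_table()].
#' @param trait trait name.
#' @param treatment treatment code.
#' @param population_sd use the n-denominator SD instead (default `FALSE`).
#' @return one-row data.frame `trait, treatment, mean, sd, cv, min, max, n`.
#'   `cv` is `NA` (with a warning) when the mean is zero.
#' @export
summarize_trait <- function(table, trait, treatment, population_sd = FALSE) {
  v <- table$value[table$trait == trait & table$treatment == treatment]
  if (length(v) < 2) stop("need at least 2 observations")
  m <- mean(v)
  s <- stats::sd(v)
  if (population_sd) s <- s * sqrt((length(v) - 1) / length(v))
  cv <- if (m == 0) { warning("undefined CV: mean is zero"); NA_real_ }
        else 100 * s / m
  data.frame(trait = trait, treatment = treatment, mean = m, sd = s, cv = cv,
             min = min(v), max = max(v), n = length(v),
             stringsAsFactors = FALSE)
}

#' Descriptive statistics for every trait x treatment
#'
#' @inheritParams summarize_trait
#' @return data.frame with one row per trait x treatment present in the
#'   table, in schema order.
#' @export
summarize_traits <- function(table, population_sd = FALSE) {
  sch <- trait_schema()
  traits <- intersect(sch$trait, unique(table$trait))
  out <- list()
  for (tr in traits)
    for (lev in intersect(treatment_levels()$code,
                          unique(table$treatment[table$trait == tr])))
      out[[length(out) + 1L]] <-
        summarize_trait(table, tr, lev, population_sd = population_sd)
  do.call(rbind, out)
}

#' Signed percent change between two values
#'
#' `100 * (after - before) / before`.  Reporting layers attach the direction
#' word ("increased"/"reduced"); the sign carries the direction here.
#'
#' @param before reference value (non-zero).
#' @param after comparison value.
#' @return signed percent change (vectorized).
#' @export
#' @examples
#' percent_change(6.14, 4.86)   # -20.85 %
#' percent_change(2.07, 8.55)   # +313.04 %
percent_change <- function(before, after) {
  if (any(before == 0)) stop("undefined change: reference value is zero")
  100 * (after - before) / before
}

#' Percent-change summary between two treatments
#'
#' Per-trait percent change of treatment means, by default from control to
#' severe stress.  Means are taken from a summary table (either computed by
#' [summarize_traits()] or the packaged published descriptives), so printed
#' claims can be audited against rounded published means.
#'
#' @param summaries data.frame with `trait`, `treatment`, `mean` columns.
#' @param from,to treatment codes (defaults `T0`, `T2`).
#' @return data.frame `trait, mean_from, mean_to, pct_change`.
#' @export
percent_change_table <- function(summaries, from = "T0", to = "T2") {
  a <- summaries[summaries$treatment == from, c("trait", "mean")]
  b <- summaries[summaries$treatment == to, c("trait", "mean")]
  m <- merge(a, b, by = "trait", suffixes = c("_from", "_to"))
  m <- m[match(intersect(summaries$trait, m$trait), m$trait), ]
  m$pct_change <- percent_change(m$mean_from, m$mean_to)
  rownames(m) <- NULL
  m
}
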