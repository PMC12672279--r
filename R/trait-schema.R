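#' Treatment levels of the osmotic-stress design
#'
#' The screening design imposes three fixed water regimes with PEG 6000:
#' `T0` (0 %, control), `T1` (10 % w/v) and `T2` (20 % w/v).  The code and
#' the PEG percentage are a fixed bijection; all functions key on the code.
#'
#' @return A data.frame with columns `code` and `peg_pct`.
#' @export
#' @examples
#' treatment_levels()
treatment_levels <- function() {
  data.frame(code = c("T0", "T1", "T2"), peg_pct = c(0, 10, 20),
             stringsAsFactors = FALSE)
}

#' Trait schema for the seedling drought screen
#'
#' Metadata for the 17 growth, root and biochemical traits handled by the
#' pipeline: measurement unit, scoring polarity, whether the trait is
#' measured or derived, which treatments it is measured under, and the
#' distribution family used by the synthetic-cohort generator.
#'
#' The oxidative-stress markers MDA and H2O2 are assayed only under control
#' and severe stress (`T0`, `T2`); every other trait is measured under all
#' three regimes.  The root-to-shoot ratio `R/S` is derived per replicate as
#' root length / shoot length and is never simulated directly.
#'
#' Polarity is the biological reading used for archetype injection and the
#' optional polarity-aware scoring mode: delayed germination (DSG) and the
#' damage markers MDA and H2O2 are "lower is better"; everything else is
#' "higher is better".
#'
#' @return A data.frame with one row per trait and columns `trait`, `unit`,
#'   `polarity`, `kind`, `family` and `measured_in` (comma-separated
#'   treatment codes).
#' @export
#' @examples
#' trait_schema()
trait_schema <- function() {
  all3 <- "T0,T1,T2"
  df <- rbind(
    data.frame(trait = "DSG",  unit = "days",    polarity = "lower_is_better",  kind = "measured", family = "count",               measured_in = all3),
    data.frame(trait = "NOL",  unit = "count",   polarity = "higher_is_better", kind = "measured", family = "count",               measured_in = all3),
    data.frame(trait = "TFW",  unit = "g",       polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "TDW",  unit = "g",       polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "SR",   unit = "fraction",polarity = "higher_is_better", kind = "measured", family = "proportion",          measured_in = all3),
    data.frame(trait = "NSR",  unit = "count",   polarity = "higher_is_better", kind = "measured", family = "count",               measured_in = all3),
    data.frame(trait = "RL",   unit = "cm",      polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "SL",   unit = "cm",      polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "RFW",  unit = "g",       polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "R/S",  unit = "ratio",   polarity = "higher_is_better", kind = "derived",  family = "ratio",               measured_in = all3),
    data.frame(trait = "Chla", unit = "mg/g",    polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "Chlb", unit = "mg/g",    polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "TChl", unit = "mg/g",    polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "CAR",  unit = "ug/mL",   polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "Pro",  unit = "umol/g",  polarity = "higher_is_better", kind = "measured", family = "positive_continuous", measured_in = all3),
    data.frame(trait = "MDA",  unit = "nmol/g",  polarity = "lower_is_better",  kind = "measured", family = "positive_continuous", measured_in = "T0,T2"),
    data.frame(trait = "H2O2", unit = "umol/g",  polarity = "lower_is_better",  kind = "measured", family = "positive_continuous", measured_in = "T0,T2")
  )
  rownames(df) <- NULL
  df
}

#' The 15 traits entering the efficiency score
#'
#' MDA and H2O2 are excluded from the cumulative mean +/- SD score: they are
#' measured under only two regimes and the published 15-parameter score list
#' omits them.
#'
#' @return Character vector of 15 trait names.
#' @export
emi_trait_set <- function() {
  c("DSG", "NOL", "TFW", "TDW", "SR", "NSR", "RL", "SL", "RFW", "R/S",
    "Chla", "Chlb", "TChl", "CAR", "Pro")
}

## treatments a trait is measured in, as a character vector
trait_treatments <- function(trait, schema = trait_schema()) {
  i <- match(trait, schema$trait)
  if (is.na(i)) stop("unknown trait: ", trait)
  strsplit(schema$measured_in[i], ",", fixed = TRUE)[[1]]
}
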