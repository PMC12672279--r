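#' Published summary tables packaged with the pipeline
#'
#' The package ships the published study's summary tables as plain-text
#' fixtures: per-trait descriptive statistics under each treatment
#' (`published_descriptives()`), the per-genotype efficiency score cards
#' (`published_scorecards()`), and the two stress-tolerance index tables,
#' one per stress level (`published_indices()`).  They calibrate the
#' synthetic-cohort generator and feed the algebraic auditor; no raw
#' replicate-level data is distributed with the study.
#'
#' One descriptive row (shoot length under control) prints a minimum larger
#' than its maximum in the source; the fixture carries it verbatim with
#' `suspect = TRUE` rather than silently correcting it, and consumers that
#' need min/max must filter on that flag.
#'
#' @param stress `"T1"` (10 % PEG) or `"T2"` (20 % PEG) for
#'   `published_indices()`.
#' @return data.frames mirroring the published tables:
#'   `published_descriptives()` has `trait, treatment, mean, sd, cv, min,
#'   max, suspect`; `published_scorecards()` has per-treatment categories
#'   and totals plus the overall total; `published_indices()` has the seven
#'   indices and the printed composite score per genotype.
#' @export
published_descriptives <- function() {
  f <- system.file("extdata", "published_descriptives.csv",
                   package = "droughtscreen", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname published_descriptives
#' @export
published_scorecards <- function() {
  f <- system.file("extdata", "published_scorecards.csv",
                   package = "droughtscreen", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname published_descriptives
#' @export
published_indices <- function(stress = c("T1", "T2")) {
  stress <- match.arg(stress)
  f <- system.file("extdata",
                   sprintf("published_indices_%s.csv", stress),
                   package = "droughtscreen", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
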