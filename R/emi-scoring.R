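#' Mean +/- SD classification thresholds
#'
#' For one trait under one treatment, the population mean and standard
#' deviation over genotype means (replicates averaged first) define the
#' efficiency bands: efficient above `mu + sd`, inefficient below
#' `mu - sd`, medium between (bounds inclusive).
#'
#' @param table a [trait_table()].
#' @param trait trait name.
#' @param treatment treatment code.
#' @return list with `trait`, `treatment`, `mu`, `sd`, `upper`, `lower`.
#' @export
emi_thresholds <- function(table, trait, treatment) {
  m <- genotype_means(table, trait, treatment)
  if (length(m) < 2) stop("need >= 2 genotypes")
  mu <- mean(m)
  s <- stats::sd(m)
  list(trait = trait, treatment = treatment, mu = mu, sd = s,
       upper = mu + s, lower = mu - s)
}

#' Classify a value against efficiency thresholds
#'
#' Strictly above `mu + sd` is efficient (`E`), strictly below `mu - sd`
#' inefficient (`I`), otherwise medium (`M`); values exactly on a bound are
#' medium.  With `polarity = "lower_is_better"` the E and I labels swap, so
#' that favourable extremes are always scored E.  When `sd` is zero the
#' bands collapse and everything is `M`.
#'
#' @param value numeric vector.
#' @param thresholds output of [emi_thresholds()] (or any list with
#'   `upper`, `lower`).
#' @param polarity `"higher_is_better"` (default) or `"lower_is_better"`.
#' @return character vector in `{"E","M","I"}`.
#' @export
#' @examples
#' th <- list(upper = 6, lower = 4)
#' classify_emi(c(3.9, 4, 5, 6, 6.001), th)
classify_emi <- function(value, thresholds,
                         polarity = c("higher_is_better", "lower_is_better")) {
  polarity <- match.arg(polarity)
  out <- ifelse(value > thresholds$upper, "E",
                ifelse(value < thresholds$lower, "I", "M"))
  if (polarity == "lower_is_better")
    out <- c(E = "I", M = "M", I = "E")[out]
  unname(out)
}

emi_score <- c(E = 3L, M = 2L, I = 1L)

#' Cumulative efficiency score cards
#'
#' For every genotype: the per-trait E/M/I category under each treatment
#' (from genotype means against the [emi_thresholds()] of that trait x
#' treatment), the 3/2/1 scores, the per-treatment total (15 traits, so
#' 15-45), the overall total across the three treatments (45-135), and a
#' per-treatment overall E/M/I letter obtained by applying the same
#' mean +/- SD rule to the distribution of treatment totals themselves
#' (the documented reconstruction of the published per-treatment letter;
#' see the methods vignette).
#'
#' By default every trait is scored with the literal "higher is efficient"
#' rule, for fidelity with the published scheme; `polarity = "biological"`
#' instead scores DSG, MDA and H2O2 (where lower values are favourable)
#' with the swapped rule from the trait schema.
#'
#' @param table a [trait_table()].
#' @param traits the traits to score (default [emi_trait_set()]; each must
#'   be present under all three treatments).
#' @param polarity `"literal"` (default) or `"biological"`.
#' @return Object of class `score_card`: data.frame with one row per
#'   genotype (`genotype`, then `cat_T*`, `total_T*` per treatment and
#'   `overall`), with the long per-trait score table in
#'   `attr(, "trait_scores")`.
#' @export
score_card <- function(table, traits = emi_trait_set(),
                       polarity = c("literal", "biological")) {
  polarity <- match.arg(polarity)
  levs <- sort(unique(table$treatment))
  absent <- traits[!vapply(traits, function(tr)
    all(levs %in% unique(table$treatment[table$trait == tr])), TRUE)]
  if (length(absent))
    stop("trait(s) absent under some treatment: ",
         paste(absent, collapse = ", "))
  pol_map <- stats::setNames(trait_schema()$polarity, trait_schema()$trait)

  long <- list()
  for (lev in levs) {
    for (tr in traits) {
      th <- emi_thresholds(table, tr, lev)
      m <- genotype_means(table, tr, lev)
      pol <- if (polarity == "biological") pol_map[[tr]] else "higher_is_better"
      cat_ <- classify_emi(m, th, pol)
      long[[length(long) + 1L]] <-
        data.frame(genotype = names(m), treatment = lev, trait = tr,
                   mean = as.numeric(m), category = cat_,
                   score = emi_score[cat_], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL

  genos <- sort(unique(long$genotype))
  card <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (lev in levs) {
    tot <- tapply(long$score[long$treatment == lev],
                  long$genotype[long$treatment == lev], sum)[genos]
    ## overall letter per treatment: mean +/- SD rule on the totals
    mu <- mean(tot); s <- stats::sd(tot)
    card[[paste0("cat_", lev)]] <-
      classify_emi(as.numeric(tot), list(upper = mu + s, lower = mu - s))
    card[[paste0("total_", lev)]] <- as.integer(tot)
  }
  card$overall <- as.integer(rowSums(card[paste0("total_", levs)]))
  structure(card, class = c("score_card", "data.frame"),
            trait_scores = long, n_traits = length(traits),
            polarity = polarity)
}

#' Rank genotypes by overall efficiency score
#'
#' Descending by overall total with dense ranking (ties share a rank and
#' the next distinct total takes the next rank); ties are listed
#' alphabetically for display.
#'
#' @param cards a [score_card()] (or any data.frame with `genotype` and
#'   `overall`).
#' @return data.frame `rank, genotype, overall`, best first.
#' @export
rank_genotypes <- function(cards) {
  if (!nrow(cards)) stop("no score cards")
  ord <- order(-cards$overall, cards$genotype)
  out <- data.frame(genotype = cards$genotype[ord],
                    overall = cards$overall[ord],
                    stringsAsFactors = FALSE)
  out$rank <- match(out$overall, sort(unique(out$overall), decreasing = TRUE))
  out[c("rank", "genotype", "overall")]
}
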