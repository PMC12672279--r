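#' Pearson correlation matrix among traits within one treatment
#'
#' By default values are aggregated to genotype means within the treatment
#' before correlating, since trait relationships are interpreted among
#' genotypes; `level = "replicate"` correlates raw replicate-level values
#' instead.  Zero-variance traits yield NA entries and are flagged, not
#' silently set to zero.
#'
#' @param table a [trait_table()].
#' @param traits traits to correlate (default: all measured under the
#'   treatment).
#' @param treatment treatment code.
#' @param level `"genotype"` (means, default) or `"replicate"`.
#' @return Object of class `trait_cor`: list with `r` (symmetric matrix,
#'   unit diagonal), `traits`, `treatment`, `n`, `degenerate` (zero-variance
#'   trait names).
#' @export
correlation_by_treatment <- function(table, traits = NULL, treatment,
                                     level = c("genotype", "replicate")) {
  level <- match.arg(level)
  sub <- table[table$treatment == treatment, ]
  if (is.null(traits))
    traits <- intersect(trait_schema()$trait, unique(sub$trait))
  sub <- sub[sub$trait %in% traits, ]
  if (!nrow(sub)) stop("no observations under ", treatment)

  if (level == "genotype") {
    wide <- sapply(traits, function(tr) genotype_means(table, tr, treatment))
  } else {
    key <- paste(sub$genotype, sub$replicate)
    wide <- sapply(traits, function(tr) {
      s <- sub[sub$trait == tr, ]
      s$value[match(sort(unique(key)), paste(s$genotype, s$replicate))]
    })
  }
  wide <- as.matrix(wide)
  if (nrow(wide) < 3) stop("need >= 3 paired observations")
  degenerate <- traits[apply(wide, 2, stats::var) == 0]
  r <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(list(r = r, traits = traits, treatment = treatment,
                 n = nrow(wide), degenerate = degenerate),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, ...) {
  cat(sprintf("Pearson correlations under %s (n = %d)\n", x$treatment, x$n))
  print(round(x$r, 3))
  if (length(x$degenerate))
    cat("zero-variance traits (NA entries):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation trajectories across stress levels
#'
#' Given per-treatment correlation matrices over the same trait set
#' (ordered from control to severe stress), reports for each trait pair the
#' ordered correlations and classifies the trajectory as `increasing`
#' (strictly), `decreasing` (strictly) or `non-monotone` — the pattern of
#' interest being growth-trait correlations that collapse and reverse as
#' stress intensifies.
#'
#' @param matrices list of `trait_cor` objects (>= 2), in treatment order.
#' @return data.frame with one row per unordered trait pair: `trait_1`,
#'   `trait_2`, one `r_<treatment>` column per matrix, `span`
#'   (max - min) and `trend`.
#' @export
correlation_shift_summary <- function(matrices) {
  if (length(matrices) < 2) stop("need at least two correlation matrices")
  traits <- matrices[[1]]$traits
  for (m in matrices)
    if (!identical(m$traits, traits))
      stop("mismatched trait sets across treatments")
  pairs <- utils::combn(traits, 2)
  rs <- sapply(matrices, function(m)
    m$r[cbind(match(pairs[1, ], traits), match(pairs[2, ], traits))])
  rs <- matrix(rs, ncol = length(matrices))
  colnames(rs) <- paste0("r_", vapply(matrices, `[[`, "", "treatment"))
  trend <- apply(rs, 1, function(v) {
    d <- diff(v)
    if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing"
    else "non-monotone"
  })
  out <- data.frame(trait_1 = pairs[1, ], trait_2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rs))
  out$span <- apply(rs, 1, max) - apply(rs, 1, min)
  out$trend <- trend
  out
}
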