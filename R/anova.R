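#' Balanced factorial ANOVA for one trait
#'
#' Fixed-effects decomposition of a balanced genotype x treatment x
#' replicate table into the sources Genotypes, Treatments, Replication
#' (a crossed blocking factor, not nested in treatment), Genotypes x
#' Treatments, and Error, with `F = MS_source / MS_error`.  The engine is
#' balanced-only: the screening design is balanced, and under balance the
#' sequential and marginal sums of squares coincide, so there is no
#' Type-I/III ambiguity.  Unbalanced tables are refused with a report of
#' the missing cells.
#'
#' Traits measured under two treatments (the oxidative markers) get a
#' 1-df treatment term; all degrees of freedom follow from the design
#' counts.  A constant response yields zero sums of squares and undefined
#' (NA) F and p, reported as such.
#'
#' @param table a [trait_table()].
#' @param trait trait name.
#' @return An object of class `trait_anova`: data.frame with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`.
#' @export
anova_trait <- function(table, trait) {
  sub <- table[table$trait == trait, ]
  if (!nrow(sub)) stop("no observations for trait ", trait)
  g <- factor(sub$genotype)
  t_ <- factor(sub$treatment)
  r <- factor(sub$replicate)
  G <- nlevels(g); Tn <- nlevels(t_); R <- nlevels(r)
  counts <- table(g, t_, r)
  if (any(counts != 1)) {
    miss <- which(counts != 1, arr.ind = TRUE)
    lab <- apply(utils::head(miss, 5), 1, function(i)
      paste(levels(g)[i[1]], levels(t_)[i[2]], levels(r)[i[3]], sep = "/"))
    stop("unbalanced design: ", sum(counts == 0), " missing and ",
         sum(counts > 1), " duplicated cells (e.g. ",
         paste(lab, collapse = ", "), ")")
  }
  y <- sub$value
  N <- length(y)
  gm <- mean(y)
  mg <- tapply(y, g, mean)
  mt <- tapply(y, t_, mean)
  mr <- tapply(y, r, mean)
  mgt <- tapply(y, list(g, t_), mean)

  ss_g <- Tn * R * sum((mg - gm)^2)
  ss_t <- G * R * sum((mt - gm)^2)
  ss_r <- G * Tn * sum((mr - gm)^2)
  ss_gt <- R * sum((mgt - outer(mg, rep(1, Tn)) -
                    outer(rep(1, G), mt) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_e <- max(ss_tot - ss_g - ss_t - ss_r - ss_gt, 0)  # guard fp underflow

  df <- c(G - 1, Tn - 1, R - 1, (G - 1) * (Tn - 1))
  df_e <- N - 1 - sum(df)
  ss <- c(ss_g, ss_t, ss_r, ss_gt)
  ms <- ss / df
  ms_e <- ss_e / df_e
  f <- if (ms_e > 0) ms / ms_e else rep(NA_real_, 4)
  p <- ifelse(is.na(f), NA_real_, stats::pf(f, df, df_e, lower.tail = FALSE))

  out <- data.frame(
    source = c("Genotypes", "Treatments", "Replication",
               "Genotypes:Treatments", "Error", "Total"),
    df = c(df, df_e, N - 1),
    ss = c(ss, ss_e, ss_tot),
    ms = c(ms, ms_e, NA),
    f = c(f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("trait_anova", "data.frame"),
            trait = trait, n = N, ms_error = ms_e, df_error = df_e,
            n_per_treatment = G * R, treatments = levels(t_))
}

#' @export
print.trait_anova <- function(x, ...) {
  cat("ANOVA for trait", attr(x, "trait"), "\n")
  df <- as.data.frame(x)
  df$p <- format_pval(df$p)
  print(df, row.names = FALSE, digits = 5)
  invisible(x)
}

## p-values below 1e-16 are reported as "<1e-16"
format_pval <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 1e-16, "<1e-16", formatC(p, format = "g", digits = 3)))
}

#' Mean-square summary across all traits
#'
#' One row per trait with the mean square of every ANOVA source and
#' significance stars for the tested terms (`***` p < 0.001, `**` < 0.01,
#' `*` < 0.05) — the layout of a multi-trait variance-analysis table.
#'
#' @inheritParams anova_trait
#' @param traits traits to include (default: all present).
#' @return data.frame, one row per trait.
#' @export
anova_all <- function(table, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_schema()$trait,
                                           unique(table$trait))
  rows <- lapply(traits, function(tr) {
    a <- anova_trait(table, tr)
    star <- function(p) if (is.na(p)) "" else
      if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    data.frame(trait = tr,
               ms_genotype = a$ms[1], sig_genotype = star(a$p[1]),
               ms_treatment = a$ms[2], sig_treatment = star(a$p[2]),
               ms_replication = a$ms[3],
               ms_interaction = a$ms[4], sig_interaction = star(a$p[4]),
               ms_error = a$ms[5],
               df_total = a$df[6],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tukey pairwise comparison of treatments
#'
#' All pairwise treatment contrasts on genotype x replicate values using
#' the studentized range with the balanced-ANOVA error mean square, plus a
#' compact letter display assigned greedily from the largest mean
#' (ties broken by descending mean, then label order).
#'
#' @inheritParams anova_trait
#' @param alpha family-wise error rate (default 0.05).
#' @return An object of class `tukey_treatments`: list with `comparisons`
#'   (mean difference, studentized-range adjusted p, 1 - alpha confidence
#'   interval per pair) and `letters` (compact letter display per
#'   treatment, largest mean first).
#' @export
tukey_treatments <- function(table, trait, alpha = 0.05) {
  a <- anova_trait(table, trait)
  levs <- attr(a, "treatments")
  k <- length(levs)
  if (k < 2) stop("need at least 2 treatments")
  sub <- table[table$trait == trait, ]
  means <- tapply(sub$value, sub$treatment, mean)[levs]
  n <- attr(a, "n_per_treatment")
  ms_e <- attr(a, "ms_error")
  df_e <- attr(a, "df_error")
  se <- sqrt(ms_e / n)

  pairs <- utils::combn(levs, 2)
  diffs <- means[pairs[2, ]] - means[pairs[1, ]]
  if (se > 0) {
    q <- abs(diffs) / se
    q[diffs == 0] <- 0   # guard 0/0 when the error MS underflows
    padj <- stats::ptukey(q, nmeans = k, df = df_e, lower.tail = FALSE)
    hw <- stats::qtukey(1 - alpha, nmeans = k, df = df_e) * se
  } else {
    padj <- ifelse(diffs == 0, 1, 0)
    hw <- 0
  }
  comp <- data.frame(treatment_1 = pairs[1, ], treatment_2 = pairs[2, ],
                     diff = as.numeric(diffs),
                     lwr = as.numeric(diffs) - hw,
                     upr = as.numeric(diffs) + hw,
                     p_adj = as.numeric(padj),
                     stringsAsFactors = FALSE)

  ## greedy compact letter display from the largest mean
  ord <- order(-means, levs)
  sig <- function(a_, b_) {
    i <- (comp$treatment_1 == a_ & comp$treatment_2 == b_) |
         (comp$treatment_1 == b_ & comp$treatment_2 == a_)
    comp$p_adj[i] < alpha
  }
  groups <- list()   # each element: treatments sharing one letter
  for (lev in levs[ord]) {
    placed <- FALSE
    for (j in seq_along(groups)) {
      if (!any(vapply(groups[[j]], sig, logical(1), b_ = lev))) {
        groups[[j]] <- c(groups[[j]], lev)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- lev
  }
  letter <- stats::setNames(rep("", k), levs)
  for (j in seq_along(groups))
    for (lev in groups[[j]])
      letter[lev] <- paste0(letter[lev], letters[j])

  structure(list(trait = trait, alpha = alpha, means = means,
                 comparisons = comp,
                 letters = data.frame(treatment = levs,
                                      mean = as.numeric(means),
                                      letters = letter[levs],
                                      stringsAsFactors = FALSE)),
            class = "tukey_treatments")
}

#' @export
print.tukey_treatments <- function(x, ...) {
  cat("Tukey pairwise treatment comparison for", x$trait,
      sprintf("(alpha = %g)\n", x$alpha))
  comp <- x$comparisons
  comp$p_adj <- format_pval(comp$p_adj)
  print(comp, row.names = FALSE, digits = 4)
  print(x$letters, row.names = FALSE, digits = 4)
  invisible(x)
}
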