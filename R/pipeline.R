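#' Run the full screening analysis pipeline
#'
#' Orchestrates every stage on one input: load (or synthesize) the trait
#' table, descriptive statistics, per-trait ANOVA, Tukey treatment
#' comparison, per-treatment correlation matrices and their trajectory
#' summary, efficiency score cards and ranking, tolerance indices with the
#' composite score for both stress levels, PCA of each index matrix, and
#' (optionally) the algebraic audit of the packaged published index
#' tables.  All numeric outputs are written to `outdir` at full precision
#' (rounding is applied only by [render_report()]), each file exactly
#' once, and a manifest with per-stage status, timing, warnings and file
#' checksums is written last.  A fixed `(input-or-config, seed)` pair
#' yields byte-identical numeric outputs.
#'
#' @param input path to a long-format trait CSV (exclusive with `config`).
#' @param config a [cohort_config()] for synthetic input (exclusive with
#'   `input`; `seed` is then mandatory).
#' @param seed integer seed used for cohort generation.
#' @param outdir output directory (created; must be empty if it exists).
#' @param alpha Tukey family-wise error rate.
#' @param gmpi_mode,sts_mode,pca_scaling,polarity analysis options, see
#'   [compute_indices()], [compute_sts()], [pca_on_indices()],
#'   [score_card()].
#' @param audit also audit the packaged published index tables.
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(input = NULL, config = NULL, seed = NULL,
                         outdir, alpha = 0.05,
                         gmpi_mode = c("formula", "as_published"),
                         sts_mode = c("as_published", "standardized"),
                         pca_scaling = c("correlation", "covariance"),
                         polarity = c("literal", "biological"),
                         audit = TRUE) {
  if (is.null(input) == is.null(config))
    stop("config error: exactly one of input / config must be given")
  if (!is.null(config) && is.null(seed))
    stop("config error: seed is mandatory for synthetic input")
  gmpi_mode <- match.arg(gmpi_mode)
  sts_mode <- match.arg(sts_mode)
  pca_scaling <- match.arg(pca_scaling)
  polarity <- match.arg(polarity)
  if (dir.exists(outdir) && length(list.files(outdir)))
    stop("outdir exists and is not empty (outputs are write-once)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    config = list(input = input, synthetic = !is.null(config), seed = seed,
                  alpha = alpha, gmpi_mode = gmpi_mode, sts_mode = sts_mode,
                  pca_scaling = pca_scaling, polarity = polarity),
    version = as.character(utils::packageVersion("droughtscreen")),
    stages = list(), warnings = character(0), outputs = list())
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    df2 <- as.data.frame(df)
    num <- vapply(df2, is.numeric, TRUE)
    df2[num] <- lapply(df2[num], function(v) formatC(v, format = "g", digits = 15))
    utils::write.csv(df2, path, row.names = FALSE)
    path
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) structure(list(error = conditionMessage(e)),
                                                    class = "stage_failure")),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    elapsed <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(res, "stage_failure")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed", seconds = round(elapsed, 3),
      error = if (ok) NULL else res$error)
    if (!ok) {
      finish()
      stop("stage '", name, "' failed: ", res$error)
    }
    res
  }
  finish <- function() {
    files <- setdiff(list.files(outdir), "manifest.json")
    manifest$outputs <<- as.list(tools::md5sum(file.path(outdir, files)))
    names(manifest$outputs) <<- files
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  tab <- run_stage("input", function() {
    if (!is.null(input)) load_trait_table(input)
    else generate_cohort(config, seed = seed)
  })
  if (length(attr(tab, "dropped")))
    manifest$warnings <- c(manifest$warnings,
      paste("dropped genotypes:", paste(attr(tab, "dropped"), collapse = ", ")))

  run_stage("descriptives", function() {
    summ <- summarize_traits(tab)
    wr(summ, "descriptives.csv")
    wr(percent_change_table(summ), "percent_change_T0_T2.csv")
    summ
  })

  run_stage("anova", function() {
    wr(anova_all(tab), "anova.csv")
    letters <- do.call(rbind, lapply(
      intersect(emi_trait_set(), unique(tab$trait)), function(tr) {
        tk <- tukey_treatments(tab, tr, alpha = alpha)
        cbind(trait = tr, tk$letters)
      }))
    wr(letters, "tukey_letters.csv")
    invisible(NULL)
  })

  cors <- run_stage("correlations", function() {
    levs <- sort(unique(tab$treatment))
    traits <- intersect(emi_trait_set(), unique(tab$trait))
    ms <- lapply(levs, function(lv) correlation_by_treatment(tab, traits, lv))
    for (m in ms)
      wr(cbind(trait = rownames(m$r), as.data.frame(m$r)),
         sprintf("correlations_%s.csv", m$treatment))
    if (length(ms) >= 2) wr(correlation_shift_summary(ms), "correlation_shift.csv")
    ms
  })

  cards <- run_stage("scoring", function() {
    cards <- score_card(tab,
                        traits = intersect(emi_trait_set(), unique(tab$trait)),
                        polarity = polarity)
    wr(cards, "scorecards.csv")
    wr(attr(cards, "trait_scores"), "trait_scores.csv")
    wr(rank_genotypes(cards), "ranking.csv")
    cards
  })

  run_stage("indices", function() {
    for (stress in intersect(c("T1", "T2"), unique(tab$treatment))) {
      im <- index_matrix(tab, stress = stress, gmpi_mode = gmpi_mode,
                         sts_mode = sts_mode)
      wr(im, sprintf("indices_%s.csv", stress))
      p <- pca_on_indices(im, scaling = pca_scaling)
      wr(scree_data(p), sprintf("pca_scree_%s.csv", stress))
      wr(cbind(index = rownames(p$contributions_pct),
               as.data.frame(p$contributions_pct)),
         sprintf("pca_contributions_%s.csv", stress))
    }
    invisible(NULL)
  })

  if (audit) run_stage("audit", function() {
    for (stress in c("T1", "T2")) {
      a <- audit_published_table(published_indices(stress))
      jsonlite::write_json(
        list(inferred_means = as.list(a$inferred_means),
             gmpi_mode_inferred = a$gmpi_mode_inferred,
             sts_rows_consistent = sum(a$sts_rowsum$consistent),
             sts_rows_total = nrow(a$sts_rowsum),
             n_flagged_cells = nrow(a$flags),
             flagged_columns = unique(a$flags$column)),
        file.path(outdir, sprintf("audit_%s.json", stress)),
        auto_unbox = TRUE, digits = NA)
    }
    invisible(NULL)
  })

  finish()
  invisible(manifest)
}

#' Render a human-readable report from a pipeline output bundle
#'
#' Produces one markdown document from the files written by
#' [run_pipeline()]: descriptive and variance-analysis tables, treatment
#' letters, percent-change paragraph from control to severe stress, the
#' score ranking with its top block, the index tables' top composite
#' scores, the PCA scree, and the audit summary.  Sections whose stage
#' output is missing are marked "not run".  Only this layer rounds (2-3
#' decimals); the underlying CSVs keep full precision.
#'
#' @param outdir directory written by [run_pipeline()].
#' @return character vector of markdown lines, invisibly printed with
#'   `cat()` if interactive.
#' @export
render_report <- function(outdir) {
  have <- function(f) file.exists(file.path(outdir, f))
  rd <- function(f) utils::read.csv(file.path(outdir, f),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE)
  fmt_tab <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits)
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  out <- c("# Seedling drought-screening report", "")

  out <- c(out, "## Descriptive statistics")
  if (have("descriptives.csv")) out <- c(out, fmt_tab(rd("descriptives.csv")), "")
  else out <- c(out, "not run", "")

  out <- c(out, "## Percent change from control to severe stress")
  if (have("percent_change_T0_T2.csv")) {
    pc <- rd("percent_change_T0_T2.csv")
    para <- vapply(seq_len(nrow(pc)), function(i) {
      v <- pc$pct_change[i]
      sprintf("%s %s by %.2f%%", pc$trait[i],
              if (v >= 0) "increased" else "was reduced", abs(v))
    }, "")
    out <- c(out, paste0("From T0 to T2, ", paste(para, collapse = "; "), "."), "")
  } else out <- c(out, "not run", "")

  out <- c(out, "## Analysis of variance")
  if (have("anova.csv")) out <- c(out, fmt_tab(rd("anova.csv")), "")
  else out <- c(out, "not run", "")

  out <- c(out, "## Tukey treatment comparison")
  if (have("tukey_letters.csv")) out <- c(out, fmt_tab(rd("tukey_letters.csv")), "")
  else out <- c(out, "not run", "")

  out <- c(out, "## Efficiency scoring")
  if (have("ranking.csv")) {
    rk <- rd("ranking.csv")
    top <- rk[rk$rank == 1, ]
    out <- c(out,
             sprintf("Top-ranked genotype(s): %s (overall total %d).",
                     paste(top$genotype, collapse = ", "), top$overall[1]),
             "", fmt_tab(rd("scorecards.csv")), "")
  } else out <- c(out, "not run", "")

  for (stress in c("T1", "T2")) {
    out <- c(out, sprintf("## Tolerance indices (%s)", stress))
    f <- sprintf("indices_%s.csv", stress)
    if (have(f)) {
      im <- rd(f)
      best <- im[order(-im$sts), ][1:min(3, nrow(im)), ]
      out <- c(out,
               sprintf("Highest composite scores: %s.",
                       paste(sprintf("%s (%.2f)", best$genotype, best$sts),
                             collapse = ", ")),
               "", fmt_tab(im), "")
    } else out <- c(out, "not run", "")
    out <- c(out, sprintf("## PCA of the index matrix (%s)", stress))
    f <- sprintf("pca_scree_%s.csv", stress)
    if (have(f)) out <- c(out, fmt_tab(rd(f)), "")
    else out <- c(out, "not run", "")
  }

  out <- c(out, "## Published-table audit")
  if (have("audit_T1.json")) {
    for (stress in c("T1", "T2")) {
      a <- jsonlite::read_json(file.path(outdir,
                                         sprintf("audit_%s.json", stress)))
      out <- c(out, sprintf(
        "%s: GMPI column follows the '%s' convention; STS row sums consistent for %d/%d genotypes; inferred cohort means xc = %.3f, xt = %.3f; %d cell(s) flagged.",
        stress, a$gmpi_mode_inferred, a$sts_rows_consistent,
        a$sts_rows_total, a$inferred_means$xc, a$inferred_means$xt,
        a$n_flagged_cells))
    }
    out <- c(out, "")
  } else out <- c(out, "not run", "")

  if (interactive()) cat(out, sep = "\n")
  invisible(out)
}
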