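#' Construct and validate a trait table
#'
#' A trait table is the single input to every analysis stage: one row per
#' genotype x treatment x replicate x trait observation.  The constructor
#' validates the schema (known traits, legal treatment codes, treatment
#' coverage per trait, non-negative values, integer counts, survival rate in
#' \[0, 1\]) and rejects duplicate observation keys.
#'
#' Genotypes with any missing genotype x treatment x replicate cell for a
#' trait measured in that treatment are incomplete.  By default they are
#' dropped with a warning (mirroring a screen in which part of the panel
#' fails to germinate and is excluded listwise); with
#' `drop_incomplete = FALSE` incompleteness is an error.
#'
#' @param observations data.frame with columns `genotype`, `treatment`,
#'   `replicate`, `trait`, `value`.
#' @param schema trait metadata as returned by [trait_schema()].
#' @param drop_incomplete drop genotypes with missing cells (default `TRUE`).
#' @return An object of class `trait_table` (a validated data.frame) with
#'   attributes `design` (named vector: n_genotypes, n_treatments,
#'   n_replicates) and `dropped` (labels of removed genotypes).
#' @seealso [load_trait_table()], [generate_cohort()]
#' @export
trait_table <- function(observations, schema = trait_schema(),
                        drop_incomplete = TRUE) {
  need <- c("genotype", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  obs <- as.data.frame(observations)[need]
  obs$genotype <- as.character(obs$genotype)
  obs$treatment <- as.character(obs$treatment)
  obs$trait <- as.character(obs$trait)

  if (!is.numeric(obs$value))
    stop("parse error: non-numeric value in rows ",
         paste(utils::head(which(is.na(suppressWarnings(as.numeric(obs$value)))), 5),
               collapse = ", "))
  bad_tr <- setdiff(unique(obs$treatment), treatment_levels()$code)
  if (length(bad_tr))
    stop("unknown treatment code(s): ", paste(bad_tr, collapse = ", "))
  unknown <- setdiff(unique(obs$trait), schema$trait)
  if (length(unknown))
    stop("schema error: unknown trait(s): ", paste(unknown, collapse = ", "))

  key <- paste(obs$genotype, obs$treatment, obs$replicate, obs$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (genotype, treatment, replicate, trait) keys: ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
               collapse = "; "))

  ## treatment coverage: a trait must not appear under a treatment it is not
  ## measured in (e.g. oxidative markers under intermediate stress)
  for (tr in unique(obs$trait)) {
    allowed <- trait_treatments(tr, schema)
    extra <- setdiff(unique(obs$treatment[obs$trait == tr]), allowed)
    if (length(extra))
      stop("treatment-coverage error: trait ", tr, " measured only under ",
           paste(allowed, collapse = "/"), " but present under ",
           paste(extra, collapse = ", "))
  }

  if (anyNA(obs$value)) stop("parse error: NA values present")
  if (any(obs$value < 0))
    stop("negative value for measured trait(s): ",
         paste(unique(obs$trait[obs$value < 0]), collapse = ", "))
  for (tr in intersect(c("DSG", "NOL", "NSR"), unique(obs$trait))) {
    v <- obs$value[obs$trait == tr]
    if (any(abs(v - round(v)) > 1e-8))
      stop("trait ", tr, " must be integer-valued")
  }
  if ("SR" %in% obs$trait) {
    v <- obs$value[obs$trait == "SR"]
    if (any(v < 0 | v > 1)) stop("SR must lie in [0, 1]")
  }

  ## completeness per genotype
  reps <- sort(unique(obs$replicate))
  traits <- unique(obs$trait)
  treatments_present <- sort(unique(obs$treatment))
  incomplete <- character(0)
  for (g in unique(obs$genotype)) {
    sub <- obs[obs$genotype == g, ]
    for (tr in traits) {
      want <- intersect(trait_treatments(tr, schema), treatments_present)
      have <- sub[sub$trait == tr, ]
      n_expected <- length(want) * length(reps)
      keys <- unique(paste(have$treatment, have$replicate))
      full <- as.vector(outer(want, reps, paste))
      if (length(setdiff(full, keys))) { incomplete <- c(incomplete, g); break }
    }
  }
  if (length(incomplete)) {
    if (!drop_incomplete)
      stop("incomplete genotypes: ", paste(incomplete, collapse = ", "))
    warning("dropping incomplete genotype(s): ",
            paste(incomplete, collapse = ", "))
    obs <- obs[!obs$genotype %in% incomplete, ]
    if (!nrow(obs)) stop("no complete genotypes left")
  }

  rownames(obs) <- NULL
  structure(obs,
            class = c("trait_table", "data.frame"),
            design = c(n_genotypes  = length(unique(obs$genotype)),
                       n_treatments = length(unique(obs$treatment)),
                       n_replicates = length(reps)),
            dropped = incomplete)
}

#' Read a long-format trait table from CSV
#'
#' Expects a UTF-8 CSV with header `genotype,treatment,replicate,trait,value`
#' and treatment codes in `T0`/`T1`/`T2`.  Validation and the
#' incomplete-genotype policy are those of [trait_table()].
#'
#' @inheritParams trait_table
#' @param path file path.
#' @return A `trait_table`.
#' @export
load_trait_table <- function(path, schema = trait_schema(),
                             drop_incomplete = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.numeric(raw$value)) {
    conv <- suppressWarnings(as.numeric(raw$value))
    if (anyNA(conv) & !anyNA(raw$value))
      stop("parse error: non-numeric value at row(s) ",
           paste(utils::head(which(is.na(conv)), 5), collapse = ", "))
    raw$value <- conv
  }
  trait_table(raw, schema = schema, drop_incomplete = drop_incomplete)
}

#' Write a trait table to CSV
#'
#' Full-precision long-format output; [load_trait_table()] on the result
#' reproduces the observations exactly.
#'
#' @param table a `trait_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  df <- as.data.frame(table)
  df$value <- formatC(df$value, format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trait_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("trait_table: %d observations, %d genotypes x %d treatments x %d replicates, %d traits\n",
              nrow(x), d[["n_genotypes"]], d[["n_treatments"]],
              d[["n_replicates"]], length(unique(x$trait))))
  if (length(attr(x, "dropped")))
    cat("dropped incomplete genotypes:",
        paste(attr(x, "dropped"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

## genotype means for one trait within one treatment (named vector)
genotype_means <- function(table, trait, treatment) {
  sub <- table[table$trait == trait & table$treatment == treatment, ]
  if (!nrow(sub)) stop("no observations for ", trait, " under ", treatment)
  out <- tapply(sub$value, sub$genotype, mean)
  out[sort(names(out))]
}
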