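#' Seven dry-weight stress tolerance indices
#'
#' For a genotype with dry weight `c` under control and `t` under stress,
#' and cohort mean dry weights `xc` (control) and `xt` (stress):
#' \deqn{SSI = (1 - T/C) / (1 - \bar{x}_T/\bar{x}_C)}
#' \deqn{MPI = (C + T)/2, \quad GMPI = \sqrt{C T}, \quad HMI = 2CT/(C+T)}
#' \deqn{STI = C T / \bar{x}_C^2, \quad TI = C - T, \quad SI = T/C}
#'
#' `gmpi_mode` exists because published index tables of this family are
#' sometimes tabulated with the plain product `C*T` in the geometric-mean
#' column even though the stated definition is its square root; the
#' default `"formula"` follows the definition and `"as_published"`
#' reproduces product-style tables.  The discrepancy is surfaced by
#' [audit_published_table()], never silently reconciled.
#'
#' @param c_dw,t_dw control and stress dry weights (g); `c_dw > 0`,
#'   `t_dw >= 0`, recycled vectors.
#' @param xc,xt cohort mean dry weights (g); `xc > 0`.  When `xt == xc`
#'   SSI is undefined and returned as NA with a warning; the other indices
#'   are still returned.
#' @param gmpi_mode `"formula"` (default) or `"as_published"`.
#' @return data.frame with columns `ssi, mpi, gmpi, hmi, sti, ti, si`.
#' @seealso [compute_sts()], [recover_c_t()], [index_matrix()]
#' @export
#' @examples
#' compute_indices(1, 0.5, xc = 1, xt = 0.5)
compute_indices <- function(c_dw, t_dw, xc, xt,
                            gmpi_mode = c("formula", "as_published")) {
  gmpi_mode <- match.arg(gmpi_mode)
  if (any(c_dw <= 0)) stop("undefined SI/SSI: control dry weight must be > 0")
  if (any(t_dw < 0)) stop("stress dry weight must be >= 0")
  if (xc <= 0) stop("cohort control mean must be > 0")
  si <- t_dw / c_dw
  if (xt == xc) {
    warning("SSI undefined: cohort means equal under control and stress")
    ssi <- rep(NA_real_, length(si))
  } else {
    ssi <- (1 - si) / (1 - xt / xc)
  }
  mpi <- (c_dw + t_dw) / 2
  prod_ct <- c_dw * t_dw
  gmpi <- if (gmpi_mode == "formula") sqrt(prod_ct) else prod_ct
  hmi <- ifelse(c_dw + t_dw > 0, 2 * prod_ct / (c_dw + t_dw), 0)
  sti <- prod_ct / xc^2
  ti <- c_dw - t_dw
  data.frame(ssi = ssi, mpi = mpi, gmpi = gmpi, hmi = hmi, sti = sti,
             ti = ti, si = si)
}

#' Composite stress tolerance score
#'
#' The composite is the plain sum of the seven indices
#' (`SSI + MPI + GMPI + HMI + STI + TI + SI`), which is what published
#' score columns equal row by row.  `mode = "standardized"` instead sums
#' per-index z-scores across the cohort — an alternative reading of
#' "standardized values" sometimes attached to this composite — and is
#' clearly labelled in the result attribute.
#'
#' @param indices data.frame with the seven index columns (lower or upper
#'   case names).
#' @param mode `"as_published"` (plain sum, default) or `"standardized"`.
#' @return numeric vector of scores, with `attr(,"mode")`.
#' @export
compute_sts <- function(indices, mode = c("as_published", "standardized")) {
  mode <- match.arg(mode)
  cols <- c("ssi", "mpi", "gmpi", "hmi", "sti", "ti", "si")
  nm <- tolower(names(indices))
  if (!all(cols %in% nm))
    stop("missing index component(s): ",
         paste(setdiff(cols, nm), collapse = ", "))
  m <- as.matrix(indices[match(cols, nm)])
  if (anyNA(m)) stop("missing index component values")
  if (mode == "standardized") m <- scale(m)
  structure(as.numeric(rowSums(m)), mode = mode)
}

#' Recover control and stress dry weights from MPI and SI
#'
#' Exact algebraic inversion of the mean-productivity and stress-index
#' definitions: `C = 2 MPI / (1 + SI)` and `T = SI * C`.  This is the core
#' of the table auditor: any published row carrying MPI and SI determines
#' the dry-weight pair that generated it.
#'
#' @param mpi mean productivity index (> 0).
#' @param si stress index (>= 0; `si = -1` is non-invertible).
#' @return data.frame with columns `c_dw`, `t_dw`.
#' @export
#' @examples
#' recover_c_t(0.173, 0.891)   # ~ (0.183, 0.163)
recover_c_t <- function(mpi, si) {
  if (any(si == -1)) stop("inversion error: si = -1")
  if (any(mpi <= 0)) stop("inversion error: mpi must be > 0")
  c_dw <- 2 * mpi / (1 + si)
  data.frame(c_dw = c_dw, t_dw = si * c_dw)
}

#' Build the genotype x index matrix from a trait table
#'
#' Computes the seven indices and the composite score per genotype for one
#' stress level, using the total-dry-weight trait: `C` is the genotype mean
#' under control, `T` under the chosen stress level, and the cohort means
#' `xc`, `xt` are the averages of those genotype means (so each stress
#' level has its own `xt`).
#'
#' @param table a [trait_table()].
#' @param stress `"T1"` or `"T2"`.
#' @param trait dry-weight trait (default `"TDW"`).
#' @param gmpi_mode,sts_mode passed to [compute_indices()] /
#'   [compute_sts()].
#' @return data.frame `genotype`, seven index columns, `sts`; attributes
#'   `xc`, `xt`, `stress`.
#' @export
index_matrix <- function(table, stress = c("T1", "T2"), trait = "TDW",
                         gmpi_mode = c("formula", "as_published"),
                         sts_mode = c("as_published", "standardized")) {
  stress <- match.arg(stress)
  c_m <- genotype_means(table, trait, "T0")
  t_m <- genotype_means(table, trait, stress)
  stopifnot(identical(names(c_m), names(t_m)))
  xc <- mean(c_m)
  xt <- mean(t_m)
  ind <- compute_indices(as.numeric(c_m), as.numeric(t_m), xc, xt,
                         gmpi_mode = match.arg(gmpi_mode))
  out <- cbind(data.frame(genotype = names(c_m), stringsAsFactors = FALSE),
               ind)
  out$sts <- as.numeric(compute_sts(ind, mode = match.arg(sts_mode)))
  structure(out, xc = xc, xt = xt, stress = stress)
}

#' Audit a published index table by algebraic back-derivation
#'
#' Recovers each genotype's dry-weight pair from the printed MPI and SI
#' columns via [recover_c_t()], recomputes every index under both
#' geometric-mean conventions, infers the cohort means by least squares
#' (`xc` from the STI column, since `STI * xc^2 = C*T`; `xt` from the SSI
#' column, since `1 - SI = SSI * (1 - xt/xc)`), and reports per-cell
#' absolute deviations from the printed values.  Cells deviating by more
#' than `tol` (half a unit in the last printed place, slightly loosened to
#' absorb the table's own input rounding) are flagged.  The composite
#' column is checked as the row sum of the seven printed columns.
#'
#' @param m published index table: data.frame with columns `genotype`,
#'   `SSI`, `MPI`, `GMPI`, `HMI`, `STI`, `TI`, `SI` and optionally `STS`
#'   (as from [published_indices()]).
#' @param means optional known cohort means, list/vector with `xc`, `xt`;
#'   when supplied they replace the least-squares inference.
#' @param tol flagging tolerance for 3-decimal columns (default 0.0015).
#' @return Object of class `index_audit`: list with `recovered` (c, t per
#'   genotype), `inferred_means` (`xc`, `xt`, and the mean of recovered
#'   `c`/`t` as a cross-check), `deviations` (per genotype x column),
#'   `flags` (cells beyond `tol`), `sts_rowsum` (printed STS vs row sum),
#'   `gmpi_mode_inferred` (`"formula"` or `"as_published"`, whichever
#'   convention the printed GMPI column matches), and `non_invertible`
#'   (rows where MPI/SI cannot be inverted).
#' @export
audit_published_table <- function(m, means = NULL, tol = 0.0015) {
  need <- c("genotype", "SSI", "MPI", "GMPI", "HMI", "STI", "TI", "SI")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ok <- m$SI != -1 & m$MPI > 0
  non_invertible <- m$genotype[!ok]
  m2 <- m[ok, ]
  rec <- recover_c_t(m2$MPI, m2$SI)
  c_ <- rec$c_dw; t_ <- rec$t_dw

  if (is.null(means)) {
    ## xc: minimize sum(STI*xc^2 - c*t)^2 over xc^2
    xc <- sqrt(sum(m2$STI * c_ * t_) / sum(m2$STI^2))
    ## xt: minimize sum((1-SI) - k*SSI)^2 over k = 1 - xt/xc
    k <- sum(m2$SSI * (1 - m2$SI)) / sum(m2$SSI^2)
    xt <- xc * (1 - k)
  } else {
    xc <- means[["xc"]]; xt <- means[["xt"]]
  }

  dev_tab <- function(mode) {
    ind <- compute_indices(c_, t_, xc, xt, gmpi_mode = mode)
    d <- cbind(SSI = ind$ssi - m2$SSI, MPI = ind$mpi - m2$MPI,
               GMPI = ind$gmpi - m2$GMPI, HMI = ind$hmi - m2$HMI,
               STI = ind$sti - m2$STI, TI = ind$ti - m2$TI,
               SI = ind$si - m2$SI)
    rownames(d) <- m2$genotype
    abs(d)
  }
  dev_formula <- dev_tab("formula")
  dev_published <- dev_tab("as_published")
  gmpi_mode_inferred <- if (max(dev_published[, "GMPI"]) <
                            max(dev_formula[, "GMPI"]))
    "as_published" else "formula"
  dev <- if (gmpi_mode_inferred == "as_published") dev_published else dev_formula

  flags <- which(dev > tol, arr.ind = TRUE)
  flags <- data.frame(genotype = rownames(dev)[flags[, 1]],
                      column = colnames(dev)[flags[, 2]],
                      deviation = dev[flags],
                      stringsAsFactors = FALSE)

  sts_rowsum <- NULL
  if ("STS" %in% names(m)) {
    rs <- rowSums(m[need[-1]])
    sts_rowsum <- data.frame(genotype = m$genotype, printed = m$STS,
                             rowsum = rs, deviation = abs(rs - m$STS),
                             consistent = abs(rs - m$STS) <= tol,
                             stringsAsFactors = FALSE)
  }

  structure(list(
    recovered = data.frame(genotype = m2$genotype, c_dw = c_, t_dw = t_,
                           stringsAsFactors = FALSE),
    inferred_means = c(xc = xc, xt = xt,
                       mean_c = mean(c_), mean_t = mean(t_)),
    deviations = dev,
    flags = flags,
    sts_rowsum = sts_rowsum,
    gmpi_mode_inferred = gmpi_mode_inferred,
    gmpi_max_dev = c(formula = max(dev_formula[, "GMPI"]),
                     as_published = max(dev_published[, "GMPI"])),
    non_invertible = non_invertible,
    tol = tol), class = "index_audit")
}

#' @export
print.index_audit <- function(x, ...) {
  cat("Index-table audit\n")
  cat(sprintf("  inferred cohort means: xc = %.4f, xt = %.4f (mean recovered c = %.4f, t = %.4f)\n",
              x$inferred_means["xc"], x$inferred_means["xt"],
              x$inferred_means["mean_c"], x$inferred_means["mean_t"]))
  cat(sprintf("  GMPI column matches the '%s' convention (max dev %.4g vs %.4g)\n",
              x$gmpi_mode_inferred, min(x$gmpi_max_dev), max(x$gmpi_max_dev)))
  if (!is.null(x$sts_rowsum))
    cat(sprintf("  STS row-sum: %d/%d rows within %.4g (max dev %.4g)\n",
                sum(x$sts_rowsum$consistent), nrow(x$sts_rowsum), x$tol,
                max(x$sts_rowsum$deviation)))
  cat(sprintf("  %d cell(s) deviate beyond %.4g across %d columns\n",
              nrow(x$flags), x$tol, length(unique(x$flags$column))))
  if (nrow(x$flags)) {
    agg <- stats::aggregate(deviation ~ column, data = x$flags,
                            FUN = function(v) c(n = length(v), max = max(v)))
    cat("  flagged columns:\n")
    for (i in seq_len(nrow(agg)))
      cat(sprintf("    %-5s n = %2d  max dev = %.4g\n", agg$column[i],
                  agg$deviation[i, "n"], agg$deviation[i, "max"]))
  }
  if (length(x$non_invertible))
    cat("  non-invertible rows:", paste(x$non_invertible, collapse = ", "), "\n")
  invisible(x)
}
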