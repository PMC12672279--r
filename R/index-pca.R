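#' Principal component analysis of a stress-index matrix
#'
#' Eigendecomposition of the explicit correlation (default) or covariance
#' matrix of the genotype x index matrix.  Correlation scaling is the
#' default because the seven indices span orders of magnitude, so an
#' unstandardized PCA is dominated by the large-scale columns.  Components
#' are ordered by descending eigenvalue, and each component's sign is
#' fixed so its largest-magnitude loading is positive (biplot orientation
#' is otherwise arbitrary); with the explicit correlation matrix the
#' eigenvalue sum equals the number of variables exactly.
#'
#' @param m numeric matrix or data.frame of index values (a column per
#'   index; a `genotype` column, if present, is dropped), or the output of
#'   [index_matrix()] (its `sts` column is not part of the decomposition).
#' @param scaling `"correlation"` (default) or `"covariance"`.
#' @return Object of class `index_pca`: list with `eigenvalues`
#'   (descending), `variance_pct`, `cumulative_pct`, `loadings` (variables
#'   x components, eigenvectors scaled by the square root of their
#'   eigenvalue), `contributions_pct` (per variable per component, each
#'   column summing to 100), `scaling`, `n`.
#' @export
pca_on_indices <- function(m, scaling = c("correlation", "covariance")) {
  scaling <- match.arg(scaling)
  df <- as.data.frame(m)
  df$genotype <- NULL
  df$sts <- NULL
  df$STS <- NULL
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("index matrix must be numeric")
  if (nrow(X) < 3) stop("need >= 3 genotypes")
  if (anyNA(X)) stop("missing cells in index matrix")
  vars <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  if (scaling == "correlation" && any(sds == 0))
    stop("degenerate variable(s) under correlation scaling: ",
         paste(vars[sds == 0], collapse = ", "))
  C <- if (scaling == "correlation") stats::cor(X) else stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  ## sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  load <- V %*% diag(sqrt(ev), nrow = length(ev))
  dimnames(load) <- list(vars, paste0("PC", seq_along(ev)))
  contrib <- 100 * sweep(V^2, 2, colSums(V^2), "/")
  dimnames(contrib) <- dimnames(load)
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev,
                 variance_pct = pct,
                 cumulative_pct = cumsum(pct),
                 loadings = load,
                 contributions_pct = contrib,
                 scaling = scaling,
                 n = nrow(X)),
            class = "index_pca")
}

#' @export
print.index_pca <- function(x, ...) {
  cat(sprintf("PCA of %d observations (%s scaling)\n", x$n, x$scaling))
  print(scree_data(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-variable contributions to one component
#'
#' `100 * loading^2 / sum(loading^2)` for the chosen component.  For a
#' zero-eigenvalue component the contribution is undefined and returned as
#' NA with a warning.
#'
#' @param r an [pca_on_indices()] result.
#' @param component component index.
#' @return named percent vector summing to 100 (or NAs).
#' @export
variable_contributions <- function(r, component) {
  stopifnot(inherits(r, "index_pca"))
  if (component < 1 || component > length(r$eigenvalues))
    stop("invalid component index")
  if (r$eigenvalues[component] == 0) {
    warning("undefined contributions: zero-eigenvalue component")
    return(stats::setNames(rep(NA_real_, nrow(r$contributions_pct)),
                           rownames(r$contributions_pct)))
  }
  r$contributions_pct[, component]
}

#' Scree table with Kaiser flags
#'
#' @param r an [pca_on_indices()] result.
#' @return data.frame `component, eigenvalue, variance_pct,
#'   cumulative_pct, kaiser` (eigenvalue > 1).
#' @export
scree_data <- function(r) {
  stopifnot(inherits(r, "index_pca"))
  data.frame(component = seq_along(r$eigenvalues),
             eigenvalue = r$eigenvalues,
             variance_pct = r$variance_pct,
             cumulative_pct = r$cumulative_pct,
             kaiser = r$eigenvalues > 1)
}
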