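#' Reference-free cell-type composition components (ReFACTor style)
#'
#' Estimates sample-level scores capturing cell-type composition from the
#' methylation matrix alone, for use as EWAS covariates. The procedure is
#' sparse-PCA-like: (1) standardize each CpG site to mean 0, sd 1; (2) form
#' the rank-`k` truncated-SVD approximation of the standardized matrix;
#' (3) score each site by the Euclidean distance between its standardized row
#' and its rank-`k` reconstruction; (4) retain the `t` lowest-distance sites
#' (ties broken by genomic coordinate, so output is deterministic); (5) run
#' PCA on the retained sub-matrix and return the first `d` sample-score
#' columns, ordered by decreasing explained variance.
#'
#' Missing beta-values are mean-imputed per site before standardization; the
#' imputation is internal to this operation only. Sites with zero variance are
#' excluded from selection.
#'
#' @param x a [TwinMethExperiment-class] (its beta assay is used) or a numeric
#'   matrix, sites x individuals.
#' @param k assumed number of cell types.
#' @param t number of sites retained for the final PCA.
#' @param d number of components returned (`d <= k`).
#' @return an object of class `CellComponents`: list with `components`
#'   (individuals x d, columns `PC1..PCd`), `selected_sites` (row indices into
#'   `x`) and `params`.
#' @references Rahmani et al. (2016) sparse PCA for cell-type heterogeneity in
#'   EWAS.
#' @export
refactorComponents <- function(x, k = 5L, t = 500L, d = 5L) {
  b <- if (methods::is(x, "TwinMethExperiment")) betaValues(x) else as.matrix(x)
  n <- ncol(b)
  if (d > k) stop("d must not exceed k")
  if (n < k + 1L) stop("need at least k + 1 individuals")
  # per-site mean imputation
  if (anyNA(b)) {
    mu <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b))
    b[idx] <- mu[(idx - 1L) %% nrow(b) + 1L]
  }
  sds <- apply(b, 1, stats::sd)
  usable <- which(is.finite(sds) & sds > 0)
  if (length(usable) < t)
    stop("t = ", t, " exceeds the ", length(usable), " sites with nonzero variance")
  bs <- b[usable, , drop = FALSE]
  xs <- (bs - rowMeans(bs)) / apply(bs, 1, stats::sd)
  sv <- svd(xs, nu = 0, nv = k)
  # rank-k reconstruction distance per site, computed without forming the
  # full reconstruction: ||row||^2 - ||projection||^2
  proj <- xs %*% sv$v                         # sites x k
  dist2 <- pmax(rowSums(xs^2) - rowSums(proj^2), 0)
  ord <- order(dist2, usable)                  # tie-break: genomic order
  sel <- sort(usable[ord[seq_len(t)]])
  xsel <- xs[match(sel, usable), , drop = FALSE]
  pc <- stats::prcomp(t(xsel), center = TRUE, scale. = FALSE)
  comp <- pc$x[, seq_len(d), drop = FALSE]
  colnames(comp) <- paste0("PC", seq_len(d))
  rownames(comp) <- colnames(b)
  structure(list(components = comp, selected_sites = sel,
                 params = list(k = k, t = t, d = d),
                 sdev = pc$sdev[seq_len(d)]),
            class = "CellComponents")
}

#' @export
print.CellComponents <- function(x, ...) {
  cat("CellComponents: ", nrow(x$components), " individuals x ",
      ncol(x$components), " components (k=", x$params$k, ", t=", x$params$t,
      ")\n", sep = "")
  invisible(x)
}

#' Write cell components for audit
#' @param comp a `CellComponents` object.
#' @param path CSV path.
#' @export
writeComponentsCsv <- function(comp, path) {
  df <- data.frame(individual_id = rownames(comp$components), comp$components,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
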