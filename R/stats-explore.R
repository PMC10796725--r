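## Exploratory layer: pairwise Pearson correlations on variety-level
## feature tables and principal component analysis of the autoscaled
## matrix. Missing-data policy: pairwise-complete deletion for
## correlations, listwise (row-drop) for PCA.

#' Pairwise Pearson correlation between two table columns
#'
#' Pearson's r with pairwise-complete deletion of missing cells. A
#' constant column yields an undefined (NA) coefficient, never a number.
#'
#' @param table data.frame (or matrix) of variety-level features.
#' @param x,y column names.
#' @param subset optional row filter: logical vector, indices, or row
#'   names.
#' @return List with `r`, `n` (complete pairs used), `x`, `y`.
#' @examples
#' d <- data.frame(a = 1:5, b = 2 * (1:5) + 1)
#' pairwisePearson(d, "a", "b")$r  # 1
#' @export
pairwisePearson <- function(table, x, y, subset = NULL) {
  table <- as.data.frame(table)
  stopifnot(x %in% names(table), y %in% names(table))
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, rownames(table))
    table <- table[subset, , drop = FALSE]
  }
  xv <- table[[x]]; yv <- table[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  n <- sum(ok)
  if (n < 3)
    stop("fewer than 3 complete pairs after subsetting", call. = FALSE)
  r <- if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0) NA_real_ else
    cor(xv[ok], yv[ok])
  list(r = r, n = n, x = x, y = y)
}

#' Autoscale (unit-variance scale) a feature table
#'
#' Column-wise standardization to mean 0 and standard deviation 1 over the
#' non-missing rows of each column; the standard chemometric
#' pre-processing before PCA so every variable carries equal weight.
#'
#' @param table numeric data.frame or matrix.
#' @return Numeric matrix with attributes `center` and `scale`. Constant
#'   (or all-missing) columns are an error naming the offending columns.
#' @export
autoscale <- function(table) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad))
    stop("constant column(s): ", paste(colnames(x)[bad], collapse = ", "),
         call. = FALSE)
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Principal component analysis of an autoscaled feature table
#'
#' Rows with a missing value in any retained variable are dropped
#' (mirroring the exclusion of varieties whose granule size could not be
#' measured), the remaining matrix is autoscaled, and scores/loadings are
#' taken from its singular value decomposition. Sign convention: the
#' largest-magnitude loading of each component is positive. Explained
#' variance per component is its squared singular value as a percentage of
#' the total.
#'
#' @param table numeric data.frame or matrix (rows = varieties).
#' @param nComponents number of components to keep; must not exceed the
#'   rank of the autoscaled matrix.
#' @return A [PcaModel-class].
#' @examples
#' d <- data.frame(a = 1:6, b = (1:6) * 2 + rnorm(6, 0, 1e-3))
#' explainedVariance(runPca(d, 2))
#' @export
runPca <- function(table, nComponents = 2) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  keep <- rowSums(!is.finite(x)) == 0
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 complete rows", call. = FALSE)
  xs <- autoscale(x)
  sv <- svd(xs)
  rank <- sum(sv$d > sv$d[1] * max(dim(xs)) * .Machine$double.eps)
  if (nComponents > rank)
    stop("nComponents (", nComponents, ") exceeds the matrix rank (", rank,
         ")", call. = FALSE)
  idx <- seq_len(nComponents)
  load <- sv$v[, idx, drop = FALSE]
  scr <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], nComponents)
  ## fix signs: largest-magnitude loading per component positive
  for (j in idx) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scr[, j] <- -scr[, j]
    }
  }
  dimnames(load) <- list(colnames(xs), paste0("PC", idx))
  dimnames(scr) <- list(rownames(xs), paste0("PC", idx))
  new("PcaModel",
      scores = scr, loadings = load,
      explainedVariance = 100 * sv$d[idx]^2 / sum(sv$d^2),
      center = attr(xs, "center"), scale = attr(xs, "scale"),
      droppedRows = dropped)
}
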