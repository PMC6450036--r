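#' Remove shallow cells from a count matrix
#'
#' Keeps exactly the cells whose total count (library depth) is at least
#' `min_reads`; the default of 1000 uniquely mapped reads after UMI
#' deduplication is the conventional floor below which per-gene medians are
#' too noisy to annotate. The gene axis is never altered.
#'
#' @param m Gene-by-cell count matrix (`dgCMatrix` or dense).
#' @param min_reads Minimum column sum to retain a cell.
#' @return The matrix restricted to retained cells.
#' @export
filter_cells_by_depth <- function(m, min_reads = 1000) {
  if (ncol(m) == 0L) abort("count matrix has no cells")
  depths <- Matrix::colSums(m)
  keep <- depths >= min_reads
  if (!any(keep)) warn("depth filter removed every cell")
  m[, keep, drop = FALSE]
}

#' Remove putative doublets by score quantile
#'
#' Drops the `ceiling(fraction * n_cells)` cells with the highest doublet
#' scores (scores are produced upstream, e.g. by a nearest-neighbour doublet
#' predictor; only the cut is applied here). Ties at the cut are broken by
#' barcode lexicographic order so the result is deterministic.
#'
#' @param m Gene-by-cell count matrix.
#' @param scores Data frame with columns `barcode`, `score`, or a numeric
#'   vector named by barcode. Every cell in `m` must have a score.
#' @param fraction Fraction of cells to remove (default 0.05 = top 5%).
#' @return The matrix with the highest-scoring cells removed.
#' @export
remove_doublets <- function(m, scores, fraction = 0.05) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$barcode)
  cells <- colnames(m)
  missing <- setdiff(cells, names(scores))
  if (length(missing) > 0L) {
    abort(paste0("missing doublet score for cell(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n_remove <- ceiling(fraction * ncol(m))
  if (n_remove == 0L) return(m)
  # highest score first; barcode order (C locale) decides ties at the cut
  ord <- order(-scores[cells], cells, method = "radix")
  drop <- cells[ord][seq_len(n_remove)]
  m[, setdiff(cells, drop), drop = FALSE]
}

#' Drop clusters below the minimum size
#'
#' Removes every cluster with fewer than `min_cells` member cells (default
#' 10); smaller clusters give unstable medians and are excluded from all
#' downstream analyses. Cluster ids are not renumbered.
#'
#' @param assign Tibble with columns `barcode`, `cluster_id`.
#' @param min_cells Minimum cluster size to retain.
#' @return The assignment restricted to retained clusters.
#' @export
filter_clusters <- function(assign, min_cells = 10) {
  assign |>
    group_by(.data$cluster_id) |>
    filter(n() >= min_cells) |>
    ungroup()
}

#' Library-size normalization with log2 transform
#'
#' Scales each cell's counts to a common library size and applies
#' `log2(x + 1)`: `value(g, c) = log2(count(g, c) / depth(c) * scale + 1)`.
#' Zero counts map to exactly zero, so sparsity is preserved; the transform
#' is monotone within each cell, so expression ordering is unchanged.
#'
#' @param m Gene-by-cell UMI count matrix; every cell must have depth > 0
#'   (zero-depth cells should have been removed by [filter_cells_by_depth()]).
#' @param scale Target library size (default 10000 counts per cell).
#' @return A `dgCMatrix` of normalized values, same axes as `m`.
#' @export
normalize_counts <- function(m, scale = 10000) {
  depths <- Matrix::colSums(m)
  if (any(depths == 0)) {
    abort(paste0("cell(s) with zero depth: ",
                 paste(head(colnames(m)[depths == 0], 5), collapse = ", ")))
  }
  m <- methods::as(m, "CsparseMatrix")
  out <- m
  # operate on the non-zero slots only; column index recovered from pointers
  col_of <- rep(seq_len(ncol(m)), diff(m@p))
  out@x <- log2(m@x / depths[col_of] * scale + 1)
  out
}

#' Log-transform an RPKM matrix
#'
#' For full-length protocols expression arrives already length- and
#' depth-normalized as RPKM; a pseudo-count of 1 avoids `log2(0)`:
#' `value = log2(rpkm + 1)`.
#'
#' @param m Gene-by-cell RPKM matrix (non-negative).
#' @return A matrix of `log2(rpkm + 1)` values, same axes.
#' @export
normalize_rpkm <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x < 0)) abort("RPKM matrix contains negative values")
  out <- m
  out@x <- log2(m@x + 1)
  out
}
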