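#' Read a sparse gene-by-cell count matrix (MatrixMarket layout)
#'
#' Expects the standard trio under `dir`: `matrix.mtx` (coordinate format,
#' genes as rows), `genes.tsv` (one identifier per line, or two tab-separated
#' fields `symbol<TAB>ensembl` which are joined as `symbol_ENSEMBL`) and
#' `barcodes.tsv` (one barcode per line).
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return A `Matrix::dgCMatrix` with genes as rows and cells as columns,
#'   dimnames set from the sidecar files.
#' @export
read_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  for (p in paths) if (!file.exists(p)) abort(paste0("missing input file: ", p))
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  genes <- readr::read_tsv(paths[2], col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  gene_ids <- if (ncol(genes) >= 2L) paste(genes[[1]], genes[[2]], sep = "_") else genes[[1]]
  barcodes <- readr::read_lines(paths[3], progress = FALSE)
  if (length(gene_ids) != nrow(m)) abort("genes.tsv length does not match matrix rows")
  if (length(barcodes) != ncol(m)) abort("barcodes.tsv length does not match matrix columns")
  dimnames(m) <- list(gene_ids, barcodes)
  validate_count_matrix(m)
  m
}

#' Write a sparse count matrix as MTX plus sidecars
#'
#' @param m Gene-by-cell matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(m), file.path(dir, "genes.tsv"))
  readr::write_lines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense gene-by-cell count matrix from CSV
#'
#' First column gene identifiers, remaining columns one cell each (header row
#' holds barcodes).
#'
#' @param path CSV file path.
#' @return A `Matrix::dgCMatrix`, genes as rows.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[-1])
  rownames(m) <- genes
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (any(m@x < 0)) abort("count matrix contains negative values")
  if (anyDuplicated(rownames(m))) abort("gene identifiers are not unique")
  if (anyDuplicated(colnames(m))) abort("cell barcodes are not unique")
  invisible(m)
}

#' Read per-cell cluster assignments
#'
#' Two-column headerless TSV: barcode, 0-indexed cluster id.
#'
#' @param path TSV path.
#' @return Tibble with columns `barcode` (character) and `cluster_id`
#'   (integer).
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  readr::read_tsv(path, col_names = c("barcode", "cluster_id"),
                  col_types = "ci", progress = FALSE)
}

#' Read per-cell doublet scores
#'
#' Two-column headerless TSV: barcode, real-valued score (higher = more
#' doublet-like). Scores come from an upstream predictor; this package only
#' applies the top-fraction cut.
#'
#' @param path TSV path.
#' @return Tibble with columns `barcode` and `score`.
#' @export
read_doublet_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  readr::read_tsv(path, col_names = c("barcode", "score"),
                  col_types = "cd", progress = FALSE)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT file path.
#' @return Tibble with columns `set_name`, `description` and list-column
#'   `genes` (each entry a character vector of unique genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tbl <- tibble(
    set_name = vapply(parts, `[`, character(1), 1L),
    description = vapply(parts, function(p) if (length(p) >= 2L) p[2] else "", character(1)),
    genes = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
  if (anyDuplicated(tbl$set_name)) abort("duplicate set names in GMT file")
  tbl
}

#' Read a one-to-one ortholog map
#'
#' Two-column TSV (header optional: `from`, `to`). The map must be strictly
#' one-to-one in both directions.
#'
#' @param path TSV path.
#' @return Tibble with columns `from` and `to`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- identical(strsplit(first, "\t")[[1]][1:2], c("from", "to"))
  map <- readr::read_tsv(path, col_names = c("from", "to"),
                         col_types = "cc", skip = as.integer(has_header),
                         progress = FALSE)
  validate_ortholog_map(map)
  map
}

validate_ortholog_map <- function(map) {
  if (anyDuplicated(map$from) || anyDuplicated(map$to)) {
    abort("ortholog map is not one-to-one: duplicated gene on one side")
  }
  invisible(map)
}

#' Read a motif hit table
#'
#' Three-column TSV: `motif`, `gene`, `score`. A header row starting with
#' `motif` is skipped; multiple rows per motif-gene pair are allowed (the
#' rescoring step sums them).
#'
#' @param path TSV path.
#' @return Tibble with columns `motif`, `gene`, `score`.
#' @export
read_motif_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- startsWith(first, "motif")
  hits <- readr::read_tsv(path, col_names = c("motif", "gene", "score"),
                          col_types = "ccd", skip = as.integer(has_header),
                          progress = FALSE)
  if (any(!is.finite(hits$score))) abort("motif hit table contains non-finite scores")
  hits
}

#' Read TF co-expression modules
#'
#' Two-column TSV (`tf`, `member`), one pair per row; each module is the set
#' of members sharing a transcription factor.
#'
#' @param path TSV path.
#' @return Tibble with columns `tf` and `member`.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- startsWith(first, "tf")
  readr::read_tsv(path, col_names = c("tf", "member"), col_types = "cc",
                  skip = as.integer(has_header), progress = FALSE)
}

#' Read a motif-to-TF map
#'
#' Two-column TSV (`motif`, `tf`).
#'
#' @param path TSV path.
#' @return Tibble with columns `motif` and `tf`.
#' @export
read_motif_tf_map <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- startsWith(first, "motif")
  readr::read_tsv(path, col_names = c("motif", "tf"), col_types = "cc",
                  skip = as.integer(has_header), progress = FALSE)
}
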