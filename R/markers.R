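#' Read a marker-gene compendium from TSV
#'
#' The compendium is a tab-separated table associating marker genes with cell
#' types, together with species, organ, germ layer and the two per-marker
#' statistics the toolkit computes (ubiquitousness index and sensitivity).
#' Mandatory columns are `species`, `gene_symbol` and `cell_type`; the
#' remaining columns of the standard layout (`ui`, `sensitivity`,
#' `marker_count`, `germ_layer`, `organ`, `aliases`, `product_description`,
#' `disease`) are filled with `NA` when absent, and unknown trailing columns
#' are preserved so that a read/write round trip is lossless.
#'
#' `species` takes values `"Mm"`, `"Hs"` or `"both"`; rows flagged `"both"`
#' match either species filter and are stored once (not duplicated), so a
#' shared marker is never double-counted when gene frequencies are computed.
#' Alias lists are pipe-delimited (`"Alias1|Alias2"`) on disk and become a
#' list-column of character vectors in memory.
#'
#' @param path Path to the TSV file (UTF-8, header row required).
#' @param species Optional species filter: `"Mm"` or `"Hs"`. `NULL` keeps all
#'   rows. Rows with `species == "both"` always pass.
#' @return A tibble with one row per marker record, carrying at least the
#'   standard columns above; `aliases` is a list-column.
#' @seealso [write_marker_table()], [gene_frequency()], [marker_weight()]
#' @export
read_marker_table <- function(path, species = NULL) {
  if (!file.exists(path)) {
    abort(paste0("marker table not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("species", "gene_symbol", "cell_type")) {
    if (!col %in% names(raw)) {
      abort(paste0("marker table is missing mandatory column '", col, "'"))
    }
  }
  for (col in c("ui", "sensitivity", "marker_count", "germ_layer", "organ",
                "aliases", "product_description", "disease")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  tbl <- raw |>
    mutate(
      ui = suppressWarnings(as.numeric(.data$ui)),
      sensitivity = suppressWarnings(as.numeric(.data$sensitivity)),
      marker_count = suppressWarnings(as.integer(.data$marker_count)),
      aliases = split_aliases(.data$aliases)
    )
  validate_marker_table(tbl)
  if (!is.null(species)) {
    species <- match.arg(species, c("Mm", "Hs"))
    keep <- c(species, "both")
    tbl <- filter(tbl, .data$species %in% keep)
    if (nrow(tbl) == 0L) {
      abort(paste0("empty table: no records match species filter '", species, "'"))
    }
  }
  tbl
}

split_aliases <- function(x) {
  lapply(x, function(a) {
    if (is.na(a) || !nzchar(a)) character(0) else strsplit(a, "|", fixed = TRUE)[[1]]
  })
}

validate_marker_table <- function(tbl) {
  if (nrow(tbl) == 0L) abort("empty table: marker table has no records")
  if (any(is.na(tbl$gene_symbol) | !nzchar(tbl$gene_symbol))) {
    abort("marker table contains empty gene_symbol values")
  }
  bad_sp <- setdiff(unique(tbl$species), c("Mm", "Hs", "both"))
  if (length(bad_sp) > 0L) {
    abort(paste0("unknown species value(s): ", paste(bad_sp, collapse = ", ")))
  }
  dup <- tbl |>
    count(.data$species, .data$gene_symbol, .data$cell_type) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate (species, gene_symbol, cell_type) record(s): ",
                 paste(paste(dup$species, dup$gene_symbol, dup$cell_type, sep = "/"),
                       collapse = "; ")))
  }
  for (col in c("ui", "sensitivity")) {
    v <- tbl[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(paste0("column '", col, "' must lie in [0, 1]"))
    }
  }
  invisible(tbl)
}

#' Write a marker-gene compendium to TSV
#'
#' Inverse of [read_marker_table()]: alias list-columns are re-joined with
#' `"|"`, numeric columns are serialized at fixed precision, and any extra
#' columns present in `markers` are written after the standard ones.
#'
#' @param markers Marker tibble as returned by [read_marker_table()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  std <- c("species", "gene_symbol", "ui", "sensitivity", "marker_count",
           "cell_type", "germ_layer", "organ", "aliases",
           "product_description", "disease")
  out <- markers |>
    mutate(aliases = vapply(.data$aliases, paste, character(1), collapse = "|")) |>
    select(all_of(intersect(std, names(markers))),
           all_of(setdiff(names(markers), std)))
  write_tsv_fixed(out, path)
}

#' Gene frequency across cell types
#'
#' For every marker gene, counts the number of distinct cell types whose
#' marker set contains it. Genes listed for many cell types are broad and
#' receive weights near 1 in [marker_weight()]; genes private to one type are
#' specific and receive weights near 2.
#'
#' @param markers Marker tibble (see [read_marker_table()]).
#' @return A tibble with columns `gene` and `f` (a positive integer), one row
#'   per distinct marker gene.
#' @export
gene_frequency <- function(markers) {
  if (nrow(markers) == 0L) abort("marker table is empty")
  markers |>
    distinct(.data$gene_symbol, .data$cell_type) |>
    count(gene = .data$gene_symbol, name = "f") |>
    arrange(.data$gene)
}

#' Frequency-based marker down-weighting
#'
#' Computes the weight `w(g) = 1 + sqrt((max f - f(g)) / (max f - min f))`
#' for each requested gene, where `f(g)` is the gene's frequency across cell
#' types. Weights are bounded in `[1, 2]`: broad markers (high `f`) contribute
#' close to 1, specific markers close to 2. When every gene has the same
#' frequency the ratio is undefined; with no frequency signal no
#' down-weighting is warranted and all genes get the specific-marker weight 2.
#'
#' @param freq Frequency tibble from [gene_frequency()] (columns `gene`, `f`).
#' @param genes Genes to score; defaults to every gene in `freq`. Unknown
#'   genes are an error.
#' @return A tibble with columns `gene`, `f` and `weight`.
#' @export
marker_weight <- function(freq, genes = NULL) {
  if (is.null(genes)) genes <- freq$gene
  missing <- setdiff(genes, freq$gene)
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from frequency table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  f_min <- min(freq$f)
  f_max <- max(freq$f)
  tibble(gene = genes) |>
    left_join(freq, by = "gene") |>
    mutate(weight = if (f_max == f_min) 2 else 1 + sqrt((f_max - .data$f) / (f_max - f_min)))
}

#' Ubiquitousness index of genes across cluster profiles
#'
#' The ubiquitousness index (UI) of a gene is the fraction of cell clusters in
#' which it is expressed (median normalized expression > 0). Values near 1
#' indicate housekeeping-like behaviour; values near 0 indicate restricted
#' expression. A gene absent from every profile has UI 0.
#'
#' @param profiles Long profile tibble from [cluster_medians()] (columns
#'   `cluster_id`, `gene`, `median_expr`).
#' @param genes Genes to report; defaults to every gene on the profile axis.
#' @return A tibble with columns `gene` and `ui` (in `[0, 1]`).
#' @export
ubiquitousness_index <- function(profiles, genes = NULL) {
  n_clusters <- dplyr::n_distinct(profiles$cluster_id)
  if (n_clusters == 0L) abort("no cluster profiles supplied")
  ui <- profiles |>
    group_by(.data$gene) |>
    summarise(ui = sum(.data$median_expr > 0) / n_clusters, .groups = "drop")
  if (is.null(genes)) return(arrange(ui, .data$gene))
  tibble(gene = genes) |>
    left_join(ui, by = "gene") |>
    mutate(ui = dplyr::coalesce(.data$ui, 0))
}

#' Marker sensitivity within annotated clusters
#'
#' For each (marker gene, cell type) pair in the compendium, sensitivity is
#' the fraction of clusters annotated as that cell type in which the marker is
#' expressed (median > 0): a measure of how reliably the marker flags
#' clusters of its type. Pairs whose cell type was never called in `calls`
#' are undefined and omitted from the result.
#'
#' @param markers Marker tibble.
#' @param calls Per-cluster call tibble with columns `cluster_id` and `label`
#'   (see [annotate_sample()]).
#' @param profiles Long profile tibble from [cluster_medians()].
#' @return A tibble with columns `gene`, `cell_type`, `n_clusters` (clusters
#'   called as the type) and `sensitivity` in `[0, 1]`.
#' @export
marker_sensitivity <- function(markers, calls, profiles) {
  called <- calls |>
    filter(.data$label != "Unknown") |>
    select(cluster_id = "cluster_id", cell_type = "label")
  pairs <- markers |>
    distinct(gene = .data$gene_symbol, .data$cell_type) |>
    inner_join(called, by = "cell_type", relationship = "many-to-many")
  if (nrow(pairs) == 0L) {
    return(tibble(gene = character(), cell_type = character(),
                  n_clusters = integer(), sensitivity = numeric()))
  }
  pairs |>
    left_join(select(profiles, "cluster_id", "gene", "median_expr"),
              by = c("gene", "cluster_id")) |>
    mutate(expressed = !is.na(.data$median_expr) & .data$median_expr > 0) |>
    group_by(.data$gene, .data$cell_type) |>
    summarise(n_clusters = n(), sensitivity = mean(.data$expressed),
              .groups = "drop") |>
    arrange(.data$cell_type, .data$gene)
}
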