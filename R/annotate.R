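#' Per-cluster median expression profiles
#'
#' Represents each cell cluster by the median of its cells' normalized
#' expression, gene by gene: the unit of annotation for everything
#' downstream (CTA scoring, enrichment, gene search). The median is robust to
#' the zero-inflation of droplet data; for even-sized clusters the mean of
#' the two central values is used (the `stats::median` convention).
#'
#' @param norm Normalized gene-by-cell matrix (see [normalize_counts()]).
#' @param assign Tibble with columns `barcode`, `cluster_id`; assignments for
#'   barcodes absent from the matrix are an error, clusters of size zero
#'   cannot occur. Cells without an assignment are ignored.
#' @return A long tibble with columns `cluster_id`, `n_cells`, `gene`,
#'   `median_expr`, one row per (cluster, gene).
#' @export
cluster_medians <- function(norm, assign) {
  missing <- setdiff(assign$barcode, colnames(norm))
  if (length(missing) > 0L) {
    abort(paste0("assigned barcode(s) absent from matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  split_cells <- split(assign$barcode, assign$cluster_id)
  if (any(lengths(split_cells) == 0L)) abort("cluster with zero cells")
  genes <- rownames(norm)
  profiles <- purrr::imap(split_cells, function(cells, cid) {
    sub <- as.matrix(norm[, cells, drop = FALSE])
    tibble(
      cluster_id = as.integer(cid),
      n_cells = length(cells),
      gene = genes,
      median_expr = unname(apply(sub, 1L, median))
    )
  })
  bind_rows(profiles) |>
    arrange(.data$cluster_id, .data$gene)
}

# Marker sets per cell type with weights and the fixed marker count N.
# N counts every marker of the type, including genes absent from the matrix
# axis (those contribute Z = 0 but still enlarge the denominator).
marker_scores_frame <- function(markers, freq = NULL) {
  if (is.null(freq)) freq <- gene_frequency(markers)
  w <- marker_weight(freq)
  markers |>
    distinct(.data$cell_type, gene = .data$gene_symbol) |>
    left_join(select(w, "gene", "weight"), by = "gene") |>
    group_by(.data$cell_type) |>
    mutate(n_markers = n()) |>
    ungroup()
}

#' Cell-type activity (CTA) scores for cluster profiles
#'
#' For each (cluster, cell type) pair computes
#' `S = sum_i(Z_i * w_i) / N^(1/3)`, where the sum runs over the cell type's
#' `N` marker genes, `Z_i` is the cluster's median normalized expression of
#' marker `i` (0 if the gene is not on the matrix axis) and `w_i` is the
#' frequency weight from [marker_weight()]. The cube-root denominator adjusts
#' for cell types with long marker lists, so a type is not favoured merely
#' for having many curated markers.
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @param markers Marker tibble; only the cell types present are scored.
#' @param freq Optional precomputed [gene_frequency()] table (defaults to the
#'   frequencies of `markers` itself).
#' @return Tibble with columns `cluster_id`, `cell_type`, `n_markers`, `cta`.
#' @export
cta_score <- function(profiles, markers, freq = NULL) {
  ms <- marker_scores_frame(markers, freq)
  clusters <- distinct(profiles, .data$cluster_id)
  grid <- tidyr::crossing(clusters, distinct(ms, .data$cell_type, .data$n_markers))
  contrib <- ms |>
    inner_join(select(profiles, "cluster_id", "gene", "median_expr"),
               by = "gene", relationship = "many-to-many") |>
    group_by(.data$cluster_id, .data$cell_type) |>
    summarise(s = sum(.data$median_expr * .data$weight), .groups = "drop")
  grid |>
    left_join(contrib, by = c("cluster_id", "cell_type")) |>
    mutate(cta = dplyr::coalesce(.data$s, 0) / .data$n_markers^(1 / 3)) |>
    select("cluster_id", "cell_type", "n_markers", "cta")
}

#' Marker-overlap significance for a cluster
#'
#' One-sided Fisher's exact (hypergeometric) test on genes being expressed or
#' not: with the matrix's gene axis as the universe, successes are the cell
#' type's markers present on the axis, draws are the cluster's expressed
#' genes (median > 0) and the observed statistic is the number of expressed
#' markers. Returns the upper tail `P(X >= k)`.
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @param markers Marker tibble.
#' @return Tibble with columns `cluster_id`, `cell_type`, `p_value`.
#' @export
cluster_p_value <- function(profiles, markers) {
  universe <- unique(profiles$gene)
  if (length(universe) == 0L) abort("empty gene universe")
  marker_sets <- markers |>
    distinct(.data$cell_type, gene = .data$gene_symbol)
  expressed <- profiles |>
    filter(.data$median_expr > 0) |>
    select("cluster_id", "gene")
  n_universe <- length(universe)
  per_cluster <- expressed |> count(.data$cluster_id, name = "n_drawn")
  clusters <- distinct(profiles, .data$cluster_id) |>
    left_join(per_cluster, by = "cluster_id") |>
    mutate(n_drawn = dplyr::coalesce(.data$n_drawn, 0L))
  types <- marker_sets |>
    filter(.data$gene %in% universe) |>
    count(.data$cell_type, name = "n_markers_in_universe")
  all_types <- distinct(marker_sets, .data$cell_type) |>
    left_join(types, by = "cell_type") |>
    mutate(n_markers_in_universe = dplyr::coalesce(.data$n_markers_in_universe, 0L))
  overlap <- expressed |>
    inner_join(marker_sets, by = "gene", relationship = "many-to-many") |>
    count(.data$cluster_id, .data$cell_type, name = "k")
  tidyr::crossing(select(clusters, "cluster_id", "n_drawn"), all_types) |>
    left_join(overlap, by = c("cluster_id", "cell_type")) |>
    mutate(
      k = dplyr::coalesce(.data$k, 0L),
      p_value = phyper(.data$k - 1L, .data$n_markers_in_universe,
                       n_universe - .data$n_markers_in_universe,
                       .data$n_drawn, lower.tail = FALSE)
    ) |>
    select("cluster_id", "cell_type", "p_value")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving with the input and
#' clipped to 1. Inputs outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Annotate cell clusters against a marker compendium
#'
#' The full inference for a set of cluster profiles: CTA scores for every
#' cell type in the compendium, hypergeometric marker-overlap p-values,
#' Benjamini-Hochberg adjustment across the cell types within each cluster,
#' and winner selection. The top-ranking cell type by CTA becomes the
#' cluster's label unless its adjusted p-value exceeds `fdr_cutoff`, in which
#' case the cluster is labelled `"Unknown"`. Ties in CTA are broken by
#' smaller p-value, then alphabetically, so results are deterministic.
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @param markers Marker tibble.
#' @param freq Optional precomputed [gene_frequency()] table.
#' @param fdr_cutoff Adjusted-p threshold for accepting the winner
#'   (default 0.05; equality keeps the label).
#' @return An object of class `cta_annotation`: a list with `calls` (one row
#'   per cluster: `cluster_id`, `n_cells`, `label`, `cta`, `p_value`, `fdr`),
#'   `scores` (the full ranked table, one row per cluster and cell type) and
#'   `params`. Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @export
annotate_clusters <- function(profiles, markers, freq = NULL, fdr_cutoff = 0.05) {
  if (nrow(markers) == 0L) abort("marker table is empty")
  scores <- cta_score(profiles, markers, freq) |>
    left_join(cluster_p_value(profiles, markers), by = c("cluster_id", "cell_type")) |>
    group_by(.data$cluster_id) |>
    mutate(fdr = bh_adjust(.data$p_value)) |>
    arrange(desc(.data$cta), .data$p_value, .data$cell_type, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  sizes <- distinct(profiles, .data$cluster_id, .data$n_cells)
  calls <- scores |>
    filter(.data$rank == 1L) |>
    mutate(label = ifelse(.data$fdr <= fdr_cutoff, .data$cell_type, "Unknown")) |>
    left_join(sizes, by = "cluster_id") |>
    select("cluster_id", "n_cells", "label", top_cell_type = "cell_type",
           "cta", "p_value", "fdr") |>
    arrange(.data$cluster_id)
  structure(
    list(calls = calls, scores = scores,
         params = list(fdr_cutoff = fdr_cutoff,
                       n_cell_types = dplyr::n_distinct(markers$cell_type))),
    class = "cta_annotation"
  )
}

#' Annotate a sample end to end
#'
#' Convenience composition for a normalized matrix plus cluster assignments:
#' computes [cluster_medians()] then [annotate_clusters()]. Deterministic in
#' its inputs; permuting cells or genes does not change the calls.
#'
#' @inheritParams cluster_medians
#' @inheritParams annotate_clusters
#' @return A `cta_annotation` object (see [annotate_clusters()]); the median
#'   profiles are attached as `$profiles`.
#' @export
annotate_sample <- function(norm, assign, markers, freq = NULL, fdr_cutoff = 0.05) {
  profiles <- cluster_medians(norm, assign)
  ann <- annotate_clusters(profiles, markers, freq = freq, fdr_cutoff = fdr_cutoff)
  ann$profiles <- profiles
  ann
}

#' @export
print.cta_annotation <- function(x, ...) {
  cat("Cell-type annotation of", nrow(x$calls), "cluster(s) against",
      x$params$n_cell_types, "cell type(s)\n")
  cat("FDR cutoff:", x$params$fdr_cutoff, "\n\n")
  print(x$calls)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Ranked annotation scores in tidy form
#'
#' @param x A `cta_annotation` object.
#' @param ... Unused.
#' @return One row per (cluster, cell type): CTA score, marker count,
#'   p-value, FDR and within-cluster rank.
#' @export
tidy.cta_annotation <- function(x, ...) {
  x$scores
}

#' One-row annotation summary
#'
#' @param x A `cta_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble: clusters annotated, labelled, unknown, distinct
#'   labels and the FDR cutoff used.
#' @export
glance.cta_annotation <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$calls),
    n_labelled = sum(x$calls$label != "Unknown"),
    n_unknown = sum(x$calls$label == "Unknown"),
    n_distinct_labels = dplyr::n_distinct(x$calls$label[x$calls$label != "Unknown"]),
    fdr_cutoff = x$params$fdr_cutoff
  )
}

#' Write per-cluster annotation calls to TSV
#'
#' One row per cluster with the winning label, score and significance, plus
#' the top alternative cell types as a semicolon-joined `type:score` list.
#'
#' @param ann A `cta_annotation` object.
#' @param path Output TSV path.
#' @param n_alternatives Number of runner-up cell types to report.
#' @return The path, invisibly.
#' @export
write_annotation <- function(ann, path, n_alternatives = 5) {
  alts <- ann$scores |>
    filter(.data$rank > 1L, .data$rank <= n_alternatives + 1L) |>
    group_by(.data$cluster_id) |>
    summarise(top_alternatives = paste0(.data$cell_type, ":", format_num(.data$cta),
                                        collapse = ";"),
              .groups = "drop")
  out <- ann$calls |>
    left_join(alts, by = "cluster_id") |>
    select("cluster_id", "n_cells", "label", cta_score = "cta",
           "p_value", "fdr", "top_alternatives")
  write_tsv_fixed(out, path)
}
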