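#' Admit gene sets by size
#'
#' Keeps sets with `min_size <= |set| <= max_size` (both ends inclusive).
#' Very small sets give unstable overlap tests and very large ones are
#' uninformative, so the defaults admit 10-500 genes.
#'
#' @param sets Gene-set tibble from [read_gmt()] (list-column `genes`).
#' @param min_size,max_size Inclusive size bounds.
#' @return The filtered collection.
#' @export
filter_gene_sets <- function(sets, min_size = 10, max_size = 500) {
  sets |>
    filter(lengths(.data$genes) >= min_size, lengths(.data$genes) <= max_size)
}

#' Restrict gene sets to one-to-one orthologs
#'
#' Translates every gene through a strictly one-to-one ortholog map; genes
#' without a partner are dropped from every set. Applied before the size
#' filter, since mapping changes the effective set sizes.
#'
#' @param sets Gene-set tibble (list-column `genes`).
#' @param map Ortholog tibble with columns `from`, `to` (one-to-one both
#'   ways; violations are an error).
#' @return The collection with genes translated to the `to` namespace.
#' @export
map_orthologs <- function(sets, map) {
  validate_ortholog_map(map)
  lut <- setNames(map$to, map$from)
  sets |>
    mutate(genes = lapply(.data$genes, function(g) unname(lut[g][!is.na(lut[g])])))
}

#' One-sided gene-set enrichment test
#'
#' Upper-tail hypergeometric probability that the expressed genes overlap the
#' set at least as strongly as observed, with the supplied universe as the
#' population. The set is intersected with the universe before testing.
#'
#' @param expressed Character vector of expressed genes (subset of universe).
#' @param gene_set Character vector, the gene set.
#' @param universe Character vector, all testable genes.
#' @return Upper-tail p-value `P(X >= k)`.
#' @export
gsa_test <- function(expressed, gene_set, universe) {
  if (length(universe) == 0L) abort("empty gene universe")
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  expressed <- intersect(unique(expressed), universe)
  k <- length(intersect(expressed, gene_set))
  phyper(k - 1L, length(gene_set), length(universe) - length(gene_set),
         length(expressed), lower.tail = FALSE)
}

#' Bonferroni selection of significant sets
#'
#' Selects the sets whose raw p-value is at most `alpha / n_tested`, the
#' family-wise control used for gene-set activity calls (default alpha 0.01).
#'
#' @param p Named numeric vector or tibble with columns `set_name`, `p`.
#' @param alpha Family-wise error rate.
#' @return Character vector of selected set names.
#' @export
bonferroni_select <- function(p, alpha = 0.01) {
  if (is.data.frame(p)) p <- setNames(p$p, p$set_name)
  if (length(p) == 0L) return(character(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  names(p)[p <= alpha / length(p)]
}

#' Gene-set activity per cluster
#'
#' Runs the enrichment test for every retained gene set in every cluster. A
#' cluster's expressed genes are those with median normalized expression > 0
#' (the same rule used for cell-type inference); the universe is the matrix's
#' gene axis. Sets are first passed through the optional ortholog map, then
#' the size filter; Bonferroni significance counts only the tested
#' (size-admissible) sets.
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @param sets Gene-set tibble from [read_gmt()].
#' @param ortholog_map Optional ortholog tibble (`from`, `to`) applied before
#'   size filtering.
#' @param alpha Bonferroni family-wise error rate (default 0.01).
#' @param min_size,max_size Set-size admission window (default 10-500).
#' @return Tibble with one row per (cluster, set): `cluster_id`, `set_name`,
#'   `overlap`, `set_size`, `p`, `significant`.
#' @export
gsa_clusters <- function(profiles, sets, ortholog_map = NULL, alpha = 0.01,
                         min_size = 10, max_size = 500) {
  if (!is.null(ortholog_map)) sets <- map_orthologs(sets, ortholog_map)
  sets <- filter_gene_sets(sets, min_size, max_size)
  universe <- unique(profiles$gene)
  n_tested <- nrow(sets)
  expressed_by_cluster <- profiles |>
    filter(.data$median_expr > 0) |>
    group_by(.data$cluster_id) |>
    summarise(expressed = list(.data$gene), .groups = "drop")
  clusters <- distinct(profiles, .data$cluster_id) |>
    left_join(expressed_by_cluster, by = "cluster_id") |>
    mutate(expressed = lapply(.data$expressed, function(e) e %||% character(0)))
  if (n_tested == 0L) {
    return(tibble(cluster_id = integer(), set_name = character(),
                  overlap = integer(), set_size = integer(), p = numeric(),
                  significant = logical()))
  }
  res <- tidyr::crossing(select(clusters, "cluster_id"), select(sets, "set_name")) |>
    left_join(clusters, by = "cluster_id") |>
    left_join(select(sets, "set_name", "genes"), by = "set_name") |>
    mutate(
      set_in_universe = lapply(.data$genes, intersect, universe),
      overlap = purrr::map2_int(.data$expressed, .data$set_in_universe,
                                ~ length(intersect(.x, .y))),
      set_size = lengths(.data$set_in_universe),
      p = purrr::map2_dbl(.data$expressed, .data$set_in_universe,
                          ~ gsa_test(.x, .y, universe)),
      significant = .data$p <= alpha / n_tested
    ) |>
    select("cluster_id", "set_name", "overlap", "set_size", "p", "significant") |>
    arrange(.data$cluster_id, .data$p, .data$set_name)
  res
}
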