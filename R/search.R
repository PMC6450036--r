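#' Within-cluster expression ranks
#'
#' Ranks the genes of each cluster by descending median expression: the most
#' highly expressed gene always has rank 1. Only expressed genes (median > 0)
#' receive a rank; ties share the minimum rank (competition ranking), so the
#' next distinct value's rank skips accordingly. Ranks make expression levels
#' comparable across datasets with different depths and normalizations.
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @return Tibble with columns `cluster_id`, `gene`, `median_expr`, `rank`;
#'   unexpressed genes are omitted.
#' @export
expression_rank <- function(profiles) {
  profiles |>
    filter(.data$median_expr > 0) |>
    group_by(.data$cluster_id) |>
    mutate(rank = as.integer(rank(-.data$median_expr, ties.method = "min"))) |>
    ungroup() |>
    select("cluster_id", "gene", "median_expr", "rank") |>
    arrange(.data$cluster_id, .data$rank, .data$gene)
}

#' Build a searchable index over annotated cluster profiles
#'
#' Combines median profiles with their cell-type calls and sample metadata
#' into the flat structure the search interface queries. Indices from several
#' samples can be concatenated with [bind_cluster_indexes()].
#'
#' @param profiles Long profile tibble from [cluster_medians()].
#' @param calls Call tibble (`cluster_id`, `label`), e.g. from a
#'   `cta_annotation`'s `$calls`.
#' @param sample_id Sample identifier attached to every row.
#' @param tissue,species Optional metadata tags.
#' @return An object of class `cluster_index`: a list of `meta` (one row per
#'   cluster) and `profiles` (long, with `sample` column).
#' @export
build_cluster_index <- function(profiles, calls, sample_id = "sample1",
                                tissue = NA_character_, species = NA_character_) {
  meta <- calls |>
    select("cluster_id", "label") |>
    mutate(sample = sample_id, tissue = tissue, species = species) |>
    select("sample", "cluster_id", "tissue", "species", "label")
  prof <- profiles |>
    mutate(sample = sample_id) |>
    select("sample", "cluster_id", "gene", "median_expr")
  structure(list(meta = meta, profiles = prof), class = "cluster_index")
}

#' Concatenate cluster indices from several samples
#'
#' @param ... `cluster_index` objects.
#' @return A single `cluster_index`; (sample, cluster) pairs must be unique.
#' @export
bind_cluster_indexes <- function(...) {
  idx <- list(...)
  meta <- bind_rows(lapply(idx, `[[`, "meta"))
  if (anyDuplicated(meta[c("sample", "cluster_id")])) {
    abort("duplicate (sample, cluster_id) across indices")
  }
  structure(list(meta = meta,
                 profiles = bind_rows(lapply(idx, `[[`, "profiles"))),
            class = "cluster_index")
}

#' Resolve gene symbols through marker aliases
#'
#' Queries may use aliases instead of official symbols. A query matching an
#' official symbol resolves to itself; otherwise the marker compendium's
#' alias lists are consulted. An alias mapping to two or more distinct
#' symbols is ambiguous and rejected with the candidates listed; an unknown
#' symbol passes through unchanged.
#'
#' @param genes Character vector of query symbols.
#' @param markers Marker tibble with `gene_symbol` and `aliases` columns.
#' @return Character vector of resolved official symbols.
#' @export
resolve_gene_alias <- function(genes, markers) {
  alias_map <- markers |>
    select("gene_symbol", "aliases") |>
    tidyr::unnest_longer("aliases", values_to = "alias") |>
    distinct(.data$alias, .data$gene_symbol)
  vapply(genes, function(g) {
    if (g %in% markers$gene_symbol) return(g)
    hits <- unique(alias_map$gene_symbol[alias_map$alias == g])
    if (length(hits) == 0L) return(g)
    if (length(hits) > 1L) {
      abort(paste0("ambiguous alias '", g, "': matches ",
                   paste(sort(hits), collapse = ", ")))
    }
    hits
  }, character(1), USE.NAMES = FALSE)
}

#' Boolean gene search over cluster profiles
#'
#' Finds the cell clusters where every `require` gene is expressed (median
#' expression > 0) and every `exclude` gene is not (median exactly 0),
#' mirroring an AND/NOT query. Result rows carry the within-cluster
#' expression rank of each required gene.
#'
#' @param index A `cluster_index` from [build_cluster_index()].
#' @param require Genes that must be expressed.
#' @param exclude Genes that must be unexpressed; must not overlap `require`.
#' @param markers Optional marker tibble for alias resolution of the query.
#' @return Tibble with one row per (cluster, required gene): `species`,
#'   `gene`, `tissue`, `sample`, `cluster_id`, `cell_type`, `rank`. With an
#'   empty `require` list, matching clusters are returned once with `gene`
#'   and `rank` as `NA`.
#' @export
search_clusters <- function(index, require = character(), exclude = character(),
                            markers = NULL) {
  if (!is.null(markers)) {
    require <- resolve_gene_alias(require, markers)
    exclude <- resolve_gene_alias(exclude, markers)
  }
  both <- intersect(require, exclude)
  if (length(both) > 0L) {
    abort(paste0("gene(s) both required and excluded: ", paste(both, collapse = ", ")))
  }
  prof <- index$profiles
  keys <- distinct(prof, .data$sample, .data$cluster_id)
  cluster_ok <- function(sample, cluster_id) {
    p <- prof[prof$sample == sample & prof$cluster_id == cluster_id, ]
    med <- setNames(p$median_expr, p$gene)
    req_med <- med[require]
    exc_med <- med[exclude]
    all(!is.na(req_med) & req_med > 0) &&
      all(is.na(exc_med) | exc_med == 0)
  }
  keys$hit <- purrr::pmap_lgl(keys, cluster_ok)
  hits <- filter(keys, .data$hit) |> select("sample", "cluster_id")
  meta <- index$meta
  if (length(require) == 0L) {
    return(hits |>
      left_join(meta, by = c("sample", "cluster_id")) |>
      mutate(gene = NA_character_, rank = NA_integer_) |>
      select("species", "gene", "tissue", "sample", "cluster_id",
             cell_type = "label", "rank"))
  }
  ranks <- prof |>
    dplyr::semi_join(hits, by = c("sample", "cluster_id")) |>
    group_by(.data$sample, .data$cluster_id) |>
    filter(.data$median_expr > 0) |>
    mutate(rank = as.integer(rank(-.data$median_expr, ties.method = "min"))) |>
    ungroup()
  hits |>
    tidyr::crossing(gene = require) |>
    left_join(select(ranks, "sample", "cluster_id", "gene", "rank"),
              by = c("sample", "cluster_id", "gene")) |>
    left_join(meta, by = c("sample", "cluster_id")) |>
    select("species", "gene", "tissue", "sample", "cluster_id",
           cell_type = "label", "rank") |>
    arrange(.data$sample, .data$cluster_id, .data$gene)
}

#' Summarize search results by cell type
#'
#' Counts matching cell clusters per inferred cell-type label (each cluster
#' counted once, regardless of how many query genes it matched).
#'
#' @param rows Search result tibble from [search_clusters()].
#' @return Tibble with columns `cell_type` and `n_clusters`, descending.
#' @export
summarize_by_cell_type <- function(rows) {
  rows |>
    distinct(.data$sample, .data$cluster_id, .data$cell_type) |>
    count(.data$cell_type, name = "n_clusters") |>
    arrange(desc(.data$n_clusters), .data$cell_type)
}
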