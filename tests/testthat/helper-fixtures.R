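# Shared fixture builders and independent oracles.

# Minimal marker tibble: sets = named list(cell_type = character vector).
tiny_markers <- function(sets, species = "both") {
  dplyr::bind_rows(lapply(names(sets), function(ct) {
    tibble::tibble(species = species, gene_symbol = sets[[ct]], cell_type = ct)
  })) |>
    dplyr::mutate(ui = NA_real_, sensitivity = NA_real_,
                  marker_count = NA_integer_, germ_layer = "layer",
                  organ = "organ", aliases = lapply(gene_symbol, function(g) character(0)),
                  product_description = NA_character_, disease = NA_character_)
}

# Dense gene-by-cell matrix as dgCMatrix with names.
tiny_matrix <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# Long profile tibble from a named list of gene -> median vectors per cluster.
tiny_profiles <- function(cluster_medians_list, n_cells = 10L) {
  dplyr::bind_rows(lapply(seq_along(cluster_medians_list), function(i) {
    med <- cluster_medians_list[[i]]
    tibble::tibble(cluster_id = i - 1L, n_cells = n_cells,
                   gene = names(med), median_expr = unname(med))
  }))
}

# Independent upper-tail hypergeometric oracle: enumerate every overlap
# outcome j >= k with binomial coefficients (no phyper).
hyper_tail_oracle <- function(k, n_universe, n_success, n_drawn) {
  j <- seq(max(k, 0), min(n_success, n_drawn))
  if (length(j) == 0L) return(if (k <= 0) 1 else 0)
  sum(choose(n_success, j) * choose(n_universe - n_success, n_drawn - j)) /
    choose(n_universe, n_drawn)
}

# Independent BH step-up oracle written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
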