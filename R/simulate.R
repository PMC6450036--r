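#' Simulation configuration
#'
#' Bundles the parameters of the synthetic scRNA-seq fixtures with defaults
#' chosen to emulate a small droplet-protocol sample: a handful of cell types
#' with curated-sized marker panels, clusters comfortably above the 10-cell
#' analysis floor, marker genes expressed at clearly detectable means against
#' a sparse background, moderate dropout, and library depths that pass the
#' 1000-read quality filter.
#'
#' @param n_cell_types Number of planted cell types.
#' @param markers_per_type Markers curated for each type.
#' @param n_clusters Number of cell clusters (planted types are recycled
#'   across clusters).
#' @param cells_per_cluster Cells per cluster.
#' @param n_background_genes Genes that are never markers.
#' @param marker_mean Expected (pre-depth-scaling) count of a planted type's
#'   markers in its own clusters.
#' @param background_mean Expected count of every other gene.
#' @param dropout_prob Probability a marker count is zeroed in a given cell
#'   (technical dropout).
#' @param library_depth_range Two integers; each cell's target depth is drawn
#'   uniformly from this range and all Poisson means are scaled to meet it.
#' @param share_fraction Fraction of each type's markers shared with the next
#'   type (exercises gene frequencies above 1 and the down-weighting path).
#' @param seed Integer seed; all generators are pure functions of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 5, markers_per_type = 20, n_clusters = 8,
                       cells_per_cluster = 50, n_background_genes = 2000,
                       marker_mean = 5.0, background_mean = 0.1,
                       dropout_prob = 0.3, library_depth_range = c(1200L, 1600L),
                       share_fraction = 0, seed = 42L) {
  cfg <- list(n_cell_types = n_cell_types, markers_per_type = markers_per_type,
              n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
              n_background_genes = n_background_genes, marker_mean = marker_mean,
              background_mean = background_mean, dropout_prob = dropout_prob,
              library_depth_range = library_depth_range,
              share_fraction = share_fraction, seed = as.integer(seed))
  stopifnot(
    cfg$n_cell_types > 0, cfg$markers_per_type > 0, cfg$n_clusters > 0,
    cfg$cells_per_cluster > 0, cfg$n_background_genes > 0,
    cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
    cfg$share_fraction >= 0, cfg$share_fraction <= 1,
    length(cfg$library_depth_range) == 2
  )
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer((as.numeric(seed) + offset) %% 2147483647))
  force(code)
}

#' Generate a synthetic marker compendium
#'
#' Builds `n_cell_types` cell types with `markers_per_type` markers each;
#' with a positive `share_fraction`, that fraction of each type's markers is
#' borrowed from the next type, producing genes with frequency above 1.
#' Deterministic in the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A marker tibble in the [read_marker_table()] layout.
#' @export
simulate_markers <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_shared <- floor(cfg$share_fraction * cfg$markers_per_type)
  types <- sprintf("CellType%02d", seq_len(cfg$n_cell_types))
  own <- lapply(seq_len(cfg$n_cell_types), function(t) {
    sprintf("T%02dM%03d", t, seq_len(cfg$markers_per_type))
  })
  rows <- lapply(seq_len(cfg$n_cell_types), function(t) {
    nxt <- (t %% cfg$n_cell_types) + 1L
    genes <- own[[t]]
    if (n_shared > 0 && nxt != t) {
      genes <- unique(c(genes[seq_len(cfg$markers_per_type - n_shared)],
                        own[[nxt]][seq_len(n_shared)]))
    }
    tibble(species = "both", gene_symbol = genes, cell_type = types[t])
  })
  bind_rows(rows) |>
    mutate(ui = NA_real_, sensitivity = NA_real_,
           marker_count = NA_integer_, germ_layer = "synthetic",
           organ = "synthetic", aliases = lapply(.data$gene_symbol, function(g)
             paste0(g, "-alias")),
           product_description = NA_character_, disease = NA_character_) |>
    select("species", "gene_symbol", "ui", "sensitivity", "marker_count",
           "cell_type", "germ_layer", "organ", "aliases",
           "product_description", "disease")
}

#' Generate a synthetic count matrix with planted cell types
#'
#' Each cluster is assigned a planted cell type (types recycled over
#' clusters). Within a cell, markers of the planted type draw counts from a
#' Poisson at `marker_mean` and are then zeroed with probability
#' `dropout_prob`; every other gene draws from a Poisson at
#' `background_mean`. All means are scaled per cell so the expected depth
#' matches a uniform draw from `library_depth_range`, which keeps default
#' cells above the 1000-read floor while leaving background genes mostly
#' unexpressed at the median.
#'
#' @param cfg A [sim_config()].
#' @param markers Marker tibble from [simulate_markers()] (defaults to
#'   generating one from `cfg`).
#' @return A list: `counts` (sparse gene-by-cell `dgCMatrix`), `clusters`
#'   (tibble `barcode`, `cluster_id`), `truth` (tibble `cluster_id`,
#'   `cell_type`).
#' @export
simulate_counts <- function(cfg, markers = simulate_markers(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  types <- sprintf("CellType%02d", seq_len(cfg$n_cell_types))
  marker_sets <- split(markers$gene_symbol, markers$cell_type)
  genes <- c(sort(unique(markers$gene_symbol)),
             sprintf("BG%05d", seq_len(cfg$n_background_genes)))
  n_cells <- cfg$n_clusters * cfg$cells_per_cluster
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  cluster_of <- rep(seq_len(cfg$n_clusters) - 1L, each = cfg$cells_per_cluster)
  planted <- types[(seq_len(cfg$n_clusters) - 1L) %% cfg$n_cell_types + 1L]
  counts <- with_sim_seed(cfg$seed, 1L, {
    cols <- lapply(seq_len(n_cells), function(ci) {
      type <- planted[cluster_of[ci] + 1L]
      is_marker <- genes %in% marker_sets[[type]]
      mu <- ifelse(is_marker, cfg$marker_mean, cfg$background_mean)
      expected <- sum(mu * ifelse(is_marker, 1 - cfg$dropout_prob, 1))
      target <- runif(1, cfg$library_depth_range[1], cfg$library_depth_range[2])
      s <- if (expected > 0) target / expected else 0
      x <- rpois(length(genes), mu * s)
      keep <- !is_marker | (rbinom(length(genes), 1L, 1 - cfg$dropout_prob) == 1L)
      x * keep
    })
    m <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    dimnames(m) <- list(genes, barcodes)
    methods::as(m, "CsparseMatrix")
  })
  list(
    counts = counts,
    clusters = tibble(barcode = barcodes, cluster_id = cluster_of),
    truth = tibble(cluster_id = seq_len(cfg$n_clusters) - 1L, cell_type = planted)
  )
}

#' Generate a synthetic motif-enrichment fixture
#'
#' Builds TF-centred co-expression modules, a motif hit table and a
#' motif-to-TF map with planted signal: each module's own motif scores the
#' module members at the very top of its ranking, while decoy motifs score
#' random genes. Used to exercise hit rescoring, recovery AUCs and the KDE
#' significance test with known ground truth.
#'
#' @param cfg A [sim_config()] (only the seed is used from the shared
#'   config).
#' @param n_modules Number of TF modules with planted motifs.
#' @param module_size Members per module.
#' @param n_motifs Total motifs (planted + decoys).
#' @param n_pool_genes Size of the gene pool motifs draw targets from.
#' @param genes_per_motif Genes scored by each motif.
#' @return A list: `hits` (tibble `motif`, `gene`, `score`), `modules`
#'   (tibble `tf`, `member`), `motif_tf_map` (tibble `motif`, `tf`), `truth`
#'   (tibble `tf`, `motif`, `planted`).
#' @export
simulate_motif_fixture <- function(cfg, n_modules = 3, module_size = 15,
                                   n_motifs = 50, n_pool_genes = 1000,
                                   genes_per_motif = 300) {
  stopifnot(inherits(cfg, "sim_config"))
  pool <- sprintf("G%05d", seq_len(n_pool_genes))
  motifs <- sprintf("M%03d", seq_len(n_motifs))
  tfs <- sprintf("TF%02d", seq_len(n_motifs))
  with_sim_seed(cfg$seed, 2L, {
    modules <- bind_rows(lapply(seq_len(n_modules), function(i) {
      tibble(tf = tfs[i], member = sample(pool, module_size))
    }))
    member_sets <- split(modules$member, modules$tf)
    hits <- bind_rows(lapply(seq_len(n_motifs), function(i) {
      if (i <= n_modules) {
        members <- member_sets[[tfs[i]]]
        fillers <- sample(setdiff(pool, members), genes_per_motif - length(members))
        tibble(
          motif = motifs[i],
          gene = c(members, fillers),
          score = c(runif(length(members), 90, 100), runif(length(fillers), 1, 50))
        )
      } else {
        tibble(motif = motifs[i], gene = sample(pool, genes_per_motif),
               score = runif(genes_per_motif, 1, 100))
      }
    }))
    # duplicate a slice of rows so rescoring's per-pair summation is exercised
    dup <- hits |> dplyr::slice_sample(prop = 0.1) |> mutate(score = .data$score / 10)
    list(
      hits = bind_rows(hits, dup),
      modules = modules,
      motif_tf_map = tibble(motif = motifs, tf = tfs),
      truth = tibble(tf = tfs[seq_len(n_modules)], motif = motifs[seq_len(n_modules)],
                     planted = TRUE)
    )
  })
}

#' Write a full synthetic fixture set to disk
#'
#' Materializes the generated inputs in the on-disk formats the readers
#' accept: MTX trio, `clusters.tsv`, `markers.tsv`, `truth.tsv` and (when
#' `motifs = TRUE`) `hits.tsv`, `modules.tsv`, `motif_map.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param motifs Also write the motif fixture.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(cfg, dir, motifs = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  markers <- simulate_markers(cfg)
  sim <- simulate_counts(cfg, markers)
  write_mtx(sim$counts, dir)
  readr::write_tsv(sim$clusters, file.path(dir, "clusters.tsv"), col_names = FALSE,
                   progress = FALSE)
  write_marker_table(markers, file.path(dir, "markers.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  if (motifs) {
    fx <- simulate_motif_fixture(cfg)
    write_tsv_fixed(fx$hits, file.path(dir, "hits.tsv"))
    readr::write_tsv(fx$modules, file.path(dir, "modules.tsv"), progress = FALSE)
    readr::write_tsv(fx$motif_tf_map, file.path(dir, "motif_map.tsv"), progress = FALSE)
  }
  invisible(dir)
}
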