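#' Combine and rank motif hits per gene
#'
#' Motif scanners report several hits per gene within the promoter-proximal
#' window, often redundant occurrences of the same motif. The hits are
#' rescored by summing all scores for each (motif, gene) pair; per motif the
#' genes are then ranked by descending combined score, truncated to the top
#' `top_n` (default 200), with lexicographic gene order breaking score ties
#' deterministically.
#'
#' @param hits Tibble with columns `motif`, `gene`, `score` (multiple rows
#'   per pair allowed; see [read_motif_hits()]).
#' @param top_n Ranking truncation length.
#' @return Tibble with columns `motif`, `gene`, `score` (combined), `rank`
#'   (1 = best), at most `top_n` rows per motif.
#' @export
rescore_hits <- function(hits, top_n = 200) {
  if (nrow(hits) == 0L) abort("motif hit table is empty")
  hits |>
    group_by(.data$motif, .data$gene) |>
    summarise(score = sum(.data$score), .groups = "drop") |>
    arrange(.data$motif, desc(.data$score), .data$gene) |>
    group_by(.data$motif) |>
    mutate(rank = row_number()) |>
    slice_head(n = top_n) |>
    ungroup()
}

#' Recovery AUC of a gene module along a motif ranking
#'
#' The recovery curve `R(t)` is the fraction of module members found within
#' the top `t` ranked genes, evaluated for `t = 1..L` where `L` is the
#' ranking cap (default 200). The AUC is the mean of `R(t)` over those
#' positions, in `[0, 1]`: 1 when all members head the ranking, 0 when none
#' appear. Members absent from the ranking never contribute.
#'
#' @param members Character vector of module genes (non-empty).
#' @param ranking Character vector of ranked genes, best first (e.g. one
#'   motif's `gene` column from [rescore_hits()]).
#' @param top_n Ranking cap `L`.
#' @return The AUC, a scalar in `[0, 1]`.
#' @export
recovery_auc <- function(members, ranking, top_n = 200) {
  members <- unique(members)
  if (length(members) == 0L) abort("module has no members")
  ranks <- match(members, ranking[seq_len(min(top_n, length(ranking)))])
  ranks <- ranks[!is.na(ranks)]
  if (length(ranks) == 0L) return(0)
  # a member at rank r contributes (L - r + 1) of the L curve evaluations
  sum(top_n - ranks + 1) / (top_n * length(members))
}

#' Upper-tail significance from a kernel density estimate
#'
#' Fits a Gaussian-kernel density (Silverman's rule-of-thumb bandwidth) to a
#' background sample and integrates it from the observed value to +Inf by
#' trapezoidal quadrature, yielding the estimated probability of a background
#' value at least as large as the observation. Used because AUC backgrounds
#' over motif collections are frequently non-Gaussian, which rules out a
#' simple z-score. If the background is degenerate (zero spread) the
#' empirical tail fraction is returned instead.
#'
#' @param observed Observed statistic (e.g. a module's AUC for one motif).
#' @param background Numeric background sample (at least 10 values).
#' @return Tail probability clipped to `[0, 1]`; monotonically non-increasing
#'   in `observed`.
#' @export
kde_significance <- function(observed, background) {
  if (length(background) < 10L) abort("background needs at least 10 values")
  if (stats::sd(background) == 0) {
    return(mean(background >= observed))
  }
  d <- density(background, kernel = "gaussian", bw = "nrd0", n = 2048,
               from = min(background) - 3 * stats::sd(background),
               to = max(background) + 3 * stats::sd(background))
  keep <- d$x >= observed
  if (!any(keep)) return(0)
  x <- c(observed, d$x[keep])
  y <- c(stats::approx(d$x, d$y, xout = observed, rule = 2)$y, d$y[keep])
  # trapezoidal quadrature of the fitted density over [observed, +Inf)
  tail_mass <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  min(max(tail_mass, 0), 1)
}

#' Motif-support test for co-expression modules (regulon construction)
#'
#' For each transcription-factor-centred co-expression module, computes the
#' recovery AUC of the module along every motif's ranking; the AUCs over all
#' motifs form the genomic background against which the TF's own motifs are
#' judged. A motif supports the module when its KDE tail significance falls
#' below `threshold` (default 0.05); a regulon is emitted when at least one
#' of the TF's motifs is supported. Target genes are the module members found
#' in the supported motif's top-`top_n` ranking.
#'
#' @param modules Tibble with columns `tf`, `member` (see [read_modules()]).
#' @param hits Motif hit tibble (`motif`, `gene`, `score`).
#' @param motif_tf_map Tibble with columns `motif`, `tf`. Modules whose TF
#'   has no mapped motif are skipped with a warning.
#' @param top_n Ranking cap (default 200).
#' @param threshold Significance threshold for motif support (default 0.05).
#' @return Tibble with one row per supported (TF, motif): `tf`, `motif`,
#'   `auc`, `significance`, `n_targets` and list-column `targets`.
#' @export
build_regulons <- function(modules, hits, motif_tf_map, top_n = 200,
                           threshold = 0.05) {
  empty <- tibble(tf = character(), motif = character(), auc = numeric(),
                  significance = numeric(), n_targets = integer(),
                  targets = list())
  if (nrow(hits) == 0L || nrow(modules) == 0L) return(empty)
  rankings <- rescore_hits(hits, top_n = top_n)
  ranked_genes <- split(rankings$gene, rankings$motif)
  module_sets <- modules |>
    group_by(.data$tf) |>
    summarise(members = list(unique(.data$member)), .groups = "drop")
  out <- purrr::pmap(module_sets, function(tf, members) {
    own_motifs <- motif_tf_map$motif[motif_tf_map$tf == tf]
    own_motifs <- intersect(own_motifs, names(ranked_genes))
    if (length(own_motifs) == 0L) {
      warn(paste0("no motif mapped for transcription factor '", tf, "'; module skipped"))
      return(empty)
    }
    background <- vapply(ranked_genes, function(r) recovery_auc(members, r, top_n),
                         numeric(1))
    tibble(
      tf = tf,
      motif = own_motifs,
      auc = unname(background[own_motifs]),
      significance = vapply(own_motifs, function(m)
        kde_significance(background[[m]], unname(background)), numeric(1))
    ) |>
      filter(.data$significance < threshold) |>
      mutate(
        targets = lapply(.data$motif, function(m) intersect(members, ranked_genes[[m]])),
        n_targets = lengths(.data$targets)
      ) |>
      select("tf", "motif", "auc", "significance", "n_targets", "targets")
  })
  bind_rows(out) |> arrange(.data$tf, .data$significance, .data$motif)
}

#' Write a regulon table to TSV
#'
#' @param regulons Tibble from [build_regulons()].
#' @param path Output path. Targets are semicolon-joined.
#' @return The path, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  out <- regulons |>
    mutate(targets = vapply(.data$targets, paste, character(1), collapse = ";"))
  write_tsv_fixed(out, path)
}
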