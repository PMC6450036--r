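test_that("cluster medians use order statistics with the midpoint convention", {
  m <- tiny_matrix(cbind(c(0, 1), c(0, 3), c(0, 9), c(5, 2), c(9, 7)),
                   genes = c("gA", "gB"))
  assign <- tibble::tibble(barcode = colnames(m),
                           cluster_id = c(0L, 0L, 0L, 0L, 0L))
  prof <- cluster_medians(m, assign)
  expect_equal(prof$median_expr[prof$gene == "gA"], 0)  # {0,0,0,5,9}

  two <- tiny_matrix(cbind(1, 3), genes = "gA")
  prof2 <- cluster_medians(two, tibble::tibble(barcode = colnames(two),
                                               cluster_id = c(0L, 0L)))
  expect_equal(prof2$median_expr, 2.0)  # mean of central pair

  same <- tiny_matrix(cbind(c(2, 4), c(2, 4), c(2, 4)))
  prof3 <- cluster_medians(same, tibble::tibble(barcode = colnames(same),
                                                cluster_id = rep(0L, 3)))
  expect_equal(prof3$median_expr, c(2, 4))

  expect_error(
    cluster_medians(two, tibble::tibble(barcode = "ghost", cluster_id = 0L)),
    "ghost")
})

test_that("CTA scores follow sum(Z*w)/N^(1/3) with N fixed by the compendium", {
  genes <- paste0("m", 1:8)
  markers <- tiny_markers(list(TypeA = genes))
  # frequencies chosen so every marker sits at max f -> weight exactly 1
  freq <- tibble::tibble(gene = c(genes, "dummy"), f = c(rep(5L, 8), 1L))
  prof <- tiny_profiles(list(setNames(rep(1, 8), genes)))
  s <- cta_score(prof, markers, freq)
  expect_equal(s$cta, 8 / 2)  # 8^(1/3) = 2

  # single marker, weight 1.5 (f = 4 in a 1..5 range), Z = 3.5 -> 5.25
  m1 <- tiny_markers(list(TypeB = "m1"))
  freq1 <- tibble::tibble(gene = c("m1", "lo", "hi"), f = c(4L, 1L, 5L))
  prof1 <- tiny_profiles(list(c(m1 = 3.5)))
  expect_equal(cta_score(prof1, m1, freq1)$cta, 5.25)

  # all-zero profile scores zero
  prof0 <- tiny_profiles(list(setNames(rep(0, 8), genes)))
  expect_equal(cta_score(prof0, markers, freq)$cta, 0)

  # markers absent from the matrix contribute Z = 0 but still enlarge N
  wider <- tiny_markers(list(TypeA = c(genes, "off_axis")))
  freq_w <- tibble::tibble(gene = c(genes, "off_axis", "dummy"),
                           f = c(rep(5L, 9), 1L))
  s_w <- cta_score(prof, wider, freq_w)
  expect_equal(s_w$cta, 8 / 9^(1 / 3))
  expect_lt(s_w$cta, s$cta)  # unexpressed marker strictly penalizes
})

test_that("marker-overlap p-values are exact upper-tail hypergeometric", {
  # universe 10, markers 5, expressed 5, all expressed are markers
  med <- setNames(c(rep(1, 5), rep(0, 5)), paste0("g", 1:10))
  prof <- tiny_profiles(list(med))
  markers <- tiny_markers(list(T = paste0("g", 1:5)))
  p <- cluster_p_value(prof, markers)
  expect_equal(p$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # zero overlap -> p = 1
  markers0 <- tiny_markers(list(T = paste0("g", 6:10)))
  prof0 <- tiny_profiles(list(setNames(c(rep(1, 5), rep(0, 5)), paste0("g", 1:10))))
  expect_equal(cluster_p_value(prof0, markers0)$p_value, 1)

  # universe 4, markers 2, expressed 2, overlap 1 -> 5/6
  med4 <- c(a = 1, b = 1, c = 0, d = 0)
  prof4 <- tiny_profiles(list(med4))
  markers4 <- tiny_markers(list(T = c("a", "c")))
  expect_equal(cluster_p_value(prof4, markers4)$p_value, 5 / 6, tolerance = 1e-12)
})

test_that("hypergeometric p-values match exhaustive enumeration on small universes", {
  set.seed(21)
  for (i in 1:40) {
    U <- sample(2:20, 1)
    genes <- paste0("u", seq_len(U))
    K <- sample(1:U, 1)
    n_expr <- sample(0:U, 1)
    markers <- tiny_markers(list(T = sample(genes, K)))
    med <- setNames(rep(0, U), genes)
    med[sample(genes, n_expr)] <- 1
    prof <- tiny_profiles(list(med))
    k_obs <- sum(med[markers$gene_symbol] > 0)
    expect_equal(cluster_p_value(prof, markers)$p_value,
                 hyper_tail_oracle(k_obs, U, K, n_expr),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition and validates input", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("winner selection labels clusters and falls back to Unknown", {
  genes <- paste0("g", 1:30)
  markers <- tiny_markers(list(Alpha = genes[1:5], Beta = genes[6:10]))
  medA <- setNames(rep(0, 30), genes); medA[genes[1:5]] <- 2
  ann <- annotate_clusters(tiny_profiles(list(medA)), markers)
  expect_equal(ann$calls$label, "Alpha")
  expect_equal(ann$scores$rank[ann$scores$cell_type == "Alpha"], 1L)

  med0 <- setNames(rep(0, 30), genes)
  ann0 <- annotate_clusters(tiny_profiles(list(med0)), markers)
  expect_equal(ann0$calls$label, "Unknown")
  expect_true(all(tidy(ann0)$p_value == 1))

  # identical marker sets tie on CTA and p; alphabetical order decides
  twins <- tiny_markers(list(Zeta = genes[1:5], Eta = genes[1:5]))
  annT <- annotate_clusters(tiny_profiles(list(medA)), twins)
  expect_equal(annT$calls$top_cell_type, "Eta")
  ctas <- tidy(annT)$cta
  expect_equal(ctas[1], ctas[2])
})

test_that("CTA is linear in the profile and the winner is scale-invariant", {
  set.seed(9)
  genes <- paste0("g", 1:40)
  markers <- tiny_markers(list(A = genes[1:8], B = genes[9:16], C = genes[17:24]))
  med <- setNames(runif(40), genes)
  prof1 <- tiny_profiles(list(med))
  prof3 <- tiny_profiles(list(med * 3.7))
  s1 <- cta_score(prof1, markers)
  s3 <- cta_score(prof3, markers)
  expect_equal(s3$cta, s1$cta * 3.7, tolerance = 1e-12)
  a1 <- annotate_clusters(prof1, markers)
  a3 <- annotate_clusters(prof3, markers)
  expect_equal(a1$calls$top_cell_type, a3$calls$top_cell_type)
})

test_that("annotation is invariant to cell and gene order and recovers planted types", {
  cfg <- sim_config(n_clusters = 4, cells_per_cluster = 20,
                    n_background_genes = 300,
                    library_depth_range = c(150, 250), seed = 77)
  mk <- simulate_markers(cfg)
  sim <- simulate_counts(cfg, mk)
  norm <- normalize_counts(sim$counts)
  ann <- annotate_sample(norm, sim$clusters, mk)
  merged <- dplyr::left_join(ann$calls, sim$truth, by = "cluster_id")
  expect_equal(merged$label, merged$cell_type)

  perm <- sample(ncol(norm))
  ann_p <- annotate_sample(norm[sample(nrow(norm)), perm], sim$clusters, mk)
  expect_equal(ann_p$calls, ann$calls)

  expect_equal(glance(ann)$n_unknown, 0L)
  expect_s3_class(ggplot2::autoplot(ann), "ggplot")
})
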