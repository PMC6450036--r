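test_that("marker table TSV round-trips field-for-field and filters by species", {
  tbl <- tiny_markers(list(Tcell = c("Cd3e", "Cd8a"), Bcell = "Ms4a1"))
  tbl$aliases[[1]] <- c("T3E", "CD3-epsilon")
  tbl$ui <- c(0.1, 0.2, NA)
  tbl$extra_note <- c("a", "b", "c")  # unknown trailing column
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(tbl, path)
  back <- read_marker_table(path)
  expect_equal(back$gene_symbol, tbl$gene_symbol)
  expect_equal(back$cell_type, tbl$cell_type)
  expect_equal(back$aliases, tbl$aliases)
  expect_equal(back$ui, tbl$ui)
  expect_equal(back$extra_note, tbl$extra_note)

  mixed <- tiny_markers(list(Tcell = "Cd3e"), species = "Hs")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(mixed, path2)
  expect_equal(nrow(read_marker_table(path2, species = "Hs")), 1L)
  expect_error(read_marker_table(path2, species = "Mm"), "empty table")
})

test_that("malformed marker tables are rejected with named problems", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(species = "Mm", gene_symbol = "Cd3e"), path)
  expect_error(read_marker_table(path), "cell_type")

  dup <- tiny_markers(list(Tcell = c("Cd3e", "Cd3e")))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    dplyr::mutate(dup, aliases = ""), path2)
  expect_error(read_marker_table(path2), "duplicate")

  bad_ui <- tiny_markers(list(Tcell = "Cd3e"))
  bad_ui$ui <- 1.5
  expect_error(validate_marker_table(bad_ui), "\\[0, 1\\]")
})

test_that("gene frequency counts distinct cell types per gene", {
  tbl <- tiny_markers(list(A = c("g1", "g2"), B = c("g1", "g3"),
                           C = c("g1", "g4"), D = c("g1", "g5"), E = "g1"))
  freq <- gene_frequency(tbl)
  expect_equal(freq$f[freq$gene == "g1"], 5L)
  expect_equal(freq$f[freq$gene == "g2"], 1L)

  flat <- gene_frequency(tiny_markers(list(A = c("x", "y"))))
  expect_equal(range(flat$f), c(1L, 1L))
  expect_error(gene_frequency(tbl[0, ]), "empty")
})

test_that("marker weights follow the down-weighting formula and its bounds", {
  freq <- tibble::tibble(gene = paste0("g", 1:5), f = 1:5)
  w <- marker_weight(freq)
  expect_equal(w$weight[w$f == 5], 1.0)            # most frequent -> 1
  expect_equal(w$weight[w$f == 1], 2.0)            # most specific -> 2
  expect_equal(w$weight[w$f == 3], 1 + sqrt(0.5))  # 1.70711 from the formula

  # degenerate range: no frequency signal, every gene maximally specific
  flat <- tibble::tibble(gene = c("a", "b"), f = c(3L, 3L))
  expect_equal(marker_weight(flat)$weight, c(2, 2))

  expect_error(marker_weight(freq, genes = "nope"), "absent")
})

test_that("weights stay in [1,2] and are non-increasing in frequency", {
  set.seed(11)
  for (i in 1:25) {
    f <- sample.int(50, size = sample(2:40, 1), replace = TRUE)
    freq <- tibble::tibble(gene = paste0("g", seq_along(f)), f = f)
    w <- marker_weight(freq) |> dplyr::arrange(f)
    expect_true(all(w$weight >= 1 & w$weight <= 2))
    expect_true(all(diff(w$weight) <= 1e-12))
  }
})

test_that("ubiquitousness index is the expressed-cluster fraction", {
  profs <- tiny_profiles(lapply(1:8, function(i) {
    c(house = 1, rare = if (i <= 3) 1 else 0, absent = 0)
  }))
  ui <- ubiquitousness_index(profs, genes = c("house", "rare", "absent", "missing"))
  expect_equal(ui$ui, c(1, 0.375, 0, 0))  # all, 3 of 8, none, off-axis
  # invariant under profile reordering
  shuffled <- profs[sample(nrow(profs)), ]
  expect_equal(ubiquitousness_index(shuffled), ubiquitousness_index(profs))
})

test_that("marker sensitivity is the expressed fraction among same-type clusters", {
  profs <- tiny_profiles(list(
    c(mk = 2, other = 0), c(mk = 0, other = 0),
    c(mk = 1, other = 0), c(mk = 0, other = 1)
  ))
  calls <- tibble::tibble(cluster_id = 0:3,
                          label = c("T", "T", "T", "T"))
  mk <- tiny_markers(list(T = "mk", B = "other"))
  sens <- marker_sensitivity(mk, calls, profs)
  expect_equal(sens$sensitivity[sens$gene == "mk"], 0.5)  # 2 of 4
  # B never called -> its marker is omitted, not zero
  expect_false("other" %in% sens$gene)

  all_on <- marker_sensitivity(mk, calls,
    tiny_profiles(rep(list(c(mk = 1, other = 0)), 4)))
  expect_equal(all_on$sensitivity, 1.0)
  none <- marker_sensitivity(mk, calls,
    tiny_profiles(rep(list(c(mk = 0, other = 0)), 4)))
  expect_equal(none$sensitivity, 0.0)
})
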