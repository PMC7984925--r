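test_that("edge rules on a toy study give the hand-enumerated network", {
  # 2 compounds {G1,G2} and {G2,G3}, 1 pathway {G1,G3}:
  # nodes: P, D, c1, c2, G1..G3, pw = 8
  # edges: 2 prescription + 4 compound-gene + 3 disease-gene + 2 pathway-gene = 11
  screen <- toy_screen(list(c1 = c("G1", "G2"), c2 = c("G2", "G3")))
  pw <- gene_set_collection(list(pw1 = c("G1", "G3")))
  net <- build_network(screen, pw)
  expect_equal(nrow(net$nodes), 8L)
  expect_equal(nrow(net$edges), 11L)
  expect_equal(sum(net$edges$relation == "prescription-compound"), 2L)
  expect_equal(sum(net$edges$relation == "compound-gene"), 4L)
  expect_equal(sum(net$edges$relation == "disease-gene"), 3L)
  expect_equal(sum(net$edges$relation == "pathway-gene"), 2L)
})

test_that("an empty screen still yields the two singleton nodes", {
  tm <- target_map(list(), provenance = "synthetic")
  screen <- suppressWarnings(intersect_with_disease(tm, character()))
  net <- build_network(screen)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("compounds with empty common sets are rejected by build_network", {
  tm <- target_map(list(c1 = "G1"), provenance = "synthetic")
  screen <- intersect_with_disease(tm, "G1")
  screen$active_compounds <- c("c1", "ghost")
  screen$common_targets$entries$ghost <- character()
  expect_error(build_network(screen), "empty common target set")
})

test_that("handshake identity holds on randomly generated networks", {
  set.seed(99)
  for (i in 1:20) {
    n_c <- sample(1:6, 1)
    genes <- paste0("G", 1:12)
    sets <- lapply(seq_len(n_c), function(j) sample(genes, sample(1:8, 1)))
    names(sets) <- paste0("c", seq_len(n_c))
    pw <- gene_set_collection(list(p1 = sample(genes, 5), p2 = sample(genes, 3)))
    net <- build_network(toy_screen(sets), pw)
    deg <- network_degrees(net)
    expect_equal(sum(deg), 2L * nrow(net$edges))
    # node count identity
    expect_equal(nrow(net$nodes),
                 n_c + length(unique(unlist(sets))) + length(pw$sets) + 2L)
  }
})

test_that("screening degrees equal common-set sizes, excluding the prescription edge", {
  screen <- toy_screen(list(c1 = c("G1", "G2"), c2 = c("G2", "G3")))
  net <- build_network(screen)
  deg <- compound_degrees(net)
  expect_equal(deg, c(c1 = 2L, c2 = 2L))
  full <- network_degrees(net)
  expect_equal(unname(full[c("c1", "c2")]), unname(deg + 1L))  # + prescription edge
})

test_that("recomputed degrees match the recorded degree column on all 21 rows", {
  tm <- read_fixture_targets()
  run <- study_run()
  recomputed <- run$degrees
  reported <- tm$degree_reported[names(recomputed)]
  expect_equal(unname(recomputed), unname(reported))
  expect_equal(recomputed[["isoastragaloside_ii"]], 32L)
  expect_equal(recomputed[["gallic_acid"]], 27L)
  expect_equal(recomputed[["rhein"]], 11L)
})

test_that("marker selection applies a strict threshold with deterministic ordering", {
  degrees <- c(b2 = 5, a1 = 5, c3 = 2, d4 = 7)
  sel <- select_markers(degrees, "fixed", fixed_value = 4)
  expect_equal(sel$selected, c("d4", "a1", "b2"))  # degree desc, ties alpha
  expect_equal(sel$rejected, "c3")
  expect_equal(select_markers(degrees, "fixed", fixed_value = 5)$selected, "d4")
  # threshold 0 selects every compound with >= 1 gene
  expect_length(select_markers(degrees, "fixed", fixed_value = 0)$selected, 4)
  expect_error(select_markers(degrees, "fixed"), "fixed_value")
  # monotonicity: raising the threshold never adds a marker
  prev <- NULL
  for (thr in 0:8) {
    cur <- select_markers(degrees, "fixed", fixed_value = thr)$selected
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("computed-mean mode uses 2E/N of the full network", {
  screen <- toy_screen(list(c1 = c("G1", "G2"), c2 = c("G2", "G3")))
  net <- build_network(screen)
  deg <- compound_degrees(net)
  sel <- select_markers(deg, "computed_mean", net = net)
  expect_equal(sel$threshold_used, 2 * nrow(net$edges) / nrow(net$nodes))
  expect_error(select_markers(deg, "computed_mean"), "net")
})

test_that("PPI summaries deduplicate undirected pairs and rank by frequency", {
  edges <- data.frame(from = c("A9", "B9", "B9", "C9"),
                      to = c("B9", "A9", "C9", "C9"))
  expect_warning(s <- ppi_summary(edges, top_k = 30), "self-loop")
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 2L)
  expect_equal(sum(s$top_genes$frequency), 2L * s$n_edges)

  empty <- ppi_summary(data.frame(from = character(), to = character()))
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$n_edges, 0L)
  expect_equal(nrow(empty$top_genes), 0L)

  star <- data.frame(from = "HUB1", to = paste0("L", 1:4))
  s2 <- ppi_summary(star, top_k = 1)
  expect_equal(s2$top_genes$gene, "HUB1")
  expect_equal(s2$top_genes$frequency, 4L)
})
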