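test_that("hypergeometric tail matches exhaustive draw enumeration (N <= 12)", {
  for (N in c(3L, 5L, 8L, 12L)) {
    for (n in 0:N) {
      for (K in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_p(N, K, n, k), hyper_tail_enum(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric tail agrees with enumeration over all C(20,5) draws", {
  expect_equal(hypergeom_p(20, 5, 5, 4), hyper_tail_enum(20, 5, 5, 4),
               tolerance = 1e-12)
})

test_that("tail boundary values and monotonicity in k", {
  expect_equal(hypergeom_p(30, 7, 9, 0), 1.0)
  expect_equal(hypergeom_p(15, 15, 6, 4), 1.0)  # K = N forces the overlap
  p <- hypergeom_p(50, 12, 20, 0:12)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeom_p(10, 12, 5, 1), "invalid")
  expect_error(hypergeom_p(10, 5, 5, 6), "invalid")
})

test_that("BH step-up matches hand-computed examples", {
  expect_equal(bh_adjust(0.05), 0.05)
  # p_(i) * m / i then monotone from the top: all become 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # worked example: sorted p (.01,.04,.09), m=3 -> (.03,.06,.09), no violation
  expect_equal(bh_adjust(c(0.09, 0.01, 0.04)), c(0.09, 0.03, 0.06))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH is order-invariant, rank-preserving, and bounded", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
    # ranking preserved: sorting by p and by adjusted p agree up to ties
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("a planted enriched set ranks first on synthetic annotation", {
  study <- generate_study(tempfile("st"), n_compounds = 10,
                          n_genes_universe = 1000, n_disease_genes = 400,
                          n_pathways = 10, pathway_size_range = c(25, 40),
                          marker_target_count = 25, nonmarker_target_count = 4,
                          enrichment_effect = 3, n_enriched_sets = 1,
                          fingerprint_bits = 256, seed = 2024)
  ann <- read_gmt(study$paths[["pathways"]])
  # query = the common gene pool the generator planted enrichment over
  disease <- read_gene_list(study$paths[["disease"]])
  lib <- read_ligand_library(study$paths[["ligands"]])
  fps <- read_fingerprints(study$paths[["fingerprints"]])
  predicted <- lapply(fps, predict_targets, library = lib, threshold = 0.80)
  common <- intersect(unique(unlist(predicted)), disease)
  res <- enrich(common, ann, universe_mode = "explicit",
                universe = sprintf("G%06d", 1:1000), top_n = 10)
  expect_equal(res$set_id[1], study$truth$planted_enriched_sets)
})

test_that("degenerate enrichment inputs behave as documented", {
  ann <- gene_set_collection(list(s1 = c("A1", "B1", "C1")))
  res <- enrich(c("A1", "B1", "C1"), ann, top_n = 5)
  expect_equal(res$k, 3L)
  expect_equal(res$K, 3L)
  expect_equal(res$n, 3L)
  expect_equal(res$p_value, 1.0)   # query == set == universe
  expect_equal(nrow(enrich(c("A1", "B1"), ann, top_n = 0)), 0L)
  ann2 <- gene_set_collection(list(s1 = c("A1", "B1"), s2 = c("C1", "D1")))
  expect_warning(res2 <- enrich("Z9", ann2, universe_mode = "explicit",
                                universe = c("A1", "B1", "C1", "D1", "Z9")),
                 "overlaps no annotated set")
  expect_equal(nrow(res2), 0L)
})

test_that("report ordering is overlap-desc, then p, then id, truncated to top_n", {
  ann <- gene_set_collection(list(
    big = paste0("X", 1:10), tight = c("A1", "A2"), loose = paste0("Y", 1:40),
    other = c("A1", "B7")))
  query <- c("A1", "A2", "X1", "X2")
  res <- enrich(query, ann, top_n = 3)
  expect_equal(nrow(res), 3L)
  expect_true(all(diff(res$k) <= 0))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  # overlap genes are recorded and subset of query
  for (i in seq_len(nrow(res))) {
    ov <- strsplit(res$overlap_genes[i], ", ", fixed = TRUE)[[1]]
    expect_length(ov, res$k[i])
    expect_true(all(ov %in% query))
  }
})
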