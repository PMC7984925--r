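test_that("tanimoto matches set arithmetic and its boundary cases", {
  a <- fingerprint(c(1, 1, 1, 0, 0, 0))
  b <- fingerprint(c(1, 1, 0, 1, 1, 0))
  expect_equal(tanimoto(a, b), 2 / (3 + 4 - 2))   # |A∩B| / (|A|+|B|-|A∩B|)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(fingerprint(c(1, 0, 0)), fingerprint(c(0, 1, 1))), 0.0)
  expect_error(tanimoto(fingerprint(c(1, 0)), fingerprint(c(1, 0, 1))),
               "length mismatch")
  expect_error(tanimoto(fingerprint(c(0, 0)), fingerprint(c(0, 0))), "undefined")
})

test_that("tanimoto is symmetric, bounded, and 1 only for identical prints", {
  set.seed(42)
  for (i in 1:25) {
    a <- fingerprint(rbinom(64, 1, 0.4))
    b <- fingerprint(rbinom(64, 1, 0.4))
    s <- tanimoto(a, b)
    expect_equal(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, identical(as.integer(a), as.integer(b)))
  }
})

test_that("predict_targets unions targets of ligands strictly above threshold", {
  set.seed(7)
  q <- fingerprint(rbinom(128, 1, 0.5))
  lib <- list(
    ref_ligand("identical", q, c("T1", "T2")),
    ref_ligand("far", fingerprint(1L - as.integer(q)), c("T9")))
  expect_equal(predict_targets(q, lib, 0.9), c("T1", "T2"))
  # brute-force check on a random library: expected = union over sims > thr
  lib2 <- lapply(1:12, function(i) {
    ref_ligand(paste0("L", i), fingerprint(rbinom(128, 1, 0.5)),
               paste0("G", i))
  })
  thr <- 0.30
  sims <- vapply(lib2, function(l) tanimoto(q, l$fingerprint), numeric(1))
  expected <- sort(unique(unlist(lapply(lib2[sims > thr], `[[`, "targets"))))
  expect_equal(predict_targets(q, lib2, thr), expected)
  # all similarities at/below threshold -> empty prediction
  expect_equal(predict_targets(q, lib2, 1), character())
})

test_that("threshold comparison is strict and monotone non-increasing", {
  a <- fingerprint(c(rep(1, 8), rep(0, 2)))
  b <- fingerprint(c(rep(1, 10)))          # tanimoto = 0.8 exactly
  expect_equal(tanimoto(a, b), 0.8)
  lib <- list(ref_ligand("edge", b, "TGT"))
  expect_equal(predict_targets(a, lib, 0.80), character())  # 0.8 > 0.8 is FALSE
  expect_equal(predict_targets(a, lib, 0.79), "TGT")
  set.seed(11)
  q <- fingerprint(rbinom(64, 1, 0.5))
  lib2 <- lapply(1:8, function(i)
    ref_ligand(paste0("L", i), fingerprint(rbinom(64, 1, 0.5)), paste0("G", i)))
  prev <- NULL
  for (thr in seq(0, 1, by = 0.1)) {
    cur <- predict_targets(q, lib2, thr)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("disease intersection splits active from excluded and counts the venn", {
  tm <- target_map(list(c1 = c("A1", "B1", "X1"), c2 = c("B1", "Y1"),
                        c3 = c("Z1")), provenance = "synthetic")
  res <- intersect_with_disease(tm, c("A1", "B1", "Y1", "Q1"))
  expect_equal(res$active_compounds, c("c1", "c2"))
  expect_equal(res$excluded_compounds, "c3")
  expect_equal(unname(res$venn),
               c(5L, 4L, 3L))  # union targets, disease, common union
  # common sets are subsets of both inputs
  for (id in names(res$common_targets$entries)) {
    cs <- as.character(res$common_targets$entries[[id]])
    expect_true(all(cs %in% tm$entries[[id]]))
    expect_true(all(cs %in% res$disease_genes))
  }
  expect_equal(sort(union(res$active_compounds, res$excluded_compounds)),
               sort(names(tm$entries)))
  expect_length(intersect(res$active_compounds, res$excluded_compounds), 0)
})

test_that("an empty disease set excludes everything, with a warning", {
  tm <- target_map(list(c1 = "A1"), provenance = "synthetic")
  expect_warning(res <- intersect_with_disease(tm, character()), "empty disease")
  expect_length(res$active_compounds, 0)
  expect_equal(res$venn[["n_common"]], 0L)
})

test_that("fingerprint and ligand-library files round-trip", {
  set.seed(3)
  fps <- list(a = fingerprint(rbinom(32, 1, 0.5)),
              b = fingerprint(rbinom(32, 1, 0.5)))
  f <- tempfile(fileext = ".tsv")
  write_fingerprints(fps, f)
  fps2 <- read_fingerprints(f)
  expect_equal(lapply(fps2, as.integer), lapply(fps, as.integer))

  lib <- list(ref_ligand("l1", fps$a, c("T1", "T2")),
              ref_ligand("l2", fps$b, "T3"))
  g <- tempfile(fileext = ".tsv")
  write_ligand_library(lib, g)
  lib2 <- read_ligand_library(g)
  expect_equal(vapply(lib2, `[[`, "", "ligand_id"), c("l1", "l2"))
  expect_equal(lib2[[1]]$targets, c("T1", "T2"))
  expect_equal(as.integer(lib2[[2]]$fingerprint), as.integer(fps$b))
})
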