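# Run the full pipeline (prediction -> intersection -> network -> selection)
# on a generated study, with the degree threshold midway between the planted
# marker and non-marker target counts.
pipeline_on_study <- function(study) {
  p <- study$paths
  tab <- read_compound_table(p[["compounds"]])
  fps <- read_fingerprints(p[["fingerprints"]])
  lib <- read_ligand_library(p[["ligands"]])
  disease <- read_gene_list(p[["disease"]])
  predicted <- lapply(fps[tab$compound_id], predict_targets, library = lib,
                      threshold = 0.80)
  tm <- target_map(predicted, provenance = "predicted")
  gp <- study$truth$generation_params
  thr <- (gp$marker_target_count + gp$nonmarker_target_count) / 2
  cfg <- pipeline_config(degree_threshold_mode = "fixed",
                         fixed_degree_threshold = thr,
                         rng_seed = study$truth$rng_seed)
  run_pipeline(tm, disease, read_gmt(p[["pathways"]]), cfg)
}

test_that("the same seed produces byte-identical fixtures", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  s1 <- generate_study(d1, n_compounds = 6, n_genes_universe = 300,
                       n_disease_genes = 120, n_pathways = 5,
                       pathway_size_range = c(5, 15), marker_target_count = 10,
                       nonmarker_target_count = 2, fingerprint_bits = 128,
                       seed = 77)
  s2 <- generate_study(d2, n_compounds = 6, n_genes_universe = 300,
                       n_disease_genes = 120, n_pathways = 5,
                       pathway_size_range = c(5, 15), marker_target_count = 10,
                       nonmarker_target_count = 2, fingerprint_bits = 128,
                       seed = 77)
  for (key in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[key]], warn = FALSE),
                     readLines(s2$paths[[key]], warn = FALSE),
                     label = key)
  }
  # a different seed changes the fixtures
  s3 <- generate_study(tempfile("gen3"), n_compounds = 6,
                       n_genes_universe = 300, n_disease_genes = 120,
                       n_pathways = 5, pathway_size_range = c(5, 15),
                       marker_target_count = 10, nonmarker_target_count = 2,
                       fingerprint_bits = 128, seed = 78)
  expect_false(identical(readLines(s1$paths[["disease"]], warn = FALSE),
                         readLines(s3$paths[["disease"]], warn = FALSE)))
})

test_that("all generated files parse cleanly through the readers", {
  study <- generate_study(tempfile("gen"), seed = 42)
  expect_no_warning({
    tab <- read_compound_table(study$paths[["compounds"]])
    fps <- read_fingerprints(study$paths[["fingerprints"]])
    lib <- read_ligand_library(study$paths[["ligands"]])
    disease <- read_gene_list(study$paths[["disease"]])
    ann <- read_gmt(study$paths[["pathways"]])
  })
  expect_equal(nrow(tab), 22L)
  expect_equal(length(fps), 22L)
  expect_equal(length(lib), 22L * 3L)   # one true ligand + two decoys each
  expect_equal(length(disease), 900L)
  expect_equal(length(ann$sets), 20L)
})

test_that("default-parameter pipeline recovers the planted markers exactly", {
  study <- generate_study(tempfile("gen"), seed = 1)
  run <- pipeline_on_study(study)
  expect_setequal(run$markers$selected, study$truth$planted_markers)
  expect_equal(run$screen$venn[["n_common"]],
               study$truth$expected_venn$n_common)
  expect_equal(run$screen$venn[["n_compound_targets"]],
               study$truth$expected_venn$n_compound_targets)
  expect_equal(run$screen$venn[["n_disease_genes"]],
               study$truth$expected_venn$n_disease)
})

test_that("recovery is exact across seeds whenever the degree gap is >= 2", {
  for (seed in c(11, 12, 13)) {
    study <- generate_study(tempfile("gen"), n_compounds = 10,
                            n_genes_universe = 600, n_disease_genes = 250,
                            n_pathways = 4, pathway_size_range = c(5, 20),
                            marker_target_count = 12, nonmarker_target_count = 3,
                            fingerprint_bits = 256, seed = seed)
    run <- pipeline_on_study(study)
    expect_setequal(run$markers$selected, study$truth$planted_markers)
    expect_length(setdiff(run$markers$selected, study$truth$planted_markers), 0)
  }
})

test_that("a zero marker fraction plants nothing and selects nothing", {
  study <- generate_study(tempfile("gen"), n_compounds = 8,
                          n_genes_universe = 400, n_disease_genes = 150,
                          n_pathways = 3, pathway_size_range = c(5, 10),
                          marker_fraction = 0, marker_target_count = 12,
                          nonmarker_target_count = 3, fingerprint_bits = 128,
                          seed = 5)
  expect_length(study$truth$planted_markers, 0)
  run <- pipeline_on_study(study)   # threshold 7.5 > non-marker count 3
  expect_length(run$markers$selected, 0)
})

test_that("infeasible parameter combinations are rejected", {
  d <- tempfile("gen")
  expect_error(generate_study(d, marker_target_count = 3,
                              nonmarker_target_count = 5), "exceed")
  expect_error(generate_study(d, n_disease_genes = 10, marker_target_count = 30),
               "disease")
  expect_error(generate_study(d, n_genes_universe = 100, n_disease_genes = 900),
               "universe")
})

test_that("the offline reproduction profile mirrors the published table shape", {
  prof <- generate_reproduction_profile(tempfile("prof"), seed = 3)
  expect_equal(nrow(read_compound_table(prof[["compounds"]])), 22L)
  tm <- suppressWarnings(read_target_map(prof[["targets"]]))
  expect_equal(length(unique(unlist(tm$entries))), 125L)
  disease <- read_gene_list(prof[["disease"]])
  expect_equal(length(disease), 969L)
  expect_true(all(unique(unlist(tm$entries)) %in% disease))
  ann <- read_gmt(prof[["pathways"]])
  expect_equal(length(ann$sets), 20L)
  # per-pathway sizes follow the recorded target-gene counts
  counts <- read.delim(qmnet_example("hxjty_pathways.tsv"))
  expect_equal(unname(lengths(ann$sets)[counts$pathway_id]),
               counts$target_gene_count)
})
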