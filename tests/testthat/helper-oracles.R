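# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Hypergeometric upper tail by honest enumeration of draws: universe 1..N,
# annotated genes 1..K, enumerate every n-subset, count overlap >= k.
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k == 0L))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Monoisotopic mass by atomic-mass summation over a CHNO formula.
ATOMIC_MASS <- c(C = 12.0, H = 1.007825, N = 14.003074, O = 15.994915)
mono_mass <- function(formula) {
  m <- gregexpr("([A-Z])([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z])([0-9]*)", formula))[[1]]
  sum(vapply(tokens, function(tk) {
    el <- substr(tk, 1, 1)
    cnt <- sub("^[A-Z]", "", tk)
    ATOMIC_MASS[[el]] * if (nzchar(cnt)) as.integer(cnt) else 1L
  }, numeric(1)))
}
PROTON_MASS <- 1.007276

# Small screen_result built directly from already-intersected sets.
toy_screen <- function(common_sets, disease = NULL) {
  tm <- target_map(common_sets, provenance = "synthetic")
  if (is.null(disease)) disease <- unique(unlist(common_sets))
  intersect_with_disease(tm, disease)
}

# Paths to the bundled study fixtures.
fixture_components <- function() qmnet_example("hxjty_components.tsv")
fixture_targets <- function() qmnet_example("hxjty_targets.tsv")

read_fixture_targets <- function() {
  suppressWarnings(read_target_map(fixture_targets(), provenance = "fixture"))
}

# Study-reproduction run: transcribed target sets are treated as the already
# intersected common targets (the implied disease set is their union).
study_run <- function(threshold = 12, pathways = NULL) {
  tm <- read_fixture_targets()
  cfg <- pipeline_config(degree_threshold_mode = "fixed",
                         fixed_degree_threshold = threshold)
  suppressWarnings(
    run_pipeline(tm, unique(unlist(tm$entries)), pathways, cfg,
                 prescription_name = "HXJTY", disease_name = "T2DM"))
}

STUDY_MARKERS <- c(
  "gallic_acid", "rhmannioside_d", "hydroxysafflor_yellow_a",
  "calycosin_7_o_d_glucoside", "calycosin", "astragaloside_iv",
  "astragaloside_iii", "astragaloside_ii", "astragaloside_i",
  "isoastragaloside_ii", "isoastragaloside_i", "ophiopojaponin_c")

# Write lines to a throwaway UTF-8 temp file, return its path.
local_tsv <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, con = file(f, encoding = "UTF-8"))
  f
}
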