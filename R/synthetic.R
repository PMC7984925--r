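# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

flip_bits <- function(bits, n_flip) {
  pos <- sample.int(length(bits), n_flip)
  bits[pos] <- 1L - bits[pos]
  bits
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Emits every input the pipeline consumes — a compound table, per-compound
#' fingerprints, a reference ligand library, a disease gene list, and pathway
#' annotations in GMT — plus a machine-readable `truth.json` describing what
#' was planted, so that every stage can be validated end to end without any
#' external database.
#'
#' Structure planted:
#' * a fraction of compounds are markers and receive `marker_target_count`
#'   disease-overlapping targets; the rest receive `nonmarker_target_count`,
#'   so a degree threshold between the two counts separates them exactly;
#' * every compound also receives `nondisease_target_count` targets outside
#'   the disease set, so the Venn intersection is a proper subset;
#' * each compound gets one high-similarity reference ligand carrying exactly
#'   its intended target set (Tanimoto to the compound's fingerprint well
#'   above 0.80) and `n_decoys` low-similarity decoy ligands carrying junk
#'   targets (similarity well below 0.80), so the strict `>` threshold rule is
#'   exercised on both sides;
#' * `n_enriched_sets` pathway sets oversample the common gene pool by
#'   `enrichment_effect` relative to the uniform expectation; the remaining
#'   sets sample the universe uniformly.
#'
#' Gene identifiers are synthetic tokens (`G000001`, ...). The same seed
#' produces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param n_compounds number of compounds; default 22.
#' @param n_genes_universe size of the gene universe; default 2000.
#' @param n_disease_genes disease gene-set size; default 900.
#' @param n_pathways number of annotation sets; default 20.
#' @param pathway_size_range inclusive size range for pathway sets.
#' @param marker_fraction fraction of compounds planted as markers.
#' @param marker_target_count,nonmarker_target_count disease-overlapping
#'   targets per marker / non-marker compound; the former must exceed the
#'   latter.
#' @param nondisease_target_count extra non-disease targets per compound.
#' @param enrichment_effect overlap multiplier for planted enriched sets.
#' @param n_enriched_sets number of planted enriched sets.
#' @param n_decoys decoy ligands per compound.
#' @param fingerprint_bits fingerprint length; default 1024.
#' @param seed integer RNG seed.
#' @return (invisibly) a list with `paths` (named file paths) and `truth`
#'   (planted markers, enriched sets, expected Venn counts, all parameters).
#' @export
generate_study <- function(dir,
                           n_compounds = 22L,
                           n_genes_universe = 2000L,
                           n_disease_genes = 900L,
                           n_pathways = 20L,
                           pathway_size_range = c(10L, 40L),
                           marker_fraction = 12 / 22,
                           marker_target_count = 30L,
                           nonmarker_target_count = 3L,
                           nondisease_target_count = 5L,
                           enrichment_effect = 3,
                           n_enriched_sets = 2L,
                           n_decoys = 2L,
                           fingerprint_bits = 1024L,
                           seed = 1L) {
  stopifnot(n_compounds >= 1, n_genes_universe >= 1, n_disease_genes >= 1,
            n_pathways >= 0, marker_fraction >= 0, marker_fraction <= 1,
            fingerprint_bits >= 8, enrichment_effect >= 1)
  if (marker_target_count <= nonmarker_target_count) {
    stop("marker_target_count must exceed nonmarker_target_count", call. = FALSE)
  }
  if (marker_target_count > n_disease_genes) {
    stop("marker_target_count exceeds the disease gene set size", call. = FALSE)
  }
  if (n_disease_genes > n_genes_universe) {
    stop("disease set larger than the gene universe", call. = FALSE)
  }
  if (nondisease_target_count > n_genes_universe - n_disease_genes) {
    stop("not enough non-disease genes in the universe", call. = FALSE)
  }
  if (n_pathways > 0 && max(pathway_size_range) > n_genes_universe) {
    stop("pathway sizes exceed the universe", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  params <- list(n_compounds = n_compounds, n_genes_universe = n_genes_universe,
                 n_disease_genes = n_disease_genes, n_pathways = n_pathways,
                 pathway_size_range = pathway_size_range,
                 marker_fraction = marker_fraction,
                 marker_target_count = marker_target_count,
                 nonmarker_target_count = nonmarker_target_count,
                 nondisease_target_count = nondisease_target_count,
                 enrichment_effect = enrichment_effect,
                 n_enriched_sets = n_enriched_sets, n_decoys = n_decoys,
                 fingerprint_bits = fingerprint_bits, seed = seed)

  with_seed(seed, {
    universe <- sprintf("G%06d", seq_len(n_genes_universe))
    disease <- sort(sample(universe, n_disease_genes))
    nondisease <- setdiff(universe, disease)

    comp_names <- sprintf("Compound %02d", seq_len(n_compounds))
    comp_ids <- compound_id(comp_names)
    n_markers <- round(marker_fraction * n_compounds)
    markers <- sort(sample(comp_ids, n_markers))

    targets <- stats::setNames(vector("list", n_compounds), comp_ids)
    for (i in seq_len(n_compounds)) {
      nd <- if (comp_ids[i] %in% markers) marker_target_count else nonmarker_target_count
      tg <- sample(disease, nd)
      if (nondisease_target_count > 0) {
        tg <- c(tg, sample(nondisease, nondisease_target_count))
      }
      targets[[i]] <- sort(tg)
    }

    # compound (monitoring-ion) table: plausible SIM metadata
    ion_tokens <- c("[M + H]+", "[M − H]−", "[M + HCOO]−")
    herb_pool <- c("AR", "RR", "RRER", "CF", "PS", "OR")
    class_pool <- c("Glycosides", "Organic acid", "Flavonoids", "Saponins",
                    "Anthraquinones")
    comp_tab <- data.frame(
      no = seq_len(n_compounds),
      component = comp_names,
      rt_min = sprintf("%.2f", sort(stats::runif(n_compounds, 4, 45))),
      ion_mode = sample(ion_tokens, n_compounds, replace = TRUE),
      mz = sprintf("%.2f", stats::runif(n_compounds, 150, 1000)),
      herbs = sample(herb_pool, n_compounds, replace = TRUE),
      compound_class = sample(class_pool, n_compounds, replace = TRUE),
      stringsAsFactors = FALSE)

    # fingerprints and reference ligands
    fps <- lapply(comp_ids, function(id) {
      fingerprint(stats::rbinom(fingerprint_bits, 1L, 0.5))
    })
    names(fps) <- comp_ids
    ligands <- list()
    for (i in seq_len(n_compounds)) {
      s <- sum(as.integer(fps[[i]]))
      true_fp <- fingerprint(flip_bits(as.integer(fps[[i]]), max(1L, round(0.04 * s))))
      ligands[[length(ligands) + 1L]] <-
        ref_ligand(sprintf("LIG_%s_true", comp_ids[i]), true_fp, targets[[i]])
      for (d in seq_len(n_decoys)) {
        decoy_fp <- fingerprint(flip_bits(as.integer(fps[[i]]), round(0.5 * s)))
        decoy_targets <- sample(universe, 5)
        ligands[[length(ligands) + 1L]] <-
          ref_ligand(sprintf("LIG_%s_decoy%d", comp_ids[i], d), decoy_fp,
                     decoy_targets)
      }
    }
    # feasibility audit: the library must reconstruct each intended target
    # set exactly at the strict 0.80 rule
    for (i in seq_len(n_compounds)) {
      got <- predict_targets(fps[[i]], ligands, threshold = 0.80)
      if (!setequal(got, targets[[i]])) {
        stop(sprintf("generated library fails to reconstruct targets of %s",
                     comp_ids[i]), call. = FALSE)
      }
    }

    # pathway annotation with planted enrichment over the common gene pool
    common_pool <- sort(unique(intersect(unlist(targets), disease)))
    path_ids <- sprintf("PW%03d", seq_len(n_pathways))
    planted_sets <- if (n_pathways > 0 && n_enriched_sets > 0) {
      sort(sample(path_ids, min(n_enriched_sets, n_pathways)))
    } else character()
    sets <- stats::setNames(vector("list", n_pathways), path_ids)
    for (pid in path_ids) {
      size <- sample(seq(pathway_size_range[1], pathway_size_range[2]), 1)
      if (pid %in% planted_sets && length(common_pool) > 0) {
        base_overlap <- size * length(common_pool) / n_genes_universe
        m_common <- min(length(common_pool), size,
                        max(1L, ceiling(enrichment_effect * base_overlap)))
        members <- c(sample(common_pool, m_common),
                     sample(setdiff(universe, common_pool), size - m_common))
      } else {
        members <- sample(universe, size)
      }
      sets[[pid]] <- sort(members)
    }
    annotation <- gene_set_collection(
      sets, stats::setNames(sprintf("Synthetic pathway %s", path_ids), path_ids))

    truth <- list(
      planted_markers = markers,
      planted_enriched_sets = planted_sets,
      expected_venn = list(
        n_compound_targets = length(unique(unlist(targets))),
        n_disease = n_disease_genes,
        n_common = length(common_pool)),
      rng_seed = as.integer(seed),
      generation_params = params)

    paths <- c(
      compounds = file.path(dir, "compounds.tsv"),
      fingerprints = file.path(dir, "fingerprints.tsv"),
      ligands = file.path(dir, "ligands.tsv"),
      disease = file.path(dir, "disease_genes.txt"),
      pathways = file.path(dir, "pathways.gmt"),
      truth = file.path(dir, "truth.json"))
    utils::write.table(comp_tab, paths[["compounds"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    write_fingerprints(fps, paths[["fingerprints"]])
    write_ligand_library(ligands, paths[["ligands"]])
    write_gene_list(disease, paths[["disease"]])
    write_gmt(annotation, paths[["pathways"]])
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)

    invisible(list(paths = paths, truth = truth))
  })
}

#' Generate the offline reproduction profile of the bundled study
#'
#' Assembles, under `dir`, everything needed to run the full pipeline on the
#' bundled HXJTY tables with no network access: copies of the monitoring-ion
#' and target tables, a disease gene list, and 20 pathway gene sets in GMT
#' format. The disease list contains the 125 common target genes from the
#' bundled target table padded with synthetic tokens (`TDG0001`, ...) to the
#' 969 genes a disease-database query returned for type 2 diabetes; the
#' pathway sets reuse the 20 published pathway identifiers/names and their
#' per-pathway target-gene counts, with memberships sampled from the 125
#' common genes (real per-pathway memberships were never published). Both
#' synthetic stand-ins are labelled as such in their file names.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the sampled pathway memberships.
#' @return (invisibly) named list of file paths.
#' @export
generate_reproduction_profile <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src_comp <- qmnet_example("hxjty_components.tsv")
  src_targ <- qmnet_example("hxjty_targets.tsv")
  src_path <- qmnet_example("hxjty_pathways.tsv")
  paths <- c(
    compounds = file.path(dir, "hxjty_components.tsv"),
    targets = file.path(dir, "hxjty_targets.tsv"),
    disease = file.path(dir, "synthetic_disease_genes.txt"),
    pathways = file.path(dir, "synthetic_pathways.gmt"))
  file.copy(src_comp, paths[["compounds"]], overwrite = TRUE)
  file.copy(src_targ, paths[["targets"]], overwrite = TRUE)

  tm <- suppressWarnings(read_target_map(src_targ, provenance = "fixture"))
  common <- sort(unique(unlist(tm$entries)))

  with_seed(seed, {
    n_total <- 969L
    pad <- sprintf("TDG%04d", seq_len(max(0L, n_total - length(common))))
    write_gene_list(c(common, pad), paths[["disease"]])

    ptab <- read.delim(src_path, sep = "\t", colClasses = "character",
                       fileEncoding = "UTF-8")
    sets <- list(); set_names <- character()
    for (i in seq_len(nrow(ptab))) {
      id <- ptab$pathway_id[i]
      sets[[id]] <- sort(sample(common, as.integer(ptab$target_gene_count[i])))
      set_names[[id]] <- ptab$description[i]
    }
    write_gmt(gene_set_collection(sets, set_names), paths[["pathways"]])
  })
  invisible(paths)
}
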