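#!/usr/bin/env Rscript
# Stage 2 — intersect component targets with the disease gene set.
#
# The transcribed target sets are the outputs of similarity-based target
# prediction already intersected with the disease; running them through the
# intersection operator against the assembled disease list reproduces the
# active/excluded split and the common-gene union, and writes the
# per-component common target table.

suppressPackageStartupMessages(library(qmnet))

tm <- suppressWarnings(read_target_map("results/profile/hxjty_targets.tsv"))
disease <- read_gene_list("results/profile/synthetic_disease_genes.txt")

screen <- intersect_with_disease(tm, disease)
print(screen)

write_target_map(screen$common_targets, "results/common_targets.tsv")
jsonlite::write_json(
  list(venn = as.list(screen$venn),
       active = screen$active_compounds,
       excluded = screen$excluded_compounds),
  "results/screen_summary.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/common_targets.tsv and results/screen_summary.json\n")
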