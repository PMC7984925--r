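---
title: "Quality-marker discovery by network pharmacology: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-marker discovery by network pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Herbal preparations are mixtures. Chromatography can quantify dozens of
constituents, but quality control should track the constituents that carry
the therapeutic effect, not merely the ones that are easy to measure. The
network-pharmacology answer is to connect each quantified constituent to the
disease through predicted target genes and to rank constituents by how many
disease-relevant targets they engage. qmnet implements that pipeline as
composable, individually testable operations, and ships the tables of a
concrete study — 22 components quantified in the eight-herb decoction HXJTY,
screened against type 2 diabetes mellitus (T2DM) — as bundled fixtures so
the whole analysis runs offline.

## Pipeline model and assumptions

**Target prediction.** A compound's fingerprint is compared against a
reference ligand library; ligands with Tanimoto similarity strictly greater
than 0.80 transfer their annotated targets, and contributions are merged by
union. The strict inequality follows the screening rule the pipeline
reproduces ("more than 0.80"); it matters only for similarities exactly at
the threshold, which the synthetic generator deliberately exercises.
Prediction platforms differ in how multiple sources are reconciled; qmnet
takes the union, the permissive choice, and records the assumption here.
When targets arrive as an already-screened table (as with the bundled study,
whose predictions were made on external platforms and published only as
results), the prediction stage is bypassed and the transcribed sets are
treated as the post-intersection common targets.

**Disease intersection.** Per-compound common targets are the intersection of
predicted targets with the disease gene set; compounds with empty
intersections are excluded from all later stages. Symbols are uppercased and
trimmed before comparison — published tables mix `Lgals3` with `LGALS3` and
ASCII commas with the ideographic comma `、` — and qmnet treats the printed
symbols as canonical (no alias resolution; see Limitations).

**Network.** Five node types; four edge rules (prescription–compound,
compound–gene, disease–gene, pathway–gene); undirected, deduplicated, no
self-edges. The node count is therefore always
`1 + #compounds + 1 + #genes + #pathways`. The original Cytoscape analysis
never published its edge rules; ours are stated explicitly because no
documented rule reproduces the edge total reported alongside the study's
network (1362 edges for 168 nodes would give mean degree ≈ 16.2, yet the
reported and screening-relevant mean is 12). Under our rules the study
network has 731 edges. qmnet consequently never asserts the published edge
total, and reproduces marker selection through the fixed threshold instead.

**Degree screening.** A component's screening degree counts its
compound–gene edges only. This is the only convention under which the
recorded per-component degrees equal the sizes of their printed target
lists for every row of the bundled table (e.g. isoastragaloside II 32,
gallic acid 27, rhein 11), so the single prescription edge is excluded.
Selection is strict (`degree > threshold`). Two threshold modes exist:

* `fixed` — a supplied value; the study-reproduction profile fixes 12, the
  network-average degree reported with the original analysis;
* `computed_mean` — `2E/N` of the full heterogeneous network, for use when
  no external value is given. On the bundled study this yields
  `2·731/168 ≈ 8.7`, which would additionally admit rhein (degree 11) — another reason the
  reproduction profile pins the threshold explicitly.

Ordering everywhere is degree descending with alphabetical tie-breaks, for
determinism across platforms.

**Over-representation.** One-sided hypergeometric upper tail
`P(X ≥ k)` for `X ~ Hypergeom(N, K, n)` (equivalently one-sided Fisher's
exact), computed through `phyper` for numerical stability at genome-scale
`N`. The universe defaults to the union of all annotated genes — the only
universe derivable from the annotation alone — with an explicit override for
genome or disease-list universes. Benjamini–Hochberg adjustment (via
`p.adjust`) runs across **all** tested sets, not just the reported ones; raw
p-values are reported alongside because published pathway tables often print
unadjusted values. Report rows require overlap `k ≥ 1` and are ordered by
`k` descending, then raw p, then set id; published orderings are typically
close to, but not exactly, this rule, and qmnet enforces the deterministic
version rather than imitating any one table. Gene Ontology structure (term
ancestry, redundancy pruning) is out of scope: GO analyses are treated as
plain gene-set ORA.

**Adduct arithmetic.** Expected m/z is the neutral monoisotopic mass plus a
fixed delta: +1.007276 Da (`[M+H]+`), −1.007276 Da (`[M−H]−`),
+44.998204 Da (`[M+HCOO]−`); deltas include the electron mass and are
applied at machine precision, with rounding confined to report columns. The
consistency audit defaults to a 0.2 Da tolerance because monitoring-ion
tables record low-resolution SIM targets, not exact masses — the bundled
table's astragaloside IV formate ion is printed 0.11 Da from its exact
value. Neutral masses are supplied as an external mapping (the bundled one
covers the 14 components with well-established molecular formulas);
compounds without a supplied mass are reported `unchecked`, never failed.

## Bundled data and curation

The fixtures transcribe the study's published tables: the 22-row
monitoring-ion table (retention time, ionization mode, monitored m/z, source
herb, compound class) and the per-component target table (21 components with
targets, plus acteoside with none). The target table as published is
internally inconsistent at four tokens: three rows' gene lists exceed their
own printed degree values, and the implied gene union exceeds the printed
125. Because the per-row degrees, the prose degree list, the 125-gene union
and the 168-node count all agree with one another, the bundled transcription
treats those four list tokens as typesetting artifacts and omits them
(SELL, F3, IGFBP1, ALOX5 from the astragaloside IV, astragaloside I and
calycosin rows), restoring full internal consistency. The reader
nevertheless re-derives every degree from the gene lists and warns on any
mismatch with a recorded degree column, so independent transcriptions are
audited rather than trusted.

The offline reproduction profile (`generate_reproduction_profile()`) supplies the
two inputs that were never published as data: a disease gene list (the 125
common genes padded with clearly synthetic `TDG....` tokens to the 969 genes
the original disease query returned) and 20 pathway gene sets reusing the
published pathway identifiers and per-pathway gene counts with memberships
sampled from the 125 common genes. Both are labelled synthetic in their
file names. They make every stage executable and preserve every count the
pipeline asserts, but carry no real biology: enrichment p-values computed
against them are placeholders (with the annotation-union universe the query
covers the whole universe and all p-values are 1, the correct degenerate
answer), and only a real GMT annotation makes stage-4 output biologically
meaningful.

## The synthetic generator

`generate_study()` plants known structure and emits every input format the
pipeline reads. Defaults mirror the bundled study's shape: 22 compounds, a
2000-gene universe, 900 disease genes, marker fraction 12/22, 20 pathway
sets, 1024-bit fingerprints. Markers receive 30 disease-overlapping targets
and non-markers 3 — a wide gap, so that a threshold between the two counts
must recover the planted set exactly; both groups also receive 5 non-disease
targets so the Venn intersection is proper. Each compound gets one
high-similarity reference ligand carrying exactly its intended targets
(≈4 % of set bits flipped, similarity ≈ 0.92) and decoys with ≈50 % of set
bits flipped (similarity ≈ 0.6, safely below the 0.80 rule but far above
zero), exercising both sides of the strict threshold; the generator verifies
reconstruction of every intended target set before writing files and aborts
otherwise. Two pathway sets oversample the common gene pool threefold
relative to the uniform expectation; the rest sample the universe uniformly.
One integer seed drives the whole study and identical seeds produce
byte-identical files. Gene identifiers are synthetic tokens (`G000001`, …)
to avoid implying real biology.

What the generator does **not** emulate: chemistry (fingerprints are i.i.d.
random bits, not structure-derived), correlated target profiles between
similar compounds, gene-symbol aliasing, annotation redundancy between
pathway sets, and PPI topology. Passing the synthetic recovery tests
therefore demonstrates that the pipeline's logic is correct under its own
assumptions, not that the assumptions hold for any particular real dataset.

## Validation problem sizes

The test suite validates the hypergeometric tail against honest enumeration
of all draws for every parameter combination with `N ≤ 12`, plus the
C(20,5) = 15 504-draw case (N=20, K=5, n=5, k=4); BH against hand-applied
step-up examples and order-invariance under random permutations; the
handshake identity `Σ deg = 2E` on every constructed network; exact planted
marker recovery at the default study shape; planted-enrichment top-ranking
over a 100-seed sweep (10 compounds, 1000-gene universe, 10 pathway sets of
25–40 genes, effect 3); and the null-model type-I error over 1000 random
queries against a 1000-gene set in a 10 000-gene universe, where the
attained rate at p < 0.05 must lie within 3 standard errors of 0.05. These
sizes keep the hypergeometric p-values nearly continuous (mean overlap 100,
so discreteness shifts the attained level by well under one standard error)
while the whole suite runs in well under a minute.

## Limitations

* Gene symbols are compared as printed; no alias/ortholog resolution.
* PPI confidence filtering is not implemented — edge lists are assumed
  pre-filtered at the source, and the configured confidence (default 0.9) is
  recorded as provenance metadata only.
* Degree is the only centrality, matching the screening rule reproduced
  here; betweenness/eigenvector variants are out of scope.
* The published Venn sizes for the un-intersected inputs (533 compound
  targets, 969 disease genes) and the published PPI counts depend on
  external database versions and are reported when full inputs are supplied,
  never asserted.
* Enrichment against the offline profile's synthetic pathway memberships is
  a plumbing demonstration, not biology.
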