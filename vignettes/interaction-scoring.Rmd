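---
title: "Bootstrap-calibrated ligand–receptor co-expression scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-calibrated ligand–receptor co-expression scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctalk)
```

## The problem

Capillary endothelial cells (cECs) in most of the brain form the
blood–brain barrier, while cECs of the median eminence (ME), a
circumventricular organ, are naturally permeable. Whether that regional
difference is maintained by signals from the perivascular environment —
pericytes, astrocyte endfeet, fibroblasts and, in the ME, tanycytes — is a
question about cell–cell communication: which ligand–receptor pairs are
co-expressed by a sender and a receiver cell type in one region but not the
other?

`vasctalk` implements a complete, reproducible version of the co-expression
approach to that question for two-region single-cell RNA-seq designs: QC
filtering, normalization, regional differential expression (DE), assembly of
a ligand–receptor database augmented with data-driven candidates, and a
bootstrap-calibrated interaction score with family-wise error control.
Because the package is validated on synthetic data with planted ground
truth, every statistical property claimed below is also checked by the test
suite.

## The score and its null

For an ordered pair (ligand *L*, receptor *R*) and a comparison
(sender subtype *s*, receiver subtype *r*, within one region), the
interaction score is

$$ S(L, R) = \bar{x}_{L,s} \cdot \bar{x}_{R,r}, $$

where $\bar{x}_{g,c}$ is the average expression of gene *g* over the cells
of subtype *c* on the **linear** CP10K scale — the arithmetic mean of
$\exp(v)-1$ over cells, with $v = \ln(1 + 10{,}000\,k/\text{total})$ the
log-normalized value of raw count *k*. Averaging on the linear scale (not
the log scale) is an interpretive choice: products of log values would be
dimensionless quantities of magnitude a few units, whereas score cutoffs in
the tens — the regime this method operates in — arise naturally from
products of mean CP10K values.

Significance is calibrated empirically. Per bootstrap iteration the cells of
the sender and receiver groups are independently resampled with replacement,
group averages are recomputed, and `database_size` pseudo-receptor genes are
drawn uniformly without replacement from all detected genes, each paired
with a ligand drawn uniformly from the database's detected ligands; the
products form the null sample. Pooling 1,000 iterations gives
`1000 * database_size` null scores. The one-sided empirical p-value of an
observed score uses the add-one estimator $p = (1 + \#\{\text{null} \ge
S\}) / (1 + N)$, so p is never zero, and is Bonferroni-corrected by the
number of scored pairs in the comparison. A pair is significant when the
corrected p falls below `alpha` (default 0.01, one-sided).

"Resampling the dataset with replacement" admits several readings — cell
bootstrap, gene-label permutation, or count resampling. We implement the
cell bootstrap plus random pseudo-receptor genes because it preserves each
gene's expression distribution and the cell-level sampling noise of the
group averages, which is what the observed scores inherit. The bootstrap
adds sampling variance on top of the gene-pool spread, which makes the null
slightly heavy-tailed relative to the observed pair scores; calibration is
therefore conservative, and the test suite verifies family-wise error below
the nominal 0.01 on null datasets.

Two further conventions matter:

* **Family definition.** Bonferroni's *m* is the number of scored pairs
  within one (sender, receiver, region) comparison, each comparison having
  its own null. The guarantee is per comparison family.
* **Cutoff as outcome.** The score cutoff reported by `determine_cutoff()`
  (the smallest observed score whose corrected p clears `alpha`) is a
  property of the dataset, not a constant of the method. A published
  fixed cutoff can be reproduced with the `fixed_cutoff` argument of
  `score_interactions()`.

## Database assembly

The database starts from a reference list of established ligand–receptor
pairs (displayed in uppercase, e.g. `PDGFB–PDGFRB`). To find novel
interactions it is supplemented with candidates derived from regional DE
genes of the sender-relevant subtypes (cECs and astrocytes by default): a DE
gene seeds candidates only if its annotated subcellular localization is
plasma membrane, secreted or extracellular matrix, and its partners are the
PPI neighbors carrying an experimental-evidence flag. Candidate pairs are
displayed in original symbol case (e.g. `Bsg–Itga6`).

Candidates are added in **both orientations** because DE status does not
reveal which member acts as ligand; the orientation that scores
significantly resolves direction empirically. Duplicates resolve in favor of
`established`, so display-case semantics are stable. Genes missing from the
localization annotation are ineligible — candidacy requires positive
evidence — and localization vocabulary outside the controlled set collapses
to `other`, never to an eligible class. Localization and PPI evidence are
consumed as file snapshots rather than live queries, so a run is exactly
reproducible offline.

## QC and differential expression

Cells pass QC iff all of: genes detected ≥ 500; total UMIs ≥ 750
("reads per cell" is interpreted as UMI totals, the only counts the
pipeline holds); mitochondrial percentage ≤ 15; novelty index — genes
detected divided by total UMIs, a library-complexity measure — ≥ 0.4.
Thresholds are inclusive on the passing side. Doublet scores and
empty-droplet FDRs are consumed as optional annotation columns produced by
external tools (cells fail on score > 0.25 or FDR > 0.01); the package does
not reimplement doublet or empty-droplet detection. Zero-count cells get
novelty 0 (thus fail) rather than an undefined ratio.

DE uses the two-sided Wilcoxon rank-sum test with midranks: exact
enumeration of all group assignments when the pooled size is ≤ 20,
otherwise a normal approximation with tie-corrected variance and no
continuity correction (the convention of the single-cell toolkits this gate
vocabulary comes from). Genes are tested only if detected in ≥ `min_pct`
(default 0.25) of one group and their average log2 fold change — computed
with pseudocount 1 on the linear mean scale — passes the threshold.
Adjustment (Benjamini–Hochberg by default, Bonferroni by flag) is applied
over tested genes only, after both gates. Two threshold conventions are
exposed rather than one default "the" value: 0.25 log2 units for cluster
markers, 0.6 (i.e. > 1.5-fold, since $2^{0.6} \approx 1.52$) for regional
enrichment.

## The synthetic-data generator

`generate_dataset()` emulates the two-region vascular design: cortex and ME,
each with cECs, pericytes, astrocytes and fibroblasts, plus ME tanycytes.
The generative model is a standard overdispersed scRNA-seq surrogate:
per-gene baseline rates are lognormal(0, 0.5); per-cell library sizes are
lognormal(log 1800, 0.15); counts are negative binomial (size 2) with mean
= library size × the gene's rate share in its (region, subtype). Defaults
of 2,000 genes (50 mitochondrial, at twice the baseline rate) and 150 cells
per subtype keep a full pipeline run under a minute while matching the
per-cluster cell numbers a study of rare vascular subtypes actually has to
work with. With a 2,000-gene panel, library sizes near 1,800 UMIs put clean
cells comfortably above all four QC thresholds (novelty ≈ 0.5–0.6), so the
kept/rejected partition is decided by construction, not chance.

Planted signal defines the ground truth. Markers (default: 10 genes at fold
5 in ME cECs) emulate regional cEC enrichment. Planted ligand–receptor
pairs (default: 8 pairs at fold 5 on both sides; cEC senders; pericyte and
astrocyte receivers; half in each region) have the ligand's rate multiplied
in the sender group and the receptor's in the receiver group. Two modeling
choices deserve explanation:

* **Planted genes sit on well-expressed baselines** (3× the central rate).
  Real vascular signaling genes detectable by this method are
  well-expressed in their source cell types; planting on the baseline
  lottery instead would conflate fold-change recovery with expression-level
  luck.
* **Markers are planted in the sender subtype only.** A marker planted in a
  receiver subtype becomes a high pseudo-receptor gene in that comparison's
  null and sits at exactly the planted-pair score level, so marker recovery
  and pair recovery would confound each other. Regional cEC markers are
  also the ones such studies validate by immunostaining. Astrocyte DE is
  still exercised because planted astrocyte receptors are regionally DE.

Half of the planted pairs are seeded into the 200-pair reference database
(the rest of which is random decoy pairs); the other half can only be
recovered through the DE → localization → PPI candidate route, so recovery
tests exercise the full database-assembly path. Contaminants are emitted as
fractions of the clean cell count (5% each): low-quality cells draw 150–600
total counts (deterministically below the 750 threshold), doublets are the
elementwise sum of two clean cells of the same region with doublet score
in (0.3, 0.9), and empty droplets draw 20–200 counts from the ambient
average profile with FDR in (0.05, 1) — each class fails QC by
construction, so QC tests are deterministic.

Seeding uses one master seed with per-stage derived streams
(`stage_seed()`), so adding a stage never perturbs earlier draws and
identical configurations are bit-identical.

What the generator does **not** emulate: gene–gene correlation structure,
batch or replicate effects, ambient-RNA contamination of clean cells, and
multi-subunit receptor complexes. Passing the recovery and calibration
tests therefore shows the pipeline's statistics behave as claimed under a
faithful null and planted-signal model — not that any particular biological
dataset satisfies those assumptions.

## Numerical and degenerate-input choices

* Natural log for normalization; fold changes reported in log2.
* Pseudocount 1 on the de-logged mean scale in `avg_log2fc()`
  (configurable).
* Empirical p uses `>=` on ties; `p = 1` for score 0 against a nonnegative
  null, and `score == 0` is never significant.
* `determine_cutoff()` returns `Inf` when no observed score qualifies.
* Zero-total cells normalize to all zeros; empty groups are errors, not
  NaNs.
* Internal indexing is 0/1-based per R convention; MatrixMarket files are
  1-based on disk as the format specifies.
* Gene symbols are case-sensitive keys; only annotation lookups are
  case-insensitive, because symbol case encodes provenance in display
  names.

## Problem sizes used by the validation suite

The packaged checks run at the generator's default scale: calibration uses
50 replicate null datasets (~2,000 genes, 150 cells per subtype, a ~200-pair
database, 1,000 bootstrap iterations each) and verifies that the fraction
of datasets with any significant call is consistent with ≤ 0.01; recovery
verifies ≥ 90% of planted pairs and markers are found with none flagged by
the non-specific screen; oracle checks compare the exact Wilcoxon p against
exhaustive enumeration for all pooled sizes ≤ 10 and the whole scoring path
against a brute-force reference on a miniature instance.

## The non-specific pair screen

When scoring ME pericyte receivers against profiles obtained by a different
technology (e.g. an external segment-level average-expression profile fed
in via `ingest_external_profile()`), pairs that clear the threshold in
every ME receiver subtype *except* pericytes are flagged
`excluded_nonspecific` — that pattern is the signature of a methodological
offset rather than pericyte-specific signaling. The rule is a literal set
comparison: a pair significant *only* for pericytes, or significant
everywhere *including* pericytes, is retained. External profiles are used
as-is (no rescaling is attempted; cross-platform scale comparability is the
user's responsibility) and their provenance is recorded in the results.

## Known limitations

* Single-gene pairs only; no multi-subunit receptor complexes or
  pathway-level aggregation.
* Clustering, integration and cell-type assignment are upstream of the
  package: subtype labels are taken as given.
* The bootstrap null is built per comparison; scores are not comparable
  across comparisons with different receivers.
* With an external receiver profile, only the sender side is resampled, so
  the null does not reflect uncertainty in the external measurements.
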