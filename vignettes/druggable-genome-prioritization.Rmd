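---
title: "Cross-referencing risk genes with the druggable genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-referencing risk genes with the druggable genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetprio)
```

## The analysis

`targetprio` integrates gene-level disease association results with an
approved-drug target catalog, a clinical repurposing trial list and
IDG-style target metadata. Everything downstream is set algebra over
UniProt-accession-keyed sets, so the substance of the method is in how those
sets are built: which associations count, how symbols map to accessions, how
trial drugs' targets are curated, and how the annotation axes are scored.
This vignette records those rules, the tunable parameters, and the design
choices made where the procedure was genuinely open.

### Evidence ingest

Each association row carries a gene symbol, an analysis kind, a study id, an
optional P value, an optional TWAS expression reference panel and a
genome-wide significance flag. The evidence class is a deterministic
function of the analysis kind: GWAS and PheWAS are common variation, CNV and
exome sequencing rare variation, TWAS and expression profiling
expression-related variation. Rows failing validation (unparseable or
out-of-range P values, unknown analysis kinds, missing symbols) are
collected into a rejects report, never silently dropped. Duplicated rows
(same gene, study and panel) are collapsed with a warning and all counts are
reported after collapse.

Symbols are normalised (upper case, trimmed) and resolved only through the
supplied mapping table — no live lookups, so a run is reproducible offline.
A symbol mapping to several accessions expands to one association per
accession, with the multiplicity recorded in a provenance column; symbols
absent from the mapping go to an unmapped report. Merging is by accession:
one entity per accession, evidence classes the union over its associations.
The merge is idempotent and invariant to row order.

The genome-wide subset retains entities with at least one genome-wide
flagged association from a whitelisted study (the studies that report
genome-wide significance). Per-source association and unique-gene counts are
both reported because they legitimately differ — a gene can be genome-wide
in two studies of the same kind, and TWAS P values from different expression
reference panels are kept as discrete entries rather than being averaged.
For ranking within a study the minimum P per gene is the natural derived
value; P values are never compared across analysis types, so the priority
table carries study-scoped significance only.

### Trial-drug curation

Trial drugs are approved drugs, so their raw target annotations come from
the catalog by name (case-insensitive, punctuation stripped; salts and
esters are distinct drugs unless the input maps them). Drugs whose
annotations contain no human target are cross-referenced against a human
mechanism-of-action table; matches append human annotations, and drugs with
no human target anywhere are excluded with an explicit reason. The remap is
idempotent.

Subunit annotations sharing a complex identifier and protein class
consolidate to one representative — the lexicographically smallest accession
— so a receptor complex counts as one target. When no complex identifier is
given, annotations sharing a ChEMBL target id are treated as one complex.

At most two protein-class entries are then retained per drug, ranked by
(1) membership of the accession in the risk-gene set, (2) the integer
primary-therapeutic-relevance rank supplied in the input (1 = primary), and,
for the second entry, (3) mechanistic diversity — a second entry from a
different level-1 class is preferred when available. Ties break
lexicographically by accession then ChEMBL target id, making curation
deterministic and invariant to input order. Two of these rules required
operationalising: "primary therapeutic relevance" is taken as an explicit
rank column rather than free-text interpretation, and "mechanistic diversity
across the drug set" is applied per drug (the second entry should differ in
level-1 class) because a set-level notion has no unique algorithmic reading.

### Two matching levels, two denominators

Gene-level repurposing status and target-level genetic support are computed
at different levels deliberately. A druggable gene is `T_clinical_repurposing`
when its accession appears among the trial drugs' human target accessions
*before* consolidation — every subunit of a targeted complex matches. The
genetically supported share of the trial pipeline is computed over the
*curated, consolidated* target list — a complex of several risk-gene
subunits is one supported target. The two numbers therefore differ by
exactly the complex structure, and both are reported. Likewise the supported
share is printed against both denominators (per trial drug and per curated
trial target) since the ratio is ambiguous otherwise.

### Class distributions

Genetic targets are tallied by target (each druggable gene once, using its
catalog class path; conflicting paths across drugs resolve to the most
frequent, logged). Trial targets are tallied by drug over curated entries,
so a target's share is proportional to the number of drugs hitting it.
Level-1 classes are used, with seven-pass-transmembrane (7TM/GPCR) receptors
broken out of the membrane receptor class. Comparing the two sides
elementwise (missing classes imputed as zero) intentionally crosses
weightings and emits a warning saying so. Proportions are kept raw in
machine output and rounded to integer percentages in reports.

### Target development levels and the priority axes

TDL assignment is a total function with precedence
`Tclin_RP > Tclin > Tchem > Tbio > Tdark`: approved-and-trialled targets are
`Tclin_RP`, approved-only targets `Tclin`, everything else keeps its base
level from the metadata. A base label of `Tclin` on an accession absent from
the approved catalog is an inconsistency; approved-set membership wins and
the label is demoted to `Tbio` — the strongest claim the remaining evidence
supports — with the case logged and returned as an attribute.

The mouse neurophenotype score counts how many of the two Mammalian
Phenotype index terms (MP:0003631 "nervous system phenotype", MP:0005386
"behavior/neurological phenotype") are annotated: NA when no phenotype data
exist, otherwise 0, 1 or 2. Score 2 requires *both* terms — the "either"
reading would duplicate score 1 — and the score is invariant to non-index
terms; malformed identifiers are ignored with a warning. Missing metadata is
never coerced to zero: nulls propagate and are excluded from threshold
counts.

Two thresholds are configurable with the defaults used throughout: genes
count as having chemical-target interaction data when ChEMBL activity > 0
(the stricter > 10 cut is used only for labelling exported figure layers),
and the low-HDA shortlist keeps genes with Harmonizome data-availability
score < 10. ChEMBL-derived metrics are snapshot-dependent, so the metadata
snapshot identifier travels through the input table into the outputs.

## The synthetic-data generator

The generator emits all input tables from a reserved namespace
(`SYNG*`/`SYNP*`/`SYNB*`), so fixtures can never be mistaken for real
annotations, plus a manifest of every downstream count enumerated directly
from the planted structure during generation — never by calling the
pipeline. Identical seeds give byte-identical bundles; all randomness is
scoped to one seeded generator.

The configuration is parameterised by explicit counts rather than fractions:
genes per Venn block of the genome-wide source sets, extra association rows
(second studies, additional TWAS panels, within-class duplicates,
cross-class memberships), planted druggable partition cells, and the trial
structure (microbial/remappable drugs, multi-target drugs, risk-gene
complexes, target totals). Counts were chosen over fractions because the
downstream quantities are exact set-algebra outcomes; rounding fractional
overlaps cannot plant a 56-gene druggable set partitioned 24/17/7/8, while
counts can, and infeasible combinations are rejected by validation before
any file is written.

`paper_scale_profile()` is the study-conditions configuration: 435/246/338
associations per class merging to 748 unique genes; 769 genome-wide
associations over 573 unique (416 GWAS associations over 414 genes —
deliberately planting the two-count discrepancy so the pipeline reports
both; 241 TWAS over 152; 112 CNV); a 56-gene druggable set targeted by 187
drugs inside a 667-target druggable genome; 89 trial drugs (7 with only
microbial targets, of which 4 remap and 3 are excluded), 20 multi-target
drugs, and five subunit complexes (sizes 3,2,2,2,2) through which 29
trial-matched risk genes consolidate onto 23 supported targets among 76;
genome-wide TDL counts 46/361/138 for Tchem/Tbio/Tdark next to the 28
genome-wide druggable genes; annotation tiers 60/266/29; shortlists 27
(low HDA), 9 dark-genome neurophenotype genes (3 multi-source) and 37/15
transcription factors. The planted protein-class counts (22 ion channels
among the 56 genetic targets; an ion-channel-lighter, transporter- and
7TM-heavier mix over the non-risk trial targets) reproduce the qualitative
contrast between the genetic and clinical-trial class distributions.
Quantities not pinned by those counts (which genes land where, P values,
metadata values) are drawn per seed.

What the generator does *not* emulate: linkage disequilibrium and locus
structure, effect sizes, realistic pathway topology, or biologically
correlated metadata (its annotation axes are planted independently given the
TDL). Passing tests therefore demonstrate that the pipeline's set algebra,
curation rules and scoring are correct on inputs with the study's tabular
and statistical structure — not that the biological conclusions generalise
to other datasets.

## Numerical and degenerate-input choices

P values must lie in (0, 1]; the −log10 transform rejects anything else.
Empty inputs flow through every operation (empty tables, empty whitelists
and empty trial sets yield empty, well-typed results). All set-valued
outputs are sorted, all curation ties break lexicographically, and repeated
runs on identical inputs produce byte-identical machine outputs (the
provenance block records input checksums, not timestamps). Problem sizes
used in the test-suite equivalence checks — twenty seeded configurations of
roughly 300 genes and 30 trial drugs plus one paper-scale run — were chosen
so the full suite exercises every rule path at the study's structure.

## Known limitations

- Risk-gene lists are taken as given: no SNP-level processing, locus
  definition, fine-mapping or direction-of-effect inference.
- The matching is only as complete as the drug-target annotation supplied;
  broader interaction databases (binding rather than mechanism-of-action)
  would implicate more targets at lower confidence.
- The HDA score is consumed as input metadata, never computed.
- No composite priority score is invented: the axes are reported side by
  side, and any scalarisation is the analyst's choice.
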