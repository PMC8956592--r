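# targetprio

Cross-referencing of disease risk-gene lists with the druggable genome, for
drug-repurposing triage and target prioritisation.

Large genetic association studies of schizophrenia implicate hundreds of risk
genes across three evidence classes — common variation (GWAS, PheWAS), rare
variation (CNV, exome sequencing) and expression-related variation (TWAS,
expression profiling). Only a fraction of those genes encode proteins that
approved drugs already hit; knowing which ones, and how they relate to the
drugs currently in clinical repurposing trials, separates immediate
repurposing opportunities from targets that first need basic
characterisation. `targetprio` implements that analysis as a tested,
reusable pipeline for anyone integrating gene-level association results with
drug-target catalogs and IDG-style target metadata.

## What the pipeline computes

Writing `C`, `R`, `E` for the per-class risk-gene sets (merged on UniProt
accession), `D` for the human target accessions of the approved-drug
catalog, and `T` for the human target accessions of clinical repurposing
trial drugs after curation, the pipeline computes:

- the **druggable set** `G = (C ∪ R ∪ E) ∩ D`, its per-drug index, and its
  partition into genes unique to one evidence class vs multi-class genes;
- **repurposing status**: `T_clinical_repurposing` for genes of `G` matched
  by a trial drug's target, `T_clinical` (novel opportunities) otherwise,
  and the genetically supported share of trial targets `T ∩ (C ∪ R ∪ E)`;
- **protein class distributions** (ChEMBL hierarchy, 7TM receptors broken
  out) of genetic targets weighted by target and of trial targets weighted
  by drug, plus their per-class comparison;
- **target development levels** over the genome-wide significant subset —
  `Tclin_RP > Tclin > Tchem > Tbio > Tdark` — where `Tclin_RP` is the
  approved-and-trialled intersection, against druggable-genome (n = 667)
  and whole-genome (n = 20,120) backgrounds;
- the **multi-axis prioritisation table** (one row per gene x source study x
  expression panel): −log10 P, approved-drug count, ChEMBL activity,
  synaptic/total pathway counts, disease count, grant dollars, patent count,
  HDA score, and the mouse neurophenotype score (0–2 or NA: the number of
  the Mammalian Phenotype index terms MP:0003631 "nervous system phenotype"
  and MP:0005386 "behavior/neurological phenotype" annotated to the gene's
  mouse orthologue);
- **shortlists** of underexplored targets: dark-genome genes with mouse
  neurophenotypes (flagged when supported by several analysis methods),
  genes with low Harmonizome data-availability scores, transcription-factor
  summaries, and the per-source gene-set intersections.

Trial drugs are curated per the published rules: drugs with only microbial
targets are remapped through a human mechanism-of-action table or excluded;
subunit annotations within one target complex are consolidated; at most two
protein-class entries are retained per drug, ranked by risk-gene match, then
primary therapeutic relevance, then mechanistic diversity, with
lexicographic tie-breaks.

A first-class synthetic-data module generates all input tables with
configurable overlap structure from a reserved namespace (`SYNG*`/`SYNP*`),
together with a ground-truth manifest of every downstream count enumerated
directly during generation — so the whole pipeline is testable with no
external downloads, and `paper_scale_profile()` reproduces the published
study conditions exactly.

## Worked example

```r
library(targetprio)

bundle <- generate_bundle(paper_scale_profile(seed = 17), "bundle")
summary <- run_all(run_config(bundle_dir = "bundle", out_dir = "out"))
writeLines(head(write_report(summary), 16))
```

```
druggable-genome cross-referencing report
=========================================
risk-gene associations parsed: 1019 (+0 rejects)
unique risk genes: 748
genome-wide significant: 573 genes / 769 associations
  GWAS 414 genes (416 associations) | TWAS 152 (241) | CNV 112 (112)
  note: association and unique-gene counts differ (multi-study/panel)

druggable genes: 56 (targeted by 187 approved drugs)
  evidence partition: 24 common-only / 17 rare-only / 7 expression-only / 8 multi-class
  repurposing status: 29 T_clinical_repurposing / 27 T_clinical (novel)

trial drugs: 89 (3 excluded, no human target)
  curated targets: 76 unique over 106 entries (1.23 per drug)
  genetically supported targets: 23
    = 26% of 89 trial drugs | 30% of 76 trial targets
```

1019 associations merge to 748 unique genes; 56 of them are targets of 187
approved drugs; 29 of those are already hit by repurposing-trial drugs,
leaving 27 novel repurposing opportunities; and 23 of the 76 curated trial
targets are genetically supported — reported against both denominators (per
trial drug and per trial target) because the two ratios answer different
questions.

The same analysis, written as a narrative workflow, lives under `analysis/`:
`01_simulate.R` (generate the inputs and their manifest), `02_run_pipeline.R`
(run everything and verify each count against the manifest) and
`03_summarise_findings.R` (TDL distribution, annotation tiers, shortlists),
each writing its tables under `results/`.

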