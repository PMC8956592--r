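#!/usr/bin/env Rscript
# Step 3 — summarise the prioritization findings.
#
# Reads the machine summary from step 2 and prints the prioritization
# story: the genome-wide TDL distribution against its genome backgrounds,
# the annotation tiers, the shortlists of underexplored targets, and the
# genetic-vs-trial protein-class comparison. Headline counts go to
# results/tables/headline_counts.tsv.

library(targetprio)

summary_path <- "results/pipeline/summary.json"
if (!file.exists(summary_path)) stop("run analysis/02_run_pipeline.R first")
s <- jsonlite::read_json(summary_path)
co <- s$counts

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
headline <- tibble::tibble(quantity = names(co),
                           value = unlist(co, use.names = FALSE))
readr::write_tsv(headline, "results/tables/headline_counts.tsv")

n_gw <- co$n_gw_genes
cat(sprintf("genome-wide TDL distribution over %d genes:\n", n_gw))
cat(sprintf("  Tclin_RP %d + Tclin %d (%.0f%%) | Tchem %d (%.0f%%) | Tbio %d (%.0f%%) | Tdark %d (%.0f%%)\n",
            co$tdl_Tclin_RP, co$tdl_Tclin,
            100 * (co$tdl_Tclin_RP + co$tdl_Tclin) / n_gw,
            co$tdl_Tchem, 100 * co$tdl_Tchem / n_gw,
            co$tdl_Tbio, 100 * co$tdl_Tbio / n_gw,
            co$tdl_Tdark, 100 * co$tdl_Tdark / n_gw))
cat(sprintf("  backgrounds: druggable genome n=%d, total genome n=%d\n",
            s$tdl_background$druggable_genome, s$tdl_background$total_genome))
cat(sprintf("annotation tiers: %d genes with ChEMBL activity, %d with mouse neurophenotypes, %d with synaptic pathways\n",
            co$tier_chembl, co$tier_neuro, co$tier_synaptic))
cat(sprintf("underexplored: %d dark-genome genes with neurophenotypes (%d multi-source), %d genes with HDA < threshold\n",
            co$n_tdark_neuro, co$n_tdark_neuro_multisource, co$n_low_hda))
cat(sprintf("source intersections: %d genes in all three sources, GWAS-TWAS overlap %d\n",
            co$n_all_sources, co$n_overlap_GWAS_TWAS))
cat(sprintf("transcription factors: %d genome-wide, %d with neurophenotypes\n",
            co$n_tf, co$n_tf_neuro))
cat(sprintf("genetically supported trial targets: %d = %.0f%% of %d trial drugs, %.0f%% of %d trial targets\n",
            co$n_supported_targets,
            100 * s$supported_share$of_trial_drugs, co$n_trial_drugs,
            100 * s$supported_share$of_trial_targets, co$n_trial_targets))
cat("full text report: results/pipeline/report.txt\n")
cat("headline table: results/tables/headline_counts.tsv\n")
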