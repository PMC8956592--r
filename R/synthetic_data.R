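# Synthetic input bundle generator with a ground-truth manifest.
#
# Emits the four pipeline input tables (evidence associations, symbol map,
# approved-drug catalog, trial drug list, plus the auxiliary human-MOA and
# target-metadata tables) from a reserved synthetic namespace
# (SYNG*/SYNP*/SYNB*/...), together with a manifest of every downstream
# count, enumerated directly from the planted structure during generation —
# never by calling the pipeline. Identical seeds give byte-identical bundles.

GW_STUDIES <- c(GWAS = "GWAS_META", TWAS = "TWAS_PANELS", CNV = "CNV_META")
GW_STUDIES_EXTRA <- c(GWAS = "GWAS_META2", CNV = "CNV_META2")
NONGW_STUDY <- c(common = "PHEWAS_SCAN", rare = "EXOME_SEQ",
                 expression = "EXPR_DE")
NONGW_KIND <- c(common = "PheWAS", rare = "exome",
                expression = "expression_profiling")
TWAS_PANELS_SET <- c("BRAIN", "BLOOD", "ADIPOSE", "CORTEX")

#' Default study whitelist of the synthetic bundles
#'
#' The synthetic studies flagged as reporting genome-wide significance.
#' @return Character vector of study ids.
#' @export
synthetic_study_whitelist <- function() {
  unname(c(GW_STUDIES, GW_STUDIES_EXTRA))
}

default_class_probs_genetic <- function() {
  c("ion channel" = 0.30, "enzyme" = 0.25, "7TM" = 0.12, "transporter" = 0.08,
    "transcription factor" = 0.06, "secreted" = 0.05, "structural" = 0.03,
    "surface antigen" = 0.03, "enzyme modulator" = 0.03,
    "epigenetic regulator" = 0.02, "auxiliary transport protein" = 0.02,
    "membrane receptor" = 0.01)
}

default_class_probs_trial <- function() {
  c("transporter" = 0.20, "7TM" = 0.20, "enzyme" = 0.25, "ion channel" = 0.06,
    "transcription factor" = 0.07, "secreted" = 0.06, "structural" = 0.03,
    "surface antigen" = 0.03, "enzyme modulator" = 0.04,
    "epigenetic regulator" = 0.03, "auxiliary transport protein" = 0.02,
    "membrane receptor" = 0.01)
}

#' Synthetic bundle configuration
#'
#' Counts are explicit (genes per Venn block of the genome-wide source sets,
#' planted druggable partition cells, trial-target structure) so that the
#' generator has exact control over every downstream set-algebra outcome; the
#' manifest records them all. Infeasible combinations (overlaps larger than
#' the sets they intersect, planted cells larger than their pools, more
#' targets than curation slots) raise a validation error before any file is
#' written.
#'
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @param gw_genes Named counts of unique genome-wide genes per source
#'   (GWAS, TWAS, CNV).
#' @param gw_overlap Named counts `gwas_twas`, `gwas_cnv`, `twas_cnv`
#'   (pairwise overlaps, each including the triple) and `triple`.
#' @param gw_extra_assoc Extra genome-wide association rows per source on
#'   already-planted genes (second genome-wide study for GWAS/CNV, additional
#'   expression reference panels for TWAS).
#' @param nongw_genes Class-unique genes supported only by a study not
#'   reporting genome-wide significance (common, rare, expression).
#' @param nongw_dup_assoc Extra non-genome-wide association rows placed on
#'   existing genome-wide genes of each class.
#' @param crossclass_nongw Named counts (`rare`, `expression`): GWAS-only
#'   genome-wide genes additionally given a non-genome-wide association in
#'   another class, creating multi-class evidence.
#' @param n_multi_accession Symbols mapped to two accessions (1:2 mapping
#'   expansion), taken from the non-genome-wide common genes.
#' @param druggable Planted druggable partition: lists `common_only`,
#'   `rare_only`, `expression_only` (each `c(gw =, nongw =)`) and `multi`
#'   (count, drawn from the cross-class genes).
#' @param n_drugs_risk Approved (non-trial) drugs targeting the planted
#'   druggable genes; must be at least the number of druggable genes so each
#'   is covered.
#' @param n_background_targets Distinct non-risk human target accessions in
#'   the catalog (the rest of the druggable genome).
#' @param trial List: `n_drugs`, `n_microbial` (drugs with only microbial
#'   raw targets), `n_remappable` (microbial drugs present in the human-MOA
#'   table), `n_multi_target` (drugs with several raw targets), `n_risk_genes`
#'   (risk genes hit by trial drugs), `complex_sizes` (subunit complexes
#'   within the risk genes; consolidation collapses each to one target),
#'   `n_targets` (unique curated trial targets), `n_drugs_on_risk` (distinct
#'   trial drugs with a risk-gene entry).
#' @param tdl_gw Optional named counts (`Tchem`, `Tbio`, `Tdark`) for
#'   non-druggable genome-wide genes; when `NULL`, derived from
#'   `tdl_mixture`.
#' @param tdl_mixture Proportions over the four base levels; the `Tclin`
#'   share is realised through the planted druggable genes, the remainder is
#'   renormalised over `Tchem`/`Tbio`/`Tdark`.
#' @param triple_tdl Base TDLs recycled over the genes common to all three
#'   sources.
#' @param annot Planted annotation-tier counts over the genome-wide genes:
#'   `n_chembl` (ChEMBL activity > 0), `n_neuro` (neurophenotype score 1-2),
#'   `n_nodata` (explicit no-phenotype-data markers), `n_synaptic`,
#'   `n_low_hda`, `n_tdark_neuro` (+ `n_tdark_neuro_multisource`), `n_tf`
#'   (+ `n_tf_neuro`), and `hda_threshold`.
#' @param class_counts_genetic Optional named counts of class labels over the
#'   druggable genes (label "7TM" plants a membrane receptor with a 7TM
#'   level-2 class); `NULL` samples from a realistic default.
#' @param class_counts_trial_nonrisk Same, for the non-risk trial targets.
#' @param activity_geom_mean Mean of the geometric tail of positive ChEMBL
#'   activity counts.
#' @param snapshot_id Metadata snapshot identifier recorded in all outputs.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(
    seed = 17,
    gw_genes = c(GWAS = 120, TWAS = 50, CNV = 35),
    gw_overlap = c(gwas_twas = 25, gwas_cnv = 8, twas_cnv = 6, triple = 4),
    gw_extra_assoc = c(GWAS = 2, TWAS = 12, CNV = 1),
    nongw_genes = c(common = 45, rare = 55, expression = 30),
    nongw_dup_assoc = c(common = 4, rare = 3, expression = 5),
    crossclass_nongw = c(rare = 3, expression = 2),
    n_multi_accession = 2,
    druggable = list(common_only = c(gw = 6, nongw = 3),
                     rare_only = c(gw = 2, nongw = 3),
                     expression_only = c(gw = 2, nongw = 1),
                     multi = 4),
    n_drugs_risk = 25,
    n_background_targets = 60,
    trial = list(n_drugs = 32, n_microbial = 3, n_remappable = 2,
                 n_multi_target = 8, n_risk_genes = 10,
                 complex_sizes = c(2, 2), n_targets = 26, n_drugs_on_risk = 9),
    tdl_gw = NULL,
    tdl_mixture = c(Tclin = 0.05, Tchem = 0.08, Tbio = 0.63, Tdark = 0.24),
    triple_tdl = c("Tchem", "Tbio", "Tdark"),
    annot = list(n_chembl = 20, n_neuro = 70, n_nodata = 40, n_synaptic = 10,
                 n_low_hda = 8, n_tdark_neuro = 4,
                 n_tdark_neuro_multisource = 1, n_tf = 8, n_tf_neuro = 3,
                 hda_threshold = 10),
    class_counts_genetic = NULL,
    class_counts_trial_nonrisk = NULL,
    activity_geom_mean = 40,
    snapshot_id = "SYN-IDG-SNAPSHOT-1") {
  cfg <- list(
    seed = as.integer(seed), gw_genes = gw_genes, gw_overlap = gw_overlap,
    gw_extra_assoc = gw_extra_assoc, nongw_genes = nongw_genes,
    nongw_dup_assoc = nongw_dup_assoc, crossclass_nongw = crossclass_nongw,
    n_multi_accession = n_multi_accession, druggable = druggable,
    n_drugs_risk = n_drugs_risk, n_background_targets = n_background_targets,
    trial = trial, tdl_gw = tdl_gw, tdl_mixture = tdl_mixture,
    triple_tdl = triple_tdl, annot = annot,
    class_counts_genetic = class_counts_genetic,
    class_counts_trial_nonrisk = class_counts_trial_nonrisk,
    activity_geom_mean = activity_geom_mean, snapshot_id = snapshot_id
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Paper-scale synthetic configuration
#'
#' A configuration whose marginal counts match the published study
#' conditions: 435/246/338 associations per evidence class merging to 748
#' unique genes; 769 genome-wide associations (416 GWAS over 414 unique
#' genes, 241 TWAS over 152, 112 CNV) merging to 573; a planted druggable set
#' of 56 genes (partition 24/17/7/8) targeted by 187 drugs within a
#' 667-target druggable genome; 89 trial drugs (7 with only microbial
#' targets, 4 remappable, 3 excluded) with 76 curated targets of which 23 are
#' genetically supported, matching 29 risk genes through five subunit
#' complexes; genome-wide TDL mixture ~5/8/63/24%; annotation tiers
#' 60/266/29; and shortlist sizes 27 (low HDA), 9 (dark-genome
#' neurophenotypes, 3 multi-source), 37/15 (transcription factors).
#'
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
paper_scale_profile <- function(seed = 17) {
  synth_config(
    seed = seed,
    gw_genes = c(GWAS = 414, TWAS = 152, CNV = 112),
    gw_overlap = c(gwas_twas = 89, gwas_cnv = 12, twas_cnv = 10, triple = 6),
    gw_extra_assoc = c(GWAS = 2, TWAS = 89, CNV = 0),
    nongw_genes = c(common = 15, rare = 118, expression = 42),
    nongw_dup_assoc = c(common = 4, rare = 10, expression = 53),
    crossclass_nongw = c(rare = 6, expression = 2),
    n_multi_accession = 0,
    druggable = list(common_only = c(gw = 14, nongw = 10),
                     rare_only = c(gw = 2, nongw = 15),
                     expression_only = c(gw = 4, nongw = 3),
                     multi = 8),
    n_drugs_risk = 157,
    n_background_targets = 611,
    trial = list(n_drugs = 89, n_microbial = 7, n_remappable = 4,
                 n_multi_target = 20, n_risk_genes = 29,
                 complex_sizes = c(3, 2, 2, 2, 2), n_targets = 76,
                 n_drugs_on_risk = 30),
    tdl_gw = c(Tchem = 46, Tbio = 361, Tdark = 138),
    triple_tdl = c("Tchem", "Tchem", "Tbio", "Tbio", "Tdark", "Tdark"),
    annot = list(n_chembl = 60, n_neuro = 266, n_nodata = 120,
                 n_synaptic = 29, n_low_hda = 27, n_tdark_neuro = 9,
                 n_tdark_neuro_multisource = 3, n_tf = 37, n_tf_neuro = 15,
                 hda_threshold = 10),
    class_counts_genetic = c(
      "ion channel" = 22, "enzyme" = 16, "7TM" = 5,
      "transcription factor" = 2, "transporter" = 1, "membrane receptor" = 1,
      "secreted" = 2, "structural" = 1, "surface antigen" = 1,
      "epigenetic regulator" = 1, "enzyme modulator" = 2,
      "auxiliary transport protein" = 2),
    class_counts_trial_nonrisk = c(
      "transporter" = 10, "7TM" = 12, "enzyme" = 12, "ion channel" = 9,
      "transcription factor" = 4, "secreted" = 2, "structural" = 1,
      "surface antigen" = 1, "enzyme modulator" = 1,
      "epigenetic regulator" = 1)
  )
}

infeasible <- function(...) {
  stop("infeasible synthetic config: ", ..., call. = FALSE)
}

validate_synth_config <- function(cfg) {
  ov <- cfg$gw_overlap
  g <- cfg$gw_genes
  for (nm in c("gwas_twas", "gwas_cnv", "twas_cnv")) {
    if (ov[[nm]] < ov[["triple"]]) {
      infeasible("pairwise overlap ", nm, " smaller than triple overlap")
    }
  }
  if (ov[["gwas_twas"]] > min(g[["GWAS"]], g[["TWAS"]]) ||
      ov[["gwas_cnv"]] > min(g[["GWAS"]], g[["CNV"]]) ||
      ov[["twas_cnv"]] > min(g[["TWAS"]], g[["CNV"]])) {
    infeasible("overlap larger than a source set")
  }
  blocks <- gw_block_sizes(cfg)
  if (any(unlist(blocks) < 0)) infeasible("negative Venn block size")
  if (any(unlist(cfg$nongw_genes) < 0) || any(unlist(cfg$nongw_dup_assoc) < 0)) {
    infeasible("negative gene or association count")
  }
  if (sum(cfg$crossclass_nongw) + sum(cfg$druggable$common_only["gw"]) >
      blocks$G_only) {
    infeasible("GWAS-only block too small for cross-class and druggable picks")
  }
  if (cfg$druggable$multi > sum(cfg$crossclass_nongw)) {
    infeasible("more multi-class druggable genes than cross-class genes")
  }
  if (cfg$n_multi_accession > cfg$nongw_genes[["common"]]) {
    infeasible("more 1:2-mapped symbols than non-genome-wide common genes")
  }
  if (cfg$druggable$common_only[["nongw"]] + cfg$n_multi_accession >
      cfg$nongw_genes[["common"]]) {
    infeasible("non-genome-wide common pool too small")
  }
  if (cfg$druggable$rare_only[["gw"]] > blocks$C_only ||
      cfg$druggable$rare_only[["nongw"]] > cfg$nongw_genes[["rare"]] ||
      cfg$druggable$expression_only[["gw"]] > blocks$T_only ||
      cfg$druggable$expression_only[["nongw"]] > cfg$nongw_genes[["expression"]]) {
    infeasible("a druggable partition cell exceeds its gene pool")
  }
  n_druggable <- planted_druggable_count(cfg)
  if (cfg$n_drugs_risk < n_druggable && n_druggable > 0) {
    infeasible("n_drugs_risk must cover every druggable gene")
  }
  tr <- cfg$trial
  if (tr$n_remappable > tr$n_microbial) {
    infeasible("more remappable than microbial trial drugs")
  }
  if (tr$n_risk_genes > n_druggable) {
    infeasible("more trial risk genes than druggable genes")
  }
  if (length(tr$complex_sizes) > 0 && any(tr$complex_sizes < 2)) {
    infeasible("complex sizes must be at least 2")
  }
  if (sum(tr$complex_sizes) > tr$n_risk_genes) {
    infeasible("complex members exceed trial risk genes")
  }
  n_risk_targets <- tr$n_risk_genes - sum(pmax(tr$complex_sizes - 1, 0))
  n_nonrisk_targets <- tr$n_targets - n_risk_targets
  if (n_nonrisk_targets < tr$n_remappable) {
    infeasible("not enough non-risk trial targets for the remapped drugs")
  }
  n_singles <- tr$n_drugs - tr$n_microbial - tr$n_multi_target
  if (n_singles < 0) infeasible("more multi-target drugs than trial drugs")
  if (tr$n_drugs_on_risk > n_singles) {
    infeasible("risk entries are assigned to single-target drugs; too few")
  }
  if (tr$n_drugs_on_risk < n_risk_targets) {
    infeasible("too few risk-entry drugs to cover the risk targets")
  }
  if (tr$n_risk_genes == 0 && tr$n_drugs_on_risk > 0) {
    infeasible("risk-entry drugs require at least one trial risk gene")
  }
  nonrisk_slots <- (n_singles - tr$n_drugs_on_risk) + 2 * tr$n_multi_target +
    tr$n_remappable
  if (nonrisk_slots < n_nonrisk_targets) {
    infeasible("fewer curation slots than non-risk trial targets")
  }
  if (cfg$n_background_targets <
      (n_nonrisk_targets - tr$n_remappable) + tr$n_multi_target) {
    infeasible("background target pool too small for trial targets and decoys")
  }
  if (!is.null(cfg$tdl_gw)) {
    n_gw <- gw_unique_count(cfg)
    gw_druggable <- cfg$druggable$common_only[["gw"]] +
      cfg$druggable$rare_only[["gw"]] + cfg$druggable$expression_only[["gw"]] +
      cfg$druggable$multi
    if (sum(cfg$tdl_gw) != n_gw - gw_druggable) {
      infeasible("tdl_gw counts must sum to the non-druggable genome-wide genes")
    }
  }
  if (abs(sum(cfg$tdl_mixture) - 1) > 0.01) {
    infeasible("tdl_mixture must sum to 1")
  }
  if (!is.null(cfg$class_counts_genetic) &&
      sum(cfg$class_counts_genetic) != n_druggable) {
    infeasible("class_counts_genetic must sum to the druggable gene count")
  }
  if (!is.null(cfg$class_counts_trial_nonrisk) &&
      sum(cfg$class_counts_trial_nonrisk) != n_nonrisk_targets) {
    infeasible("class_counts_trial_nonrisk must sum to the non-risk targets")
  }
  an <- cfg$annot
  n_gw <- gw_unique_count(cfg)
  if (an$n_neuro + an$n_nodata > n_gw) {
    infeasible("neurophenotype and no-data sets exceed the genome-wide genes")
  }
  if (an$n_tdark_neuro_multisource > an$n_tdark_neuro ||
      an$n_tf_neuro > an$n_tf) {
    infeasible("a shortlist sub-count exceeds its parent count")
  }
  invisible(cfg)
}

gw_block_sizes <- function(cfg) {
  g <- cfg$gw_genes
  ov <- cfg$gw_overlap
  t3 <- ov[["triple"]]
  list(
    T3 = t3,
    GT = ov[["gwas_twas"]] - t3,
    GC = ov[["gwas_cnv"]] - t3,
    TC = ov[["twas_cnv"]] - t3,
    G_only = g[["GWAS"]] - ov[["gwas_twas"]] - ov[["gwas_cnv"]] + t3,
    T_only = g[["TWAS"]] - ov[["gwas_twas"]] - ov[["twas_cnv"]] + t3,
    C_only = g[["CNV"]] - ov[["gwas_cnv"]] - ov[["twas_cnv"]] + t3
  )
}

gw_unique_count <- function(cfg) {
  sum(unlist(gw_block_sizes(cfg)))
}

planted_druggable_count <- function(cfg) {
  d <- cfg$druggable
  sum(d$common_only) + sum(d$rare_only) + sum(d$expression_only) + d$multi
}

take <- function(pool, n, what) {
  if (n > length(pool)) infeasible("pool exhausted while picking ", what)
  if (n == 0) return(pool[0])
  sample(pool, n)
}

label_to_class <- function(labels) {
  l1 <- ifelse(labels == "7TM", "membrane receptor", labels)
  l2 <- dplyr::case_when(
    labels == "7TM" ~ "7TM",
    labels == "membrane receptor" ~ "catalytic receptor",
    labels == "ion channel" ~ "voltage-gated",
    TRUE ~ "family A"
  )
  tibble(class_l1 = l1, class_l2 = l2, class_l3 = "subfamily 1")
}

assign_labels <- function(n, counts = NULL, probs = NULL) {
  if (n == 0) return(character(0))
  if (!is.null(counts)) {
    if (sum(counts) != n) infeasible("class counts do not sum to pool size")
    return(sample(rep(names(counts), counts)))
  }
  sample(names(probs), n, replace = TRUE, prob = probs)
}

rand_p <- function(n, lo, hi) {
  signif(10^(-runif(n, lo, hi)), 6)
}

#' Generate a synthetic input bundle with a ground-truth manifest
#'
#' Writes `evidence.tsv`, `symbol_map.tsv`, `drug_catalog.tsv`,
#' `trial_drugs.tsv`, `human_moa.tsv`, `target_meta.tsv` and `manifest.json`
#' to `dir`. The manifest holds every downstream count and set, enumerated
#' from the planted structure during generation.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths` and `manifest`.
#' @export
generate_bundle <- function(config, dir) {
  validate_synth_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- withr::with_seed(config$seed, build_bundle(config))
  paths <- list(
    evidence = file.path(dir, "evidence.tsv"),
    symbol_map = file.path(dir, "symbol_map.tsv"),
    drug_catalog = file.path(dir, "drug_catalog.tsv"),
    trial_drugs = file.path(dir, "trial_drugs.tsv"),
    human_moa = file.path(dir, "human_moa.tsv"),
    target_meta = file.path(dir, "target_meta.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_tsv_out(out$evidence, paths$evidence)
  write_tsv_out(out$symbol_map, paths$symbol_map)
  write_tsv_out(out$catalog, paths$drug_catalog)
  write_tsv_out(out$trial, paths$trial_drugs)
  write_tsv_out(out$human_moa, paths$human_moa)
  write_tsv_out(out$meta, paths$target_meta)
  jsonlite::write_json(out$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dir = dir, paths = paths, manifest = out$manifest))
}

# the actual construction; runs under a fixed seed
build_bundle <- function(cfg) {
  blocks <- gw_block_sizes(cfg)
  tr <- cfg$trial
  an <- cfg$annot

  ## ---- gene universe -------------------------------------------------
  block_names <- c("T3", "GT", "GC", "TC", "G_only", "T_only", "C_only")
  block_of <- rep(block_names, times = unlist(blocks)[block_names])
  n_gw <- length(block_of)
  nongw_block <- rep(c("N_common", "N_rare", "N_expression"),
                     times = unlist(cfg$nongw_genes)[c("common", "rare",
                                                       "expression")])
  universe <- tibble(
    idx = seq_len(n_gw + length(nongw_block)),
    block = c(block_of, nongw_block)
  ) |>
    mutate(
      accession = sprintf("SYNP%05d", .data$idx),
      symbol = sprintf("SYNG%05d", .data$idx),
      in_G = .data$block %in% c("T3", "GT", "GC", "G_only"),
      in_T = .data$block %in% c("T3", "GT", "TC", "T_only"),
      in_C = .data$block %in% c("T3", "GC", "TC", "C_only"),
      n_sources = .data$in_G + .data$in_T + .data$in_C
    )

  # class membership from genome-wide sources and non-genome-wide blocks
  universe <- universe |>
    mutate(
      cl_common = .data$in_G | .data$block == "N_common",
      cl_rare = .data$in_C | .data$block == "N_rare",
      cl_expression = .data$in_T | .data$block == "N_expression"
    )

  # cross-class genes: GWAS-only genes gaining a non-genome-wide class
  g_only_pool <- universe$accession[universe$block == "G_only"]
  cross_rare <- take(g_only_pool, cfg$crossclass_nongw[["rare"]],
                     "cross-class rare genes")
  cross_expr <- take(setdiff(g_only_pool, cross_rare),
                     cfg$crossclass_nongw[["expression"]],
                     "cross-class expression genes")
  universe$cl_rare[universe$accession %in% cross_rare] <- TRUE
  universe$cl_expression[universe$accession %in% cross_expr] <- TRUE

  # 1:2-mapped symbols: twin accessions for non-genome-wide common genes
  twin_src <- take(universe$accession[universe$block == "N_common"],
                   cfg$n_multi_accession, "twin symbols")
  twins <- universe |>
    filter(.data$accession %in% twin_src) |>
    mutate(accession = sprintf("SYNP9%04d", dplyr::row_number()),
           block = "N_common_twin")
  universe_all <- bind_rows(universe, twins)

  symbol_map <- universe_all |>
    distinct(symbol = .data$symbol, accession = .data$accession) |>
    arrange(.data$symbol, .data$accession)

  ## ---- associations --------------------------------------------------
  rows <- list()
  gwas_genes <- universe |> filter(.data$in_G)
  twas_genes <- universe |> filter(.data$in_T)
  cnv_genes <- universe |> filter(.data$in_C)
  rows$gwas <- tibble(gene_symbol = gwas_genes$symbol, analysis_kind = "GWAS",
                      study_id = GW_STUDIES[["GWAS"]],
                      p_value = rand_p(nrow(gwas_genes), 8, 30),
                      expression_panel = NA_character_, genome_wide = TRUE)
  twas_panel1 <- sample(TWAS_PANELS_SET, nrow(twas_genes), replace = TRUE)
  rows$twas <- tibble(gene_symbol = twas_genes$symbol, analysis_kind = "TWAS",
                      study_id = GW_STUDIES[["TWAS"]],
                      p_value = rand_p(nrow(twas_genes), 8, 25),
                      expression_panel = twas_panel1, genome_wide = TRUE)
  rows$cnv <- tibble(gene_symbol = cnv_genes$symbol, analysis_kind = "CNV",
                     study_id = GW_STUDIES[["CNV"]],
                     p_value = rand_p(nrow(cnv_genes), 6, 15),
                     expression_panel = NA_character_, genome_wide = TRUE)

  # extra genome-wide rows: second study (GWAS/CNV), extra panels (TWAS)
  eg <- cfg$gw_extra_assoc
  extra_g <- take(gwas_genes$symbol, eg[["GWAS"]], "extra GWAS associations")
  rows$gwas2 <- tibble(gene_symbol = extra_g, analysis_kind = "GWAS",
                       study_id = GW_STUDIES_EXTRA[["GWAS"]],
                       p_value = rand_p(length(extra_g), 8, 20),
                       expression_panel = NA_character_, genome_wide = TRUE)
  extra_c <- take(cnv_genes$symbol, eg[["CNV"]], "extra CNV associations")
  rows$cnv2 <- tibble(gene_symbol = extra_c, analysis_kind = "CNV",
                      study_id = GW_STUDIES_EXTRA[["CNV"]],
                      p_value = rand_p(length(extra_c), 6, 12),
                      expression_panel = NA_character_, genome_wide = TRUE)
  n_extra_t <- eg[["TWAS"]]
  panel_pool <- tibble(gene_symbol = rep(twas_genes$symbol,
                                         each = length(TWAS_PANELS_SET)),
                       expression_panel = rep(TWAS_PANELS_SET,
                                              nrow(twas_genes))) |>
    anti_join(tibble(gene_symbol = twas_genes$symbol,
                     expression_panel = twas_panel1),
              by = c("gene_symbol", "expression_panel"))
  if (n_extra_t > nrow(panel_pool)) infeasible("too many extra TWAS panels")
  extra_t <- panel_pool |> slice(sample.int(dplyr::n(), n_extra_t))
  rows$twas2 <- tibble(gene_symbol = extra_t$gene_symbol,
                       analysis_kind = "TWAS",
                       study_id = GW_STUDIES[["TWAS"]],
                       p_value = rand_p(n_extra_t, 8, 25),
                       expression_panel = extra_t$expression_panel,
                       genome_wide = TRUE)

  # non-genome-wide rows: class-unique genes, duplicates on genome-wide
  # genes of the class, and the cross-class rows
  nongw_rows <- function(symbols, class) {
    tibble(gene_symbol = symbols, analysis_kind = NONGW_KIND[[class]],
           study_id = NONGW_STUDY[[class]],
           p_value = rand_p(length(symbols), 2, 5),
           expression_panel = NA_character_, genome_wide = FALSE)
  }
  rows$n_common <- nongw_rows(universe$symbol[universe$block == "N_common"],
                              "common")
  rows$n_rare <- nongw_rows(universe$symbol[universe$block == "N_rare"], "rare")
  rows$n_expr <- nongw_rows(universe$symbol[universe$block == "N_expression"],
                            "expression")
  dup <- cfg$nongw_dup_assoc
  rows$dup_common <- nongw_rows(take(gwas_genes$symbol, dup[["common"]],
                                     "common duplicate rows"), "common")
  rows$dup_rare <- nongw_rows(take(cnv_genes$symbol, dup[["rare"]],
                                   "rare duplicate rows"), "rare")
  rows$dup_expr <- nongw_rows(take(twas_genes$symbol, dup[["expression"]],
                                   "expression duplicate rows"), "expression")
  cross_sym <- function(acc) universe$symbol[match(acc, universe$accession)]
  rows$cross_rare <- nongw_rows(cross_sym(cross_rare), "rare")
  rows$cross_expr <- nongw_rows(cross_sym(cross_expr), "expression")

  evidence <- bind_rows(rows)
  evidence <- evidence[sample.int(nrow(evidence)), ]

  ## ---- druggable planting --------------------------------------------
  d <- cfg$druggable
  pool_common_gw <- setdiff(g_only_pool, c(cross_rare, cross_expr))
  pool_common_ngw <- setdiff(universe$accession[universe$block == "N_common"],
                             twin_src)
  druggable_accs <- c(
    take(pool_common_gw, d$common_only[["gw"]], "druggable common gw"),
    take(pool_common_ngw, d$common_only[["nongw"]], "druggable common nongw"),
    take(universe$accession[universe$block == "C_only"],
         d$rare_only[["gw"]], "druggable rare gw"),
    take(universe$accession[universe$block == "N_rare"],
         d$rare_only[["nongw"]], "druggable rare nongw"),
    take(universe$accession[universe$block == "T_only"],
         d$expression_only[["gw"]], "druggable expression gw"),
    take(universe$accession[universe$block == "N_expression"],
         d$expression_only[["nongw"]], "druggable expression nongw"),
    take(c(cross_rare, cross_expr), d$multi, "druggable multi-class")
  )
  druggable_accs <- sort(druggable_accs)
  n_druggable <- length(druggable_accs)

  # class labels per druggable gene
  genetic_labels <- assign_labels(
    n_druggable, counts = cfg$class_counts_genetic,
    probs = default_class_probs_genetic()
  )
  class_map <- tibble(accession = druggable_accs, label = genetic_labels)

  ## ---- trial structure -----------------------------------------------
  # complexes: groups of risk genes sharing a class
  complex_sizes <- tr$complex_sizes
  complex_members <- list()
  remaining <- class_map
  for (i in seq_along(complex_sizes)) {
    tallies <- remaining |> count(.data$label) |> arrange(dplyr::desc(.data$n))
    if (nrow(tallies) == 0 || tallies$n[1] < complex_sizes[i]) {
      infeasible("no protein class has enough genes for a complex of size ",
                 complex_sizes[i])
    }
    lab <- tallies$label[1]
    members <- take(remaining$accession[remaining$label == lab],
                    complex_sizes[i], "complex members")
    complex_members[[i]] <- members
    remaining <- remaining |> filter(!.data$accession %in% members)
  }
  n_singleton_risk <- tr$n_risk_genes - sum(complex_sizes)
  singleton_risk <- take(remaining$accession, n_singleton_risk,
                         "singleton trial risk genes")
  trial_risk_genes <- sort(c(unlist(complex_members), singleton_risk))

  risk_target_tbl <- bind_rows(
    purrr::imap_dfr(complex_members, function(m, i) {
      tibble(target = min(m), members = list(sort(m)),
             complex_id = sprintf("SYNC%02d", i),
             label = class_map$label[match(min(m), class_map$accession)])
    }),
    tibble(target = singleton_risk,
           members = lapply(singleton_risk, identity),
           complex_id = NA_character_,
           label = class_map$label[match(singleton_risk,
                                         class_map$accession)])
  )
  n_risk_targets <- nrow(risk_target_tbl)

  # non-risk targets: remapped MOA accessions + background catalog targets
  n_nonrisk_targets <- tr$n_targets - n_risk_targets
  bg_accs <- sprintf("SYNB%04d", seq_len(cfg$n_background_targets))
  moa_accs <- sprintf("SYNH%03d", seq_len(tr$n_remappable))
  bg_trial_accs <- take(bg_accs, n_nonrisk_targets - tr$n_remappable,
                        "background trial targets")
  nonrisk_accs <- c(moa_accs, bg_trial_accs)
  nonrisk_labels <- assign_labels(
    length(nonrisk_accs), counts = cfg$class_counts_trial_nonrisk,
    probs = default_class_probs_trial()
  )
  class_map <- bind_rows(class_map,
                         tibble(accession = nonrisk_accs,
                                label = nonrisk_labels))

  # decoys for multi-target drugs, matching the first entry's class
  decoy_pool <- setdiff(bg_accs, bg_trial_accs)

  # drug roster
  drug_names <- sprintf("SYNDRUG_T%03d", seq_len(tr$n_drugs))
  microbial_drugs <- drug_names[seq_len(tr$n_microbial)]
  remappable_drugs <- microbial_drugs[seq_len(tr$n_remappable)]
  excluded_drugs <- setdiff(microbial_drugs, remappable_drugs)
  nonmicrobial <- setdiff(drug_names, microbial_drugs)
  multi_drugs <- nonmicrobial[seq_len(tr$n_multi_target)]
  single_drugs <- setdiff(nonmicrobial, multi_drugs)

  # risk entries on single-target drugs: cover each risk target, extras random
  risk_drugs <- take(single_drugs, tr$n_drugs_on_risk, "risk-entry trial drugs")
  risk_entry_targets <- c(
    risk_target_tbl$target,
    if (tr$n_drugs_on_risk > n_risk_targets) {
      sample(risk_target_tbl$target,
             tr$n_drugs_on_risk - n_risk_targets, replace = TRUE)
    }
  )
  risk_entries <- tibble(drug_name = risk_drugs,
                         target = sample(risk_entry_targets))

  # non-risk entries: cover every non-risk target, extras random
  nonrisk_singles <- setdiff(single_drugs, risk_drugs)
  coverage <- sample(setdiff(nonrisk_accs, moa_accs))
  n_slots <- length(nonrisk_singles) + 2 * length(multi_drugs)
  pop <- function(n) {
    if (n == 0) return(character(0))
    picked <- head(coverage, n)
    coverage <<- coverage[-seq_len(length(picked))]
    if (length(picked) < n) {
      picked <- c(picked, sample(setdiff(nonrisk_accs, moa_accs),
                                 n - length(picked), replace = TRUE))
    }
    picked
  }
  lab_of <- function(acc) class_map$label[match(acc, class_map$accession)]
  multi_entries <- purrr::map_dfr(multi_drugs, function(dn) {
    a <- pop(1)
    # second target: prefer a different level-1 class, never the same target;
    # drain the coverage queue before sampling extras
    if (length(coverage) > 0) {
      alt_idx <- which(lab_of(coverage) != lab_of(a))
      pick <- if (length(alt_idx) > 0) alt_idx[1] else 1L
      b <- coverage[pick]
      coverage <<- coverage[-pick]
    } else {
      pool <- setdiff(nonrisk_accs, c(a, moa_accs))
      pool_diff <- pool[lab_of(pool) != lab_of(a)]
      b <- sample(if (length(pool_diff) > 0) pool_diff else pool, 1)
    }
    tibble(drug_name = dn, target = c(a, b), rank = c(1L, 2L))
  })
  single_nonrisk_entries <- tibble(
    drug_name = nonrisk_singles,
    target = pop(length(nonrisk_singles)),
    rank = 1L
  )
  if (length(coverage) > 0) infeasible("uncovered non-risk trial targets")
  moa_entries <- tibble(drug_name = remappable_drugs, target = moa_accs,
                        rank = 1L)

  planted_entries <- bind_rows(
    risk_entries |> mutate(rank = 1L),
    multi_entries,
    single_nonrisk_entries,
    moa_entries
  )

  ## ---- catalog rows ---------------------------------------------------
  class_cols <- function(accs) {
    label_to_class(lab_of(accs))
  }
  target_row <- function(drug, acc, rank, complex_id = NA_character_,
                         organism = "human") {
    bind_cols(
      tibble(drug_name = drug, molecule_type = "small molecule",
             moa = paste0("modulator of ", acc), accession = acc,
             chembl_target_id = paste0("SYNCHEMBL_", acc)),
      class_cols(acc),
      tibble(organism = organism, complex_id = complex_id,
             atc = "N05AX", approval_year = sample(1950:2015, 1),
             therapeutic_rank = rank)
    )
  }

  catalog_rows <- list()
  # trial drugs: expand risk entries to complex subunits; add decoys
  expand_entry <- function(drug, target, rank) {
    hit <- match(target, risk_target_tbl$target)
    if (!is.na(hit)) {
      members <- risk_target_tbl$members[[hit]]
      purrr::map_dfr(members, function(m) {
        target_row(drug, m, rank,
                   complex_id = risk_target_tbl$complex_id[hit])
      })
    } else {
      target_row(drug, target, rank)
    }
  }
  catalog_rows$trial_risk <- purrr::pmap_dfr(
    risk_entries |> mutate(rank = 1L),
    function(drug_name, target, rank) expand_entry(drug_name, target, rank)
  )
  catalog_rows$trial_multi <- purrr::pmap_dfr(
    multi_entries, function(drug_name, target, rank) {
      expand_entry(drug_name, target, rank)
    }
  )
  # one decoy per multi-target drug, same level-1 class as its first entry
  decoys <- purrr::map_dfr(multi_drugs, function(dn) {
    first_target <- multi_entries$target[multi_entries$drug_name == dn &
                                           multi_entries$rank == 1L]
    want <- lab_of(first_target)
    cand <- decoy_pool[is.na(match(decoy_pool, class_map$accession)) |
                         lab_of(decoy_pool) %in% want]
    acc <- if (length(cand) > 0) cand[1] else decoy_pool[1]
    decoy_pool <<- setdiff(decoy_pool, acc)
    if (!acc %in% class_map$accession) {
      class_map <<- bind_rows(class_map, tibble(accession = acc, label = want))
    }
    target_row(dn, acc, 3L)
  })
  catalog_rows$decoys <- decoys
  catalog_rows$trial_single <- purrr::pmap_dfr(
    single_nonrisk_entries, function(drug_name, target, rank) {
      target_row(drug_name, target, rank)
    }
  )
  # microbial drugs: only microbial annotations in the catalog
  catalog_rows$microbial <- purrr::map_dfr(seq_along(microbial_drugs),
    function(i) {
      tibble(drug_name = microbial_drugs[i], molecule_type = "small molecule",
             moa = "microbial enzyme inhibitor",
             accession = sprintf("SYNM%03d", i),
             chembl_target_id = sprintf("SYNCHEMBL_M%03d", i),
             class_l1 = "enzyme", class_l2 = "family A",
             class_l3 = "subfamily 1", organism = "microbial",
             complex_id = NA_character_, atc = "J01XX",
             approval_year = sample(1950:2015, 1), therapeutic_rank = 1L)
    })

  # approved (non-trial) drugs covering every druggable gene
  n_drugs_risk_eff <- if (n_druggable == 0) 0L else cfg$n_drugs_risk
  if (n_drugs_risk_eff > 0) {
    risk_drug_names <- sprintf("SYNDRUG_R%03d", seq_len(n_drugs_risk_eff))
    risk_assign <- c(druggable_accs,
                     if (n_drugs_risk_eff > n_druggable) {
                       sample(druggable_accs,
                              n_drugs_risk_eff - n_druggable, replace = TRUE)
                     })
    catalog_rows$risk_drugs <- purrr::map_dfr(seq_len(n_drugs_risk_eff),
      function(i) target_row(risk_drug_names[i], risk_assign[i], 1L))
  }

  # background drugs covering the rest of the druggable genome
  used_bg <- unique(c(bg_trial_accs,
                      catalog_rows$decoys$accession %||% character(0)))
  bg_rest <- setdiff(bg_accs, used_bg)
  # classes for untouched background accessions
  new_bg <- setdiff(bg_rest, class_map$accession)
  if (length(new_bg) > 0) {
    class_map <- bind_rows(class_map, tibble(
      accession = new_bg,
      label = assign_labels(length(new_bg),
                            probs = default_class_probs_trial())
    ))
  }
  if (length(bg_rest) > 0) {
    grp <- ceiling(seq_along(bg_rest) / 2)
    catalog_rows$background <- purrr::map_dfr(unique(grp), function(g) {
      accs <- bg_rest[grp == g]
      purrr::map_dfr(seq_along(accs), function(j) {
        target_row(sprintf("SYNDRUG_B%03d", g), accs[j], j)
      })
    })
  }

  catalog <- bind_rows(catalog_rows)
  catalog <- catalog[sample.int(nrow(catalog)), ]

  trial_tbl <- tibble(drug_name = drug_names,
                      n_trial_listings = sample(1:6, tr$n_drugs,
                                                replace = TRUE))

  human_moa <- bind_cols(
    tibble(drug_name = remappable_drugs, accession = moa_accs,
           chembl_target_id = paste0("SYNCHEMBL_", moa_accs)),
    class_cols(moa_accs),
    tibble(therapeutic_rank = 1L)
  )

  ## ---- metadata -------------------------------------------------------
  gw_accs <- universe$accession[universe$n_sources > 0]
  gw_druggable <- intersect(gw_accs, druggable_accs)
  nondrug_gw <- setdiff(gw_accs, druggable_accs)

  # base TDLs for non-druggable genome-wide genes, with forced blocks
  tdl_counts <- cfg$tdl_gw
  if (is.null(tdl_counts)) {
    mix <- cfg$tdl_mixture[c("Tchem", "Tbio", "Tdark")]
    mix <- mix / sum(mix)
    n_nd <- length(nondrug_gw)
    tdl_counts <- floor(mix * n_nd)
    tdl_counts[["Tbio"]] <- tdl_counts[["Tbio"]] + (n_nd - sum(tdl_counts))
  }
  tdl_vec <- stats::setNames(rep(NA_character_, length(nondrug_gw)),
                             nondrug_gw)
  triple_accs <- intersect(universe$accession[universe$block == "T3"],
                           nondrug_gw)
  if (length(triple_accs) > 0) {
    tdl_vec[triple_accs] <- rep(cfg$triple_tdl,
                                length.out = length(triple_accs))
  }
  multi_source_accs <- universe$accession[universe$n_sources >= 2]
  need_ms_dark <- an$n_tdark_neuro_multisource -
    sum(tdl_vec[intersect(triple_accs, multi_source_accs)] == "Tdark",
        na.rm = TRUE)
  if (need_ms_dark > 0) {
    pool <- setdiff(intersect(multi_source_accs, nondrug_gw),
                    names(tdl_vec)[!is.na(tdl_vec)])
    forced <- take(pool, need_ms_dark, "multi-source dark-genome genes")
    tdl_vec[forced] <- "Tdark"
  }
  remaining_counts <- tdl_counts
  for (lv in names(remaining_counts)) {
    remaining_counts[[lv]] <- remaining_counts[[lv]] -
      sum(tdl_vec == lv, na.rm = TRUE)
  }
  if (any(remaining_counts < 0)) {
    infeasible("forced TDL assignments exceed the tdl_gw counts")
  }
  open <- names(tdl_vec)[is.na(tdl_vec)]
  tdl_vec[sample(open)] <- rep(names(remaining_counts),
                               times = unlist(remaining_counts))

  tdark_gw <- names(tdl_vec)[tdl_vec == "Tdark"]
  tchem_gw <- names(tdl_vec)[tdl_vec == "Tchem"]
  tbio_gw <- names(tdl_vec)[tdl_vec == "Tbio"]

  # planted annotation tiers over genome-wide genes
  ms_dark_pool <- intersect(tdark_gw, multi_source_accs)
  tdark_neuro <- c(
    take(ms_dark_pool, an$n_tdark_neuro_multisource,
         "multi-source dark neuro genes"),
    take(setdiff(tdark_gw, ms_dark_pool),
         an$n_tdark_neuro - an$n_tdark_neuro_multisource, "dark neuro genes")
  )
  tf_pool <- setdiff(gw_accs, c(tdark_gw, gw_druggable))
  tf_genes <- take(tf_pool, an$n_tf, "transcription factor genes")
  tf_neuro <- take(tf_genes, an$n_tf_neuro, "TF neurophenotype genes")
  extra_pool <- setdiff(gw_accs, c(tdark_gw, tf_genes, tdark_neuro, tf_neuro))
  neuro_extra <- take(extra_pool,
                      an$n_neuro - length(tdark_neuro) - length(tf_neuro),
                      "neurophenotype genes")
  neuro_set <- c(tdark_neuro, tf_neuro, neuro_extra)
  nodata_set <- take(setdiff(gw_accs, neuro_set), an$n_nodata,
                     "no-phenotype-data genes")

  chembl_order <- c(sample(gw_druggable), sample(tchem_gw), sample(tbio_gw),
                    sample(setdiff(gw_accs,
                                   c(gw_druggable, tchem_gw, tbio_gw))))
  if (an$n_chembl > length(gw_accs)) infeasible("n_chembl exceeds gene count")
  chembl_set <- head(chembl_order, an$n_chembl)

  synaptic_set <- take(gw_accs, an$n_synaptic, "synaptic-pathway genes")

  hda_low_pool <- c(sample(tdark_gw), sample(tbio_gw),
                    sample(setdiff(gw_accs, c(tdark_gw, tbio_gw))))
  hda_low <- head(hda_low_pool, an$n_low_hda)

  all_meta_accs <- unique(c(universe_all$accession, bg_accs, moa_accs))
  meta <- tibble(accession = all_meta_accs) |>
    mutate(
      is_gw = .data$accession %in% gw_accs,
      tdl = dplyr::case_when(
        .data$accession %in% druggable_accs ~ "Tclin",
        .data$accession %in% bg_accs ~ "Tclin",
        .data$accession %in% names(tdl_vec) ~
          unname(tdl_vec[.data$accession]),
        .data$accession %in% moa_accs ~ "Tbio",
        TRUE ~ NA_character_
      )
    )
  # non-genome-wide genes without a planted TDL draw from the mixture
  open_rows <- is.na(meta$tdl)
  if (any(open_rows)) {
    mix <- cfg$tdl_mixture[c("Tchem", "Tbio", "Tdark")]
    meta$tdl[open_rows] <- sample(names(mix), sum(open_rows), replace = TRUE,
                                  prob = mix / sum(mix))
  }

  thr <- an$hda_threshold
  n_meta <- nrow(meta)
  junk_terms <- function(n) {
    vapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) return("")
      paste(sample(c("MP:0000001", "MP:0001262", "MP:0002066"), k),
            collapse = ";")
    }, character(1))
  }
  in_neuro <- meta$accession %in% neuro_set
  in_nodata <- meta$accession %in% nodata_set
  # non-genome-wide accessions: phenotype data present but non-neuro, so the
  # genome-wide tier counts stay exactly as planted
  score2 <- in_neuro & (runif(n_meta) < 0.5)
  mp <- junk_terms(n_meta)
  mp[in_neuro & !score2] <- paste0(
    sample(MP_INDEX_TERMS, sum(in_neuro & !score2), replace = TRUE), ";",
    mp[in_neuro & !score2])
  mp[score2] <- paste0(paste(MP_INDEX_TERMS, collapse = ";"), ";", mp[score2])
  mp <- sub(";$", "", mp)
  mp[mp == ""] <- "MP:0000001"
  mp[in_nodata] <- NO_DATA_MARKER

  in_chembl <- meta$accession %in% chembl_set
  activity <- integer(n_meta)
  activity[in_chembl] <- 1L + rgeom(sum(in_chembl),
                                    1 / cfg$activity_geom_mean)
  # background approved targets also carry activity data
  in_bg <- meta$accession %in% bg_accs
  activity[in_bg] <- 1L + rgeom(sum(in_bg), 1 / cfg$activity_geom_mean)

  in_synaptic <- meta$accession %in% synaptic_set
  synaptic <- integer(n_meta)
  synaptic[in_synaptic] <- sample(1:6, sum(in_synaptic), replace = TRUE)

  in_low <- meta$accession %in% hda_low
  hda <- runif(n_meta, thr + 2, 100)
  hda[in_low] <- runif(sum(in_low), 0.5, thr - 0.5)

  is_tf <- meta$accession %in% tf_genes
  # transcription-factor flags off the genome-wide set don't affect planted
  # counts (the priority table covers genome-wide genes only)
  off_gw <- !meta$is_gw
  is_tf[off_gw] <- runif(sum(off_gw)) < 0.05

  meta_tbl <- tibble(
    accession = meta$accession,
    tdl = meta$tdl,
    chembl_activity_count = activity,
    selective_compound_count = ifelse(activity > 0,
                                      rbinom(n_meta, 5, 0.3), 0L),
    pathway_count_total = synaptic + rpois(n_meta, 3),
    synaptic_pathway_count = synaptic,
    disease_count = rpois(n_meta, 2),
    mp_terms = mp,
    grant_dollars = round(rlnorm(n_meta, 13, 1.5), 2),
    patent_count = rnbinom(n_meta, size = 1.2, mu = 8),
    hda_score = round(hda, 3),
    is_tf = is_tf,
    snapshot_id = cfg$snapshot_id
  ) |>
    arrange(.data$accession)

  ## ---- manifest (direct enumeration of the planted structure) ---------
  trial_accessions_all <- sort(unique(c(
    unlist(risk_target_tbl$members[match(risk_entries$target,
                                         risk_target_tbl$target)]),
    multi_entries$target, decoys$accession, single_nonrisk_entries$target,
    moa_accs
  )))
  curated_targets <- sort(unique(planted_entries$target))
  supported_targets <- sort(intersect(curated_targets,
                                      universe_all$accession))
  tclin_rp_genes <- sort(intersect(druggable_accs, trial_accessions_all))

  # evidence partition cells over the druggable genes
  cls <- universe |>
    filter(.data$accession %in% druggable_accs) |>
    mutate(n_classes = .data$cl_common + .data$cl_rare + .data$cl_expression)
  part <- c(
    unique_common = sum(cls$n_classes == 1 & cls$cl_common),
    unique_rare = sum(cls$n_classes == 1 & cls$cl_rare),
    unique_expression = sum(cls$n_classes == 1 & cls$cl_expression),
    multi_class = sum(cls$n_classes >= 2)
  )

  label_tally <- function(accs, weights = NULL) {
    lab <- lab_of(accs)
    tb <- if (is.null(weights)) table(lab) else table(rep(lab, weights))
    out <- as.integer(tb)
    names(out) <- names(tb)
    as.list(out)
  }
  dist_genetic <- label_tally(druggable_accs)
  dist_trial <- label_tally(planted_entries$target)

  curated_by_drug <- planted_entries |>
    group_by(.data$drug_name) |>
    summarise(targets = list(sort(.data$target)), .groups = "drop")
  curated_list <- stats::setNames(curated_by_drug$targets,
                                  curated_by_drug$drug_name)

  dpt <- planted_entries |>
    group_by(.data$target) |>
    summarise(n = dplyr::n_distinct(.data$drug_name), .groups = "drop") |>
    arrange(.data$target)

  gw_tdl_label <- function(acc) {
    if (acc %in% druggable_accs) {
      if (acc %in% trial_accessions_all) "Tclin_RP" else "Tclin"
    } else {
      unname(tdl_vec[acc])
    }
  }
  gw_labels <- vapply(gw_accs, gw_tdl_label, character(1))

  n_excluded <- length(excluded_drugs)
  manifest <- list(
    counts = list(
      n_associations_input = nrow(evidence),
      n_rejects = 0L,
      n_associations_mapped = nrow(evidence) + cfg$n_multi_accession,
      n_unique_genes = nrow(universe_all),
      n_gw_genes = length(gw_accs),
      n_gw_associations = nrow(rows$gwas) + nrow(rows$gwas2) +
        nrow(rows$twas) + nrow(rows$twas2) + nrow(rows$cnv) + nrow(rows$cnv2),
      gw_genes_GWAS = sum(universe$in_G),
      gw_genes_TWAS = sum(universe$in_T),
      gw_genes_CNV = sum(universe$in_C),
      gw_assoc_GWAS = nrow(rows$gwas) + nrow(rows$gwas2),
      gw_assoc_TWAS = nrow(rows$twas) + nrow(rows$twas2),
      gw_assoc_CNV = nrow(rows$cnv) + nrow(rows$cnv2),
      n_druggable_genes = n_druggable,
      n_druggable_drugs = n_drugs_risk_eff +
        if (n_druggable > 0) tr$n_drugs_on_risk else 0L,
      part_unique_common = unname(part[["unique_common"]]),
      part_unique_rare = unname(part[["unique_rare"]]),
      part_unique_expression = unname(part[["unique_expression"]]),
      part_multi_class = unname(part[["multi_class"]]),
      n_trial_drugs = tr$n_drugs,
      n_trial_excluded = n_excluded,
      n_curated_entries = nrow(planted_entries),
      n_trial_targets = length(curated_targets),
      n_supported_targets = length(supported_targets),
      n_tclin_rp = length(tclin_rp_genes),
      n_tclin = n_druggable - length(tclin_rp_genes),
      gw_druggable_GWAS = length(intersect(gw_druggable,
                                           universe$accession[universe$in_G])),
      gw_druggable_TWAS = length(intersect(gw_druggable,
                                           universe$accession[universe$in_T])),
      gw_druggable_CNV = length(intersect(gw_druggable,
                                          universe$accession[universe$in_C])),
      tdl_Tclin_RP = sum(gw_labels == "Tclin_RP"),
      tdl_Tclin = sum(gw_labels == "Tclin"),
      tdl_Tchem = sum(gw_labels == "Tchem"),
      tdl_Tbio = sum(gw_labels == "Tbio"),
      tdl_Tdark = sum(gw_labels == "Tdark"),
      tier_chembl = length(chembl_set),
      tier_neuro = length(neuro_set),
      tier_synaptic = length(synaptic_set),
      n_tdark_neuro = length(tdark_neuro),
      n_tdark_neuro_multisource = length(intersect(tdark_neuro,
                                                   multi_source_accs)),
      n_low_hda = length(hda_low),
      n_all_sources = sum(universe$n_sources == 3),
      n_overlap_GWAS_TWAS = sum(universe$in_G & universe$in_T),
      n_overlap_GWAS_CNV = sum(universe$in_G & universe$in_C),
      n_overlap_TWAS_CNV = sum(universe$in_T & universe$in_C),
      n_tf = length(tf_genes),
      n_tf_neuro = length(tf_neuro),
      mean_curated_per_drug = nrow(planted_entries) /
        (tr$n_drugs - n_excluded)
    ),
    sets = list(
      druggable = druggable_accs,
      tclin_rp = tclin_rp_genes,
      trial_targets = curated_targets,
      supported_targets = supported_targets,
      trial_accessions_all = trial_accessions_all,
      tdark_neuro = sort(tdark_neuro),
      low_hda = sort(hda_low),
      all_sources = sort(universe$accession[universe$n_sources == 3]),
      excluded_drugs = sort(excluded_drugs)
    ),
    dist_genetic = dist_genetic,
    dist_trial = dist_trial,
    drugs_per_target = stats::setNames(as.list(dpt$n), dpt$target),
    curated = curated_list,
    study_whitelist = synthetic_study_whitelist(),
    hda_threshold = thr,
    snapshot_id = cfg$snapshot_id,
    seed = cfg$seed
  )

  list(
    evidence = evidence |>
      mutate(p_value = format(.data$p_value, scientific = TRUE, digits = 6)),
    symbol_map = symbol_map,
    catalog = catalog,
    trial = trial_tbl,
    human_moa = human_moa,
    meta = meta_tbl,
    manifest = manifest
  )
}
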