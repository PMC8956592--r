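# End-to-end orchestration: ingest -> catalog -> overlap -> trial curation ->
# TDL annotation -> prioritization, with TSV/JSON outputs and a text report.

#' Build a run configuration
#'
#' Paths to the input tables plus the thresholds and study whitelist of a
#' pipeline run. Either explicit input paths or a synthetic bundle directory
#' is given, not both.
#'
#' @param evidence,symbol_map,drug_catalog,trial_drugs,human_moa,target_meta
#'   Paths to the input tables.
#' @param bundle_dir Directory produced by [generate_bundle()]; sets all six
#'   paths and (unless overridden) the study whitelist.
#' @param study_whitelist Studies reporting genome-wide significance.
#' @param hda_threshold HDA score below which a gene enters the low-HDA
#'   shortlist (default 10).
#' @param chembl_label_threshold ChEMBL activity count above which genes are
#'   labelled in exported figures-layer tables (default 10); the annotation
#'   tier count itself uses activity > 0.
#' @param out_dir Output directory; `NULL` to skip writing files.
#' @param verbose Verbosity 0-2 (log lines go to standard error).
#' @return A `run_config` list.
#' @export
run_config <- function(evidence = NULL, symbol_map = NULL, drug_catalog = NULL,
                       trial_drugs = NULL, human_moa = NULL, target_meta = NULL,
                       bundle_dir = NULL, study_whitelist = NULL,
                       hda_threshold = 10, chembl_label_threshold = 10,
                       out_dir = NULL, verbose = 1) {
  paths_given <- !vapply(list(evidence, symbol_map, drug_catalog, trial_drugs,
                              human_moa, target_meta), is.null, logical(1))
  if (!is.null(bundle_dir) && any(paths_given)) {
    stop("give either explicit input paths or bundle_dir, not both",
         call. = FALSE)
  }
  if (!is.null(bundle_dir)) {
    evidence <- file.path(bundle_dir, "evidence.tsv")
    symbol_map <- file.path(bundle_dir, "symbol_map.tsv")
    drug_catalog <- file.path(bundle_dir, "drug_catalog.tsv")
    trial_drugs <- file.path(bundle_dir, "trial_drugs.tsv")
    human_moa <- file.path(bundle_dir, "human_moa.tsv")
    target_meta <- file.path(bundle_dir, "target_meta.tsv")
    if (is.null(study_whitelist)) study_whitelist <- synthetic_study_whitelist()
  }
  if (is.null(study_whitelist)) {
    stop("study_whitelist is required", call. = FALSE)
  }
  structure(list(
    evidence = evidence, symbol_map = symbol_map, drug_catalog = drug_catalog,
    trial_drugs = trial_drugs, human_moa = human_moa,
    target_meta = target_meta, study_whitelist = study_whitelist,
    hda_threshold = hda_threshold,
    chembl_label_threshold = chembl_label_threshold,
    out_dir = out_dir, verbose = verbose
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

log_msg <- function(config, level, ...) {
  if ((config$verbose %||% 1) >= level) {
    message("[targetprio] ", ...)
  }
}

stage <- function(config, name, expr) {
  log_msg(config, 1, "stage: ", name)
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      log_msg(config, 1, "  note (", name, "): ", conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log_msg(config, 2, "  ", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
}

#' Run the full pipeline
#'
#' Executes ingest, accession mapping and merge, the genome-wide subset, the
#' drug-catalog cross-reference, trial-drug curation, TDL assignment and the
#' prioritization tables, in order. When `config$out_dir` is set, writes the
#' module TSV outputs, `summary.json` (every headline count plus a
#' provenance block with input checksums) and `report.txt`. Any stage failure
#' aborts with a stage-named error and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly when writing to disk.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  result <- tryCatch(
    run_all_impl(config),
    error = function(e) {
      if (!is.null(config$out_dir) && dir.exists(config$out_dir)) {
        unlink(file.path(config$out_dir,
                         c("summary.json", "report.txt", "run.log")))
      }
      stop(e)
    }
  )
  if (is.null(config$out_dir)) result else invisible(result)
}

run_all_impl <- function(config) {
  ## a) ingest and merge
  ing <- stage(config, "evidence_ingest", {
    parsed <- parse_evidence_table(config$evidence)
    mapped <- map_to_accessions(parsed$associations, config$symbol_map)
    entities <- merge_by_accession(mapped$mapped)
    gw <- genome_wide_subset(entities, config$study_whitelist)
    list(parsed = parsed, mapped = mapped, entities = entities, gw = gw)
  })
  sc <- ing$gw$source_counts
  mismatch <- sc$n_associations != sc$n_genes
  if (any(mismatch)) {
    log_msg(config, 1, "genome-wide association vs unique-gene counts differ",
            " for: ", paste(sc$source[mismatch], collapse = ", "),
            " (multiple studies or panels per gene)")
  }

  ## b) approved-drug catalog
  cat_data <- stage(config, "drug_catalog", {
    parsed <- parse_drug_catalog(config$drug_catalog)
    list(parsed = parsed, index = index_by_accession(parsed$targets))
  })
  risk_accessions <- ing$entities$accession

  ## c) druggable genes and evidence partition
  overlap <- stage(config, "repurposing_overlap", {
    dg <- druggable_genes(ing$entities, cat_data$index)
    part <- partition_by_evidence(dg$genes)
    classes <- gene_class_assignments(dg$genes$accession, cat_data$parsed$targets)
    list(dg = dg, part = part, classes = classes,
         dist_genetic = genetic_distribution(classes))
  })

  ## d) trial drug curation
  trial <- stage(config, "trial_curation", {
    tl <- load_trial_list(config$trial_drugs)
    tl <- attach_trial_targets(tl, cat_data$parsed$targets)
    tl <- remap_microbial(tl, config$human_moa)
    cur <- curate_trial_drugs(tl, risk_accessions)
    raw_human <- purrr::map2_dfr(tl$drug_name, tl$targets, function(d, tg) {
      tg |>
        filter(.data$organism == "human", !is.na(.data$accession)) |>
        transmute(drug_name = d, accession = .data$accession)
    }) |>
      semi_join(tl |> filter(!.data$excluded), by = "drug_name")
    list(trial = cur$trial, curated = cur$curated,
         accessions_all = sort_unique(raw_human$accession),
         dist_trial = trial_distribution(cur$curated),
         per_target = drugs_per_target(cur$curated))
  })

  ## e) cross-referencing the two target spaces
  cross <- stage(config, "crossref", {
    status <- repurposing_status(overlap$dg$genes$accession,
                                 trial$accessions_all)
    trial_targets <- sort_unique(trial$curated$accession)
    supported <- genetically_supported_trial_targets(trial_targets,
                                                     risk_accessions)
    comparison <- compare_distributions(overlap$dist_genetic,
                                        trial$dist_trial)
    list(status = status, trial_targets = trial_targets,
         supported = supported, comparison = comparison)
  })

  ## f, g) TDL annotation over the genome-wide subset
  tdl <- stage(config, "tdl_annotation", {
    meta <- load_target_meta(config$target_meta)
    labels <- assign_tdl(meta, names(cat_data$index), trial$accessions_all)
    gw_labels <- labels |>
      filter(.data$accession %in% ing$gw$entities$accession)
    list(meta = meta, labels = labels, gw_labels = gw_labels,
         dist = tdl_distribution(gw_labels))
  })

  ## h) prioritization table, tiers and shortlists
  prio <- stage(config, "prioritization", {
    table <- build_priority_table(ing$gw, cat_data$index, tdl$meta,
                                  tdl$labels)
    list(
      table = table,
      tiers = annotation_tier_counts(table),
      tdark_neuro = shortlist_tdark_neuro(table),
      low_hda = shortlist_low_hda(table, config$hda_threshold),
      multi_source = multi_source_intersection(table),
      tf = transcription_factor_summary(table)
    )
  })

  summary <- build_summary(config, ing, cat_data, overlap, trial, cross,
                           tdl, prio)
  if (!is.null(config$out_dir)) {
    write_outputs(config, ing, overlap, trial, cross, tdl, prio, summary)
  }
  summary
}

count_or_zero <- function(df, src, col) {
  i <- match(src, df$source)
  if (is.na(i)) 0L else df[[col]][i]
}

pair_n <- function(ms, a, b) {
  hit <- ms$pairwise |>
    filter((.data$source_a == a & .data$source_b == b) |
             (.data$source_a == b & .data$source_b == a))
  if (nrow(hit) == 0) 0L else hit$n[1]
}

build_summary <- function(config, ing, cat_data, overlap, trial, cross, tdl,
                          prio) {
  sc <- ing$gw$source_counts
  part <- overlap$part$table
  part_n <- stats::setNames(part$n, part$cell)
  status_tab <- table(cross$status$status)
  tdl_tab <- tdl$dist$summary
  tdl_n <- stats::setNames(tdl_tab$n, as.character(tdl_tab$tdl))
  gw_druggable <- prio$table |>
    filter(.data$accession %in% overlap$dg$genes$accession)
  gw_drug_src <- gw_druggable |>
    group_by(.data$source) |>
    summarise(n = dplyr::n_distinct(.data$accession), .groups = "drop")
  dist_to_list <- function(d) {
    stats::setNames(as.list(as.integer(d$n)), d$class)
  }
  n_excluded <- sum(trial$trial$excluded)
  n_trial_drugs <- nrow(trial$trial)
  curated_list <- trial$curated |>
    group_by(.data$drug_name) |>
    summarise(targets = list(sort(.data$accession)), .groups = "drop")

  list(
    counts = list(
      n_associations_input = nrow(ing$parsed$associations),
      n_rejects = nrow(ing$parsed$rejects),
      n_associations_mapped = nrow(ing$mapped$mapped),
      n_unique_genes = nrow(ing$entities),
      n_gw_genes = nrow(ing$gw$entities),
      n_gw_associations = nrow(ing$gw$gw_associations),
      gw_genes_GWAS = count_or_zero(sc, "GWAS", "n_genes"),
      gw_genes_TWAS = count_or_zero(sc, "TWAS", "n_genes"),
      gw_genes_CNV = count_or_zero(sc, "CNV", "n_genes"),
      gw_assoc_GWAS = count_or_zero(sc, "GWAS", "n_associations"),
      gw_assoc_TWAS = count_or_zero(sc, "TWAS", "n_associations"),
      gw_assoc_CNV = count_or_zero(sc, "CNV", "n_associations"),
      n_druggable_genes = nrow(overlap$dg$genes),
      n_druggable_drugs = length(overlap$dg$drugs),
      part_unique_common = unname(part_n[["unique_common"]]),
      part_unique_rare = unname(part_n[["unique_rare"]]),
      part_unique_expression = unname(part_n[["unique_expression"]]),
      part_multi_class = unname(part_n[["multi_class"]]),
      n_trial_drugs = n_trial_drugs,
      n_trial_excluded = n_excluded,
      n_curated_entries = nrow(trial$curated),
      n_trial_targets = length(cross$trial_targets),
      n_supported_targets = length(cross$supported),
      n_tclin_rp = unname(status_tab["T_clinical_repurposing"] %|na|% 0L),
      n_tclin = unname(status_tab["T_clinical"] %|na|% 0L),
      gw_druggable_GWAS = count_or_zero(gw_drug_src, "GWAS", "n"),
      gw_druggable_TWAS = count_or_zero(gw_drug_src, "TWAS", "n"),
      gw_druggable_CNV = count_or_zero(gw_drug_src, "CNV", "n"),
      tdl_Tclin_RP = unname(tdl_n[["Tclin_RP"]]),
      tdl_Tclin = unname(tdl_n[["Tclin"]]),
      tdl_Tchem = unname(tdl_n[["Tchem"]]),
      tdl_Tbio = unname(tdl_n[["Tbio"]]),
      tdl_Tdark = unname(tdl_n[["Tdark"]]),
      tier_chembl = prio$tiers$n_chembl,
      tier_neuro = prio$tiers$n_neuro,
      tier_synaptic = prio$tiers$n_synaptic,
      n_tdark_neuro = nrow(prio$tdark_neuro),
      n_tdark_neuro_multisource = sum(prio$tdark_neuro$multi_source),
      n_low_hda = nrow(prio$low_hda),
      n_all_sources = length(prio$multi_source$all_sources),
      n_overlap_GWAS_TWAS = pair_n(prio$multi_source, "GWAS", "TWAS"),
      n_overlap_GWAS_CNV = pair_n(prio$multi_source, "GWAS", "CNV"),
      n_overlap_TWAS_CNV = pair_n(prio$multi_source, "TWAS", "CNV"),
      n_tf = prio$tf$n_tf,
      n_tf_neuro = prio$tf$n_tf_neuro,
      mean_curated_per_drug = if (n_trial_drugs - n_excluded > 0) {
        nrow(trial$curated) / (n_trial_drugs - n_excluded)
      } else NA_real_
    ),
    sets = list(
      druggable = sort(overlap$dg$genes$accession),
      tclin_rp = sort(cross$status$accession[
        cross$status$status == "T_clinical_repurposing"]),
      trial_targets = cross$trial_targets,
      supported_targets = cross$supported,
      trial_accessions_all = trial$accessions_all,
      tdark_neuro = sort(prio$tdark_neuro$accession),
      low_hda = sort(prio$low_hda$accession),
      all_sources = prio$multi_source$all_sources,
      excluded_drugs = sort(trial$trial$drug_name[trial$trial$excluded])
    ),
    dist_genetic = dist_to_list(overlap$dist_genetic),
    dist_trial = dist_to_list(trial$dist_trial),
    drugs_per_target = stats::setNames(as.list(trial$per_target$n_drugs),
                                       trial$per_target$accession),
    curated = stats::setNames(curated_list$targets, curated_list$drug_name),
    supported_share = list(
      of_trial_drugs = if (n_trial_drugs > 0) {
        length(cross$supported) / n_trial_drugs
      } else NA_real_,
      of_trial_targets = if (length(cross$trial_targets) > 0) {
        length(cross$supported) / length(cross$trial_targets)
      } else NA_real_
    ),
    tdl_background = as.list(stats::setNames(tdl$dist$background$n,
                                             tdl$dist$background$set)),
    provenance = list(
      inputs = as.list(vapply(
        config[c("evidence", "symbol_map", "drug_catalog", "trial_drugs",
                 "human_moa", "target_meta")],
        function(p) unname(tools::md5sum(p)), character(1))),
      study_whitelist = config$study_whitelist,
      hda_threshold = config$hda_threshold,
      chembl_label_threshold = config$chembl_label_threshold,
      package_version = as.character(utils::packageVersion("targetprio"))
    )
  )
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

write_outputs <- function(config, ing, overlap, trial, cross, tdl, prio,
                          summary) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv_out(flatten_list_cols(
    ing$entities |> select(-"associations")), file.path(out, "entities.tsv"))
  write_tsv_out(ing$mapped$unmapped, file.path(out, "unmapped.tsv"))
  write_tsv_out(ing$parsed$rejects, file.path(out, "evidence_rejects.tsv"))
  dg_out <- overlap$dg$genes |>
    select("accession", "symbols", "evidence_classes", "n_drugs", "drugs") |>
    left_join(cross$status, by = "accession")
  write_tsv_out(flatten_list_cols(dg_out), file.path(out, "druggable_genes.tsv"))
  write_tsv_out(trial$per_target, file.path(out, "trial_targets.tsv"))
  write_tsv_out(trial$curated, file.path(out, "curated_trial.tsv"))
  write_tsv_out(trial$trial |>
                  select("drug_name", "trial_weight", "excluded",
                         "exclusion_reason"),
                file.path(out, "trial_exclusions.tsv"))
  dist_out <- bind_rows(
    overlap$dist_genetic |> mutate(side = "genetic", .before = 1),
    trial$dist_trial |> mutate(side = "trial", .before = 1)
  )
  write_tsv_out(dist_out, file.path(out, "class_distribution.tsv"))
  write_tsv_out(cross$comparison, file.path(out, "comparison.tsv"))
  write_tsv_out(prio$table |> select(-"mp_terms"),
                file.path(out, "priority_table.tsv"))
  write_tsv_out(flatten_list_cols(prio$tdark_neuro),
                file.path(out, "shortlist_tdark_neuro.tsv"))
  write_tsv_out(prio$low_hda, file.path(out, "shortlist_low_hda.tsv"))
  jsonlite::write_json(
    list(summary = tdl$dist$summary, background = tdl$dist$background),
    file.path(out, "tdl_summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(write_report(summary), file.path(out, "report.txt"))
  invisible(out)
}

#' Format a human-readable summary report
#'
#' Renders the headline counts, both "genetically supported" denominators,
#' the class-distribution layers and the TDL summary as plain text tables.
#'
#' @param summary Summary list from [run_all()].
#' @return Character vector of report lines.
#' @export
write_report <- function(summary) {
  if (is.null(summary$counts)) {
    return(c("druggable-genome cross-referencing report", "(empty summary)"))
  }
  co <- summary$counts
  fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.0f%%", 100 * x))
  dist_lines <- function(d, title) {
    total <- sum(unlist(d))
    c(title, vapply(names(d), function(cl) {
      sprintf("  %-28s %4d  (%s)", cl, d[[cl]],
              fmt_pct(if (total > 0) d[[cl]] / total else NA))
    }, character(1)))
  }
  c(
    "druggable-genome cross-referencing report",
    "=========================================",
    sprintf("risk-gene associations parsed: %d (+%d rejects)",
            co$n_associations_input, co$n_rejects),
    sprintf("unique risk genes: %d", co$n_unique_genes),
    sprintf("genome-wide significant: %d genes / %d associations",
            co$n_gw_genes, co$n_gw_associations),
    sprintf("  GWAS %d genes (%d associations) | TWAS %d (%d) | CNV %d (%d)",
            co$gw_genes_GWAS, co$gw_assoc_GWAS, co$gw_genes_TWAS,
            co$gw_assoc_TWAS, co$gw_genes_CNV, co$gw_assoc_CNV),
    if (co$gw_assoc_GWAS != co$gw_genes_GWAS ||
        co$gw_assoc_TWAS != co$gw_genes_TWAS ||
        co$gw_assoc_CNV != co$gw_genes_CNV) {
      "  note: association and unique-gene counts differ (multi-study/panel)"
    },
    "",
    sprintf("druggable genes: %d (targeted by %d approved drugs)",
            co$n_druggable_genes, co$n_druggable_drugs),
    sprintf("  evidence partition: %d common-only / %d rare-only / %d expression-only / %d multi-class",
            co$part_unique_common, co$part_unique_rare,
            co$part_unique_expression, co$part_multi_class),
    sprintf("  repurposing status: %d T_clinical_repurposing / %d T_clinical (novel)",
            co$n_tclin_rp, co$n_tclin),
    "",
    sprintf("trial drugs: %d (%d excluded, no human target)",
            co$n_trial_drugs, co$n_trial_excluded),
    sprintf("  curated targets: %d unique over %d entries (%.2f per drug)",
            co$n_trial_targets, co$n_curated_entries,
            co$mean_curated_per_drug %|na|% NA_real_),
    sprintf("  genetically supported targets: %d", co$n_supported_targets),
    sprintf("    = %s of %d trial drugs | %s of %d trial targets",
            fmt_pct(summary$supported_share$of_trial_drugs), co$n_trial_drugs,
            fmt_pct(summary$supported_share$of_trial_targets),
            co$n_trial_targets),
    "",
    dist_lines(summary$dist_genetic,
               "protein class distribution, genetic targets (by target):"),
    dist_lines(summary$dist_trial,
               "protein class distribution, trial targets (by drug):"),
    "",
    "genome-wide TDL distribution:",
    sprintf("  Tclin_RP %d | Tclin %d | Tchem %d | Tbio %d | Tdark %d",
            co$tdl_Tclin_RP, co$tdl_Tclin, co$tdl_Tchem, co$tdl_Tbio,
            co$tdl_Tdark),
    sprintf("  background: druggable genome %d, total genome %d",
            summary$tdl_background$druggable_genome %||% NA,
            summary$tdl_background$total_genome %||% NA),
    "",
    sprintf("annotation tiers (unique genes): ChEMBL %d | neurophenotype %d | synaptic %d",
            co$tier_chembl, co$tier_neuro, co$tier_synaptic),
    sprintf("dark-genome neurophenotype shortlist: %d genes (%d multi-source)",
            co$n_tdark_neuro, co$n_tdark_neuro_multisource),
    sprintf("low-HDA shortlist: %d genes", co$n_low_hda),
    sprintf("source intersections: all three %d | GWAS-TWAS %d | GWAS-CNV %d | TWAS-CNV %d",
            co$n_all_sources, co$n_overlap_GWAS_TWAS, co$n_overlap_GWAS_CNV,
            co$n_overlap_TWAS_CNV),
    sprintf("transcription factors: %d (%d with neurophenotypes)",
            co$n_tf, co$n_tf_neuro)
  )
}
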