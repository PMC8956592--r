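# Cross-referencing of risk-gene entities with the approved-drug catalog and
# the curated trial list: druggable gene set, evidence partition, repurposing
# status, and genetic vs clinical-trial protein class distributions.

#' Druggable genes and the approved drugs targeting them
#'
#' @param entities Entity tibble from [merge_by_accession()].
#' @param catalog_index Accession-to-drugs index from [index_by_accession()].
#' @return List with `genes` (entity subset plus `n_drugs` and `drugs`
#'   list-column) and `drugs` (sorted unique drug names over the gene set).
#' @export
druggable_genes <- function(entities, catalog_index) {
  hit <- entities |> filter(.data$accession %in% names(catalog_index))
  hit$drugs <- lapply(hit$accession, function(a) catalog_index[[a]])
  hit$n_drugs <- vapply(hit$drugs, length, integer(1))
  list(genes = hit, drugs = sort_unique(unlist(hit$drugs)))
}

#' Partition druggable genes by evidence class
#'
#' A gene is unique to a class iff its evidence classes equal exactly that
#' class; genes supported by two or more classes form the multi-class cell.
#' The four cells are pairwise disjoint and cover the input.
#'
#' @param druggable Entity tibble (the druggable subset).
#' @return List with `sets` (named list of accession vectors:
#'   `unique_common`, `unique_rare`, `unique_expression`, `multi_class`) and
#'   `table` (cell sizes).
#' @export
partition_by_evidence <- function(druggable) {
  cell <- vapply(druggable$evidence_classes, function(cl) {
    if (length(cl) == 1) paste0("unique_", cl) else "multi_class"
  }, character(1))
  cells <- c("unique_common", "unique_rare", "unique_expression", "multi_class")
  sets <- lapply(cells, function(cl) sort(druggable$accession[cell == cl]))
  names(sets) <- cells
  list(
    sets = sets,
    table = tibble(cell = cells,
                   n = vapply(sets, length, integer(1)))
  )
}

#' Repurposing status of druggable genes
#'
#' A druggable gene already matched by the target of a drug in a clinical
#' repurposing trial is `T_clinical_repurposing`; the remainder are
#' `T_clinical` (novel repurposing opportunities). Matching is on any of the
#' trial drugs' human target accessions (before subunit consolidation, so
#' every subunit of a targeted complex matches).
#'
#' @param druggable_accessions Accessions of the druggable gene set.
#' @param trial_accessions Human target accessions of non-excluded trial
#'   drugs.
#' @return Tibble with `accession` and `status`.
#' @export
repurposing_status <- function(druggable_accessions, trial_accessions) {
  tibble(
    accession = sort(druggable_accessions),
    status = ifelse(sort(druggable_accessions) %in% trial_accessions,
                    "T_clinical_repurposing", "T_clinical")
  )
}

#' Trial targets supported by genetic evidence
#'
#' @param trial_targets Curated trial-target accessions (consolidated).
#' @param risk_accessions All risk-gene accessions.
#' @return Sorted accessions of trial targets that are risk genes.
#' @export
genetically_supported_trial_targets <- function(trial_targets, risk_accessions) {
  sort(intersect(trial_targets, risk_accessions))
}

#' Class label with the 7TM receptors broken out
#'
#' Level-1 class labels, except that membrane receptors whose level-2 class
#' is the seven-pass-transmembrane (7TM/GPCR) family are reported as "7TM".
#' @param class_l1,class_l2 Character vectors of class levels.
#' @return Character vector of class labels.
#' @export
class_label <- function(class_l1, class_l2) {
  as.character(ifelse(class_l1 == "membrane receptor" & !is.na(class_l2) &
                        grepl("7TM", class_l2, fixed = TRUE),
                      "7TM", class_l1))
}

new_class_distribution <- function(counts, weighting) {
  stopifnot(weighting %in% c("by_target", "by_drug"))
  total <- sum(counts$n)
  counts$proportion <- if (total > 0) counts$n / total else numeric(nrow(counts))
  counts$pct <- round(100 * counts$proportion)
  out <- counts |> arrange(dplyr::desc(.data$n), .data$class)
  attr(out, "weighting") <- weighting
  out
}

#' Resolve one protein class path per gene from the catalog
#'
#' A gene annotated with conflicting class paths across drugs is resolved to
#' the most frequent path (ties broken lexicographically) and logged.
#'
#' @param accessions Gene accessions to annotate.
#' @param targets Drug-target tibble from [parse_drug_catalog()].
#' @return Tibble `accession`, `class_l1`, `class_l2`, `class_l3`,
#'   `class_conflict`.
#' @export
gene_class_assignments <- function(accessions, targets) {
  rows <- targets |>
    filter(.data$organism == "human", .data$accession %in% accessions)
  res <- rows |>
    count(.data$accession, .data$class_l1, .data$class_l2, .data$class_l3) |>
    group_by(.data$accession) |>
    mutate(class_conflict = dplyr::n() > 1) |>
    arrange(dplyr::desc(.data$n), .data$class_l1, .data$class_l2,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"n")
  conflicted <- res$accession[res$class_conflict]
  if (length(conflicted) > 0) {
    message("class path conflicts resolved by most frequent path for: ",
            paste(conflicted, collapse = ", "))
  }
  res
}

#' Protein class distribution of the genetic (druggable) targets
#'
#' Each druggable gene counts once (by-target weighting), using its resolved
#' catalog class path.
#'
#' @param gene_classes Tibble from [gene_class_assignments()] over the
#'   druggable genes.
#' @return A class distribution tibble (`class`, `n`, `proportion`, `pct`)
#'   with a `weighting` attribute of "by_target".
#' @export
genetic_distribution <- function(gene_classes) {
  counts <- gene_classes |>
    mutate(class = class_label(.data$class_l1, .data$class_l2)) |>
    count(.data$class)
  new_class_distribution(counts, "by_target")
}

#' Protein class distribution of clinical-trial targets
#'
#' By-drug weighting over the curated entries of non-excluded trial drugs:
#' each retained (drug, target) pair contributes one count, so a target's
#' share is proportional to the number of drugs associated with it.
#'
#' @param curated Flat curated tibble from [curate_trial_drugs()].
#' @return A class distribution tibble with a `weighting` attribute of
#'   "by_drug".
#' @export
trial_distribution <- function(curated) {
  if (nrow(curated) == 0) {
    return(new_class_distribution(tibble(class = character(0), n = integer(0)),
                                  "by_drug"))
  }
  counts <- curated |>
    mutate(class = class_label(.data$class_l1, .data$class_l2)) |>
    count(.data$class)
  new_class_distribution(counts, "by_drug")
}

#' Compare two protein class distributions
#'
#' Missing classes are imputed as zero; classes are ordered by decreasing
#' absolute difference in proportion. Comparing distributions with different
#' weightings (the standard genetic by-target vs trial by-drug comparison)
#' raises a warning noting the weighting mismatch.
#'
#' @param a,b Class distributions.
#' @return Tibble with `class`, `proportion_a`, `proportion_b`, `difference`.
#' @export
compare_distributions <- function(a, b) {
  wa <- attr(a, "weighting") %||% "unknown"
  wb <- attr(b, "weighting") %||% "unknown"
  if (!identical(wa, wb)) {
    warning("comparing distributions with different weightings: ",
            wa, " vs ", wb, call. = FALSE)
  }
  full_join(
    a |> select("class", proportion_a = "proportion"),
    b |> select("class", proportion_b = "proportion"),
    by = "class"
  ) |>
    mutate(proportion_a = dplyr::coalesce(.data$proportion_a, 0),
           proportion_b = dplyr::coalesce(.data$proportion_b, 0),
           difference = .data$proportion_a - .data$proportion_b) |>
    arrange(dplyr::desc(abs(.data$difference)), .data$class)
}
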