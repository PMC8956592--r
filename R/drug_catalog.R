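# Approved-drug target-efficacy catalog and curation of the clinical
# repurposing trial drug list: microbial remapping, exclusion, subunit
# consolidation, <=2-entry selection, drug-per-target weighting.

CATALOG_COLUMNS <- c("drug_name", "molecule_type", "moa", "accession",
                     "chembl_target_id", "class_l1", "class_l2", "class_l3",
                     "organism", "complex_id", "atc", "approval_year",
                     "therapeutic_rank")

#' Level-1 protein target class vocabulary
#'
#' The controlled vocabulary of top-level ChEMBL-style protein target
#' classes used throughout the class distributions.
#' @return Character vector of level-1 class labels.
#' @export
protein_class_vocabulary <- function() {
  c("ion channel", "membrane receptor", "secreted", "structural",
    "surface antigen", "transcription factor", "transporter",
    "auxiliary transport protein", "enzyme", "enzyme modulator",
    "epigenetic regulator")
}

#' Parse the approved-drug target-efficacy catalog
#'
#' One input row is one (drug, target annotation) pair. Human annotations
#' must carry a protein accession; rows failing validation are reported in
#' `rejects`. The same drug appearing with conflicting molecule types is a
#' hard error.
#'
#' @param source Path to a TSV/CSV file, or a data frame, with columns
#'   `drug_name`, `molecule_type`, `moa`, `accession`, `chembl_target_id`,
#'   `class_l1`, `class_l2`, `class_l3`, `organism`, `complex_id`, `atc`,
#'   `approval_year`, `therapeutic_rank`.
#' @return List with `targets` (tibble of valid drug-target rows), `drugs`
#'   (one row per drug) and `rejects`.
#' @export
parse_drug_catalog <- function(source) {
  df <- read_table_auto(source)
  if (nrow(df) == 0 && length(names(df)) == 0) {
    df <- tibble::as_tibble(setNames(
      replicate(length(CATALOG_COLUMNS), character(0), simplify = FALSE),
      CATALOG_COLUMNS))
  }
  require_columns(df, c("drug_name", "accession", "class_l1", "organism"),
                  "drug catalog")
  for (col in setdiff(CATALOG_COLUMNS, names(df))) df[[col]] <- NA_character_

  n <- nrow(df)
  reason <- rep(NA_character_, n)
  organism <- tolower(trimws(df$organism))
  reason[is.na(reason) & is_blank(df$drug_name)] <- "missing drug_name"
  reason[is.na(reason) & !(organism %in% c("human", "microbial", "other"))] <-
    "invalid organism"
  reason[is.na(reason) & organism == "human" & is_blank(df$accession)] <-
    "human annotation without accession"
  reason[is.na(reason) & is_blank(df$class_l1)] <- "missing protein class"

  keep <- is.na(reason)
  rejects <- tibble(row = which(!keep),
                    drug_name = df$drug_name[!keep],
                    reason = reason[!keep])

  targets <- tibble(
    drug_name = trimws(df$drug_name[keep]),
    molecule_type = trimws(df$molecule_type[keep]),
    moa = df$moa[keep],
    accession = ifelse(is_blank(df$accession[keep]), NA_character_,
                       trimws(df$accession[keep])),
    chembl_target_id = trimws(df$chembl_target_id[keep]),
    class_l1 = trimws(df$class_l1[keep]),
    class_l2 = ifelse(is_blank(df$class_l2[keep]), NA_character_,
                      trimws(df$class_l2[keep])),
    class_l3 = ifelse(is_blank(df$class_l3[keep]), NA_character_,
                      trimws(df$class_l3[keep])),
    organism = organism[keep],
    complex_id = ifelse(is_blank(df$complex_id[keep]), NA_character_,
                        trimws(df$complex_id[keep])),
    atc = df$atc[keep],
    approval_year = parse_int(df$approval_year[keep]),
    therapeutic_rank = parse_int(df$therapeutic_rank[keep])
  )

  conflicts <- targets |>
    mutate(key = norm_drug_name(.data$drug_name)) |>
    filter(!is_blank(.data$molecule_type)) |>
    distinct(.data$key, .data$molecule_type) |>
    count(.data$key) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    stop("duplicate drug with conflicting molecule_type: ",
         paste(conflicts$key, collapse = ", "), call. = FALSE)
  }

  drugs <- targets |>
    group_by(.data$drug_name) |>
    summarise(molecule_type = dplyr::first(.data$molecule_type),
              moa = dplyr::first(.data$moa),
              atc = dplyr::first(.data$atc),
              approval_year = dplyr::first(.data$approval_year),
              n_targets = dplyr::n(), .groups = "drop")

  list(targets = targets, drugs = drugs, rejects = rejects)
}

#' Index approved drugs by human target accession
#'
#' @param targets Drug-target tibble from [parse_drug_catalog()].
#' @return Named list mapping accession to the sorted unique drug names with
#'   that human target. Non-human annotations contribute no keys.
#' @export
index_by_accession <- function(targets) {
  human <- targets |> filter(.data$organism == "human", !is.na(.data$accession))
  if (nrow(human) == 0) return(structure(list(), names = character(0)))
  lapply(split(human$drug_name, human$accession), sort_unique)
}

#' Load the clinical repurposing trial drug list
#'
#' @param source Path or data frame with columns `drug_name`,
#'   `n_trial_listings`.
#' @return Tibble with `drug_name` and integer `trial_weight`.
#' @export
load_trial_list <- function(source) {
  df <- read_table_auto(source)
  require_columns(df, c("drug_name", "n_trial_listings"), "trial drug list")
  tibble(drug_name = trimws(df$drug_name),
         trial_weight = parse_int(df$n_trial_listings))
}

#' Attach catalog target annotations to trial drugs
#'
#' Trial drugs are approved drugs, so their raw target annotations are looked
#' up in the catalog by drug name (case-insensitive, punctuation stripped).
#'
#' @param trial Tibble from [load_trial_list()].
#' @param targets Drug-target tibble from [parse_drug_catalog()].
#' @return Trial tibble with a nested `targets` list-column.
#' @export
attach_trial_targets <- function(trial, targets) {
  tg <- targets |> mutate(.key = norm_drug_name(.data$drug_name))
  trial |>
    mutate(.key = norm_drug_name(.data$drug_name)) |>
    mutate(targets = lapply(.data$.key, function(k) {
      tg |> filter(.data$.key == k) |> select(-".key", -"drug_name")
    })) |>
    select(-".key")
}

#' Remap trial drugs with only microbial targets to human annotations
#'
#' Drugs whose raw annotations contain no human target are cross-referenced
#' against a mechanism-of-action table of human targets (DrugBank-style);
#' matching human annotations are appended. Drugs with no human annotation
#' anywhere are marked excluded with reason "no human target". Idempotent.
#'
#' @param trial Trial tibble with nested `targets` (see
#'   [attach_trial_targets()]).
#' @param human_moa Path or data frame with columns `drug_name`, `accession`,
#'   `chembl_target_id`, `class_l1`, `class_l2`, `class_l3`,
#'   `therapeutic_rank`.
#' @return Updated trial tibble with `excluded` and `exclusion_reason`
#'   columns.
#' @export
remap_microbial <- function(trial, human_moa) {
  moa <- read_table_auto(human_moa)
  require_columns(moa, c("drug_name", "accession"), "human MOA table")
  for (col in c("chembl_target_id", "class_l1", "class_l2", "class_l3",
                "therapeutic_rank")) {
    if (!col %in% names(moa)) moa[[col]] <- NA_character_
  }
  moa <- moa |> mutate(.key = norm_drug_name(.data$drug_name))

  out <- trial
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  if (!"exclusion_reason" %in% names(out)) out$exclusion_reason <- NA_character_

  for (i in seq_len(nrow(out))) {
    tg <- out$targets[[i]]
    has_human <- nrow(tg) > 0 && any(tg$organism == "human" & !is.na(tg$accession))
    if (has_human) next
    key <- norm_drug_name(out$drug_name[i])
    hits <- moa |> filter(.data$.key == key)
    if (nrow(hits) > 0) {
      add <- tibble(
        molecule_type = NA_character_, moa = NA_character_,
        accession = trimws(hits$accession),
        chembl_target_id = hits$chembl_target_id,
        class_l1 = hits$class_l1, class_l2 = hits$class_l2,
        class_l3 = hits$class_l3,
        organism = "human", complex_id = NA_character_,
        atc = NA_character_, approval_year = NA_integer_,
        therapeutic_rank = parse_int(hits$therapeutic_rank)
      )
      common <- intersect(names(tg), names(add))
      out$targets[[i]] <- bind_rows(tg[, common, drop = FALSE],
                                    add[, common, drop = FALSE])
      out$excluded[i] <- FALSE
      out$exclusion_reason[i] <- NA_character_
    } else {
      out$excluded[i] <- TRUE
      out$exclusion_reason[i] <- "no human target"
    }
  }
  out
}

#' Consolidate subunit annotations of one target complex
#'
#' Annotations sharing a complex identifier and protein class collapse to a
#' single representative (the lexicographically smallest accession). When
#' `complex_id` is absent, annotations sharing a ChEMBL target id are treated
#' as one complex. Output order follows first appearance in the input.
#'
#' @param targets Tibble of human target annotations for one drug.
#' @return Consolidated tibble with `n_subunits` and `subunit_accessions`.
#' @export
consolidate_subunits <- function(targets) {
  if (nrow(targets) == 0) {
    return(targets |> mutate(n_subunits = integer(0),
                             subunit_accessions = list()))
  }
  key <- paste(
    dplyr::coalesce(targets$complex_id, targets$chembl_target_id,
                    targets$accession),
    targets$class_l1, targets$class_l2 %||% "", sep = "\r"
  )
  targets |>
    mutate(.grp = match(key, unique(key)), .ord = dplyr::row_number()) |>
    group_by(.data$.grp) |>
    arrange(.data$accession, .by_group = TRUE) |>
    summarise(dplyr::across(!dplyr::all_of(c("accession", ".ord")), dplyr::first),
              n_subunits = dplyr::n(),
              subunit_accessions = list(sort_unique(.data$accession)),
              accession = min(.data$accession),
              .first_ord = min(.data$.ord),
              .groups = "drop") |>
    arrange(.data$.first_ord) |>
    select(-".grp", -".first_ord") |>
    relocate("accession")
}

#' Select up to two protein-class entries for a multi-target drug
#'
#' Entries are ranked by (1) membership of the accession in the risk-gene
#' set, (2) the primary-therapeutic-relevance rank supplied in the input
#' metadata (1 = primary), and, for the second entry, (3) mechanistic
#' diversity (a second entry from a different level-1 class is preferred
#' when available). Ties break lexicographically by accession then ChEMBL
#' target id, so the selection is deterministic and invariant to the input
#' target order.
#'
#' @param targets Consolidated human target annotations for one drug (see
#'   [consolidate_subunits()]).
#' @param risk_accessions Character vector of risk-gene accessions.
#' @param excluded Is the drug excluded? Excluded drugs return an empty
#'   selection unchanged.
#' @return Tibble of at most two entries with a `selection_reason` column.
#' @export
curate_multi_target <- function(targets, risk_accessions, excluded = FALSE) {
  empty <- targets[0, , drop = FALSE] |> mutate(selection_reason = character(0))
  if (excluded || nrow(targets) == 0) return(empty)
  ranked <- targets |>
    mutate(.is_risk = .data$accession %in% risk_accessions,
           .rank = ifelse(is.na(.data$therapeutic_rank), Inf,
                          .data$therapeutic_rank)) |>
    arrange(dplyr::desc(.data$.is_risk), .data$.rank, .data$accession,
            .data$chembl_target_id)
  first <- ranked[1, , drop = FALSE]
  first$selection_reason <- if (nrow(ranked) == 1) {
    "sole target"
  } else if (first$.is_risk) {
    "risk gene match"
  } else {
    "primary therapeutic relevance"
  }
  if (nrow(ranked) == 1) {
    return(first |> select(-".is_risk", -".rank"))
  }
  rest <- ranked[-1, , drop = FALSE] |>
    arrange(dplyr::desc(.data$.is_risk),
            .data$class_l1 == first$class_l1,  # different class preferred
            .data$.rank, .data$accession, .data$chembl_target_id)
  second <- rest[1, , drop = FALSE]
  second$selection_reason <- if (second$.is_risk) {
    "risk gene match"
  } else if (second$class_l1 != first$class_l1) {
    "mechanistic diversity"
  } else {
    "primary therapeutic relevance"
  }
  bind_rows(first, second) |> select(-".is_risk", -".rank")
}

#' Curate all trial drugs
#'
#' Consolidates subunits and selects up to two class entries per
#' non-excluded drug.
#'
#' @param trial Trial tibble after [remap_microbial()].
#' @param risk_accessions Character vector of risk-gene accessions.
#' @return List with `trial` (input plus `curated` list-column) and
#'   `curated` (flat tibble, one row per retained (drug, target) pair).
#' @export
curate_trial_drugs <- function(trial, risk_accessions) {
  out <- trial
  out$curated <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    tg <- out$targets[[i]] |>
      filter(.data$organism == "human", !is.na(.data$accession))
    cons <- consolidate_subunits(tg)
    out$curated[[i]] <- curate_multi_target(cons, risk_accessions,
                                            excluded = out$excluded[i])
  }
  flat <- purrr::map2_dfr(out$drug_name, out$curated, function(d, cur) {
    if (nrow(cur) == 0) return(NULL)
    cur |> mutate(drug_name = d, .before = 1)
  })
  list(trial = out, curated = flat)
}

#' Drugs per curated target
#'
#' @param curated Flat curated tibble from [curate_trial_drugs()].
#' @return Tibble with `accession`, `chembl_target_id`, `class_l1` and
#'   `n_drugs`; the sum of `n_drugs` equals the total number of curated
#'   entries across drugs.
#' @export
drugs_per_target <- function(curated) {
  if (nrow(curated) == 0) {
    return(tibble(accession = character(0), chembl_target_id = character(0),
                  class_l1 = character(0), n_drugs = integer(0)))
  }
  curated |>
    group_by(.data$accession) |>
    summarise(chembl_target_id = dplyr::first(.data$chembl_target_id),
              class_l1 = dplyr::first(.data$class_l1),
              n_drugs = dplyr::n_distinct(.data$drug_name), .groups = "drop") |>
    arrange(.data$accession)
}
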