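# Target development levels (including the clinical-repurposing category),
# neurophenotype scoring, the multi-axis prioritization table and shortlists.

TDL_LEVELS <- c("Tclin_RP", "Tclin", "Tchem", "Tbio", "Tdark")
MP_INDEX_TERMS <- c("MP:0003631", "MP:0005386")  # nervous system; behavior/neurological
NO_DATA_MARKER <- "NO_DATA"

#' Load the per-target metadata table
#'
#' IDG-style metadata: base target development level, ChEMBL activity and
#' selective-compound counts, pathway/disease counts, mouse phenotype terms
#' (semicolon-separated MP identifiers, or the explicit `NO_DATA` marker),
#' grant dollars, patent count, Harmonizome data-availability (HDA) score and
#' a transcription-factor flag.
#'
#' @param source Path or data frame with columns `accession`, `tdl`,
#'   `chembl_activity_count`, `selective_compound_count`,
#'   `pathway_count_total`, `synaptic_pathway_count`, `disease_count`,
#'   `mp_terms`, `grant_dollars`, `patent_count`, `hda_score`, `is_tf`.
#' @return Tibble of typed metadata.
#' @export
load_target_meta <- function(source) {
  df <- read_table_auto(source)
  require_columns(df, c("accession", "tdl"), "target metadata table")
  opt <- c("chembl_activity_count", "selective_compound_count",
           "pathway_count_total", "synaptic_pathway_count", "disease_count",
           "mp_terms", "grant_dollars", "patent_count", "hda_score", "is_tf")
  for (col in setdiff(opt, names(df))) df[[col]] <- NA_character_
  bad <- !(df$tdl %in% c("Tclin", "Tchem", "Tbio", "Tdark"))
  if (any(bad)) {
    stop("target metadata: invalid base TDL value(s): ",
         paste(unique(df$tdl[bad]), collapse = ", "), call. = FALSE)
  }
  tibble(
    accession = trimws(df$accession),
    tdl_base = df$tdl,
    chembl_activity_count = parse_int(df$chembl_activity_count),
    selective_compound_count = parse_int(df$selective_compound_count),
    pathway_count_total = parse_int(df$pathway_count_total),
    synaptic_pathway_count = parse_int(df$synaptic_pathway_count),
    disease_count = parse_int(df$disease_count),
    mp_terms = ifelse(is_blank(df$mp_terms), NA_character_, trimws(df$mp_terms)),
    grant_dollars = parse_num(df$grant_dollars),
    patent_count = parse_int(df$patent_count),
    hda_score = parse_num(df$hda_score),
    is_tf = parse_logical(df$is_tf)
  )
}

#' Assign target development levels
#'
#' `Tclin_RP` if the accession is both an approved-drug target and a
#' clinical repurposing-trial target; `Tclin` if an approved-drug target
#' only; otherwise the base TDL from the metadata. A base label of `Tclin`
#' for an accession absent from the approved set is an inconsistency:
#' approved-set membership wins, the label is demoted to `Tbio`, and the case
#' is recorded in the `inconsistencies` attribute.
#'
#' @param meta Metadata tibble from [load_target_meta()].
#' @param approved_accessions Human target accessions of the approved-drug
#'   catalog.
#' @param trial_accessions Human target accessions of non-excluded trial
#'   drugs.
#' @return Tibble `accession`, `tdl` (factor with levels `Tclin_RP`,
#'   `Tclin`, `Tchem`, `Tbio`, `Tdark`).
#' @export
assign_tdl <- function(meta, approved_accessions, trial_accessions) {
  in_approved <- meta$accession %in% approved_accessions
  in_trial <- meta$accession %in% trial_accessions
  label <- meta$tdl_base
  inconsistent <- !in_approved & label == "Tclin"
  label[inconsistent] <- "Tbio"
  label[in_approved] <- "Tclin"
  label[in_approved & in_trial] <- "Tclin_RP"
  out <- tibble(accession = meta$accession,
                tdl = factor(label, levels = TDL_LEVELS))
  if (any(inconsistent)) {
    message(sum(inconsistent), " target(s) carried base TDL 'Tclin' without ",
            "approved-set membership; demoted to 'Tbio'")
    attr(out, "inconsistencies") <- meta$accession[inconsistent]
  }
  out
}

#' TDL distribution with genome background
#'
#' Counts and integer percentages per label over the supplied accessions,
#' with background rows for the druggable genome and the total genome for
#' comparison.
#'
#' @param labels Tibble from [assign_tdl()], restricted to the gene set of
#'   interest.
#' @param n_druggable_genome Size of the druggable genome background
#'   (distinct human targets of approved drugs; default 667).
#' @param n_genome Total protein-coding genes in the genome background
#'   (default 20120).
#' @return List with `summary` (label, n, proportion, pct) and `background`.
#' @export
tdl_distribution <- function(labels, n_druggable_genome = 667,
                             n_genome = 20120) {
  counts <- labels |>
    count(.data$tdl, .drop = FALSE) |>
    mutate(proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0,
           pct = round(100 * .data$proportion))
  background <- tibble(
    set = c("druggable_genome", "total_genome"),
    n = c(n_druggable_genome, n_genome)
  )
  list(summary = counts, background = background)
}

#' Mouse neurophenotype score
#'
#' Number of the two Mammalian Phenotype index terms — MP:0003631 "nervous
#' system phenotype" and MP:0005386 "behavior/neurological phenotype" —
#' present among a gene's mouse-orthologue annotations: 0, 1 or 2, or `NA`
#' when no phenotype data exist. Score 2 requires both terms. Malformed term
#' identifiers are ignored with a warning; the score is invariant to
#' non-index terms.
#'
#' @param mp_terms Character vector: each element a semicolon-separated list
#'   of MP identifiers, or the `NO_DATA` marker / `NA` for no data.
#' @return Integer vector of scores (NA where no data).
#' @export
neurophenotype_score <- function(mp_terms) {
  vapply(mp_terms, function(x) {
    if (is.na(x) || identical(toupper(trimws(x)), NO_DATA_MARKER)) {
      return(NA_integer_)
    }
    terms <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    terms <- terms[terms != ""]
    malformed <- !grepl("^MP:\\d+$", terms)
    if (any(malformed)) {
      warning("ignoring malformed MP term identifier(s): ",
              paste(terms[malformed], collapse = ", "), call. = FALSE)
      terms <- terms[!malformed]
    }
    sum(MP_INDEX_TERMS %in% terms)
  }, integer(1), USE.NAMES = FALSE)
}

#' Build the multi-axis prioritization table
#'
#' One record per genome-wide entity x source study x expression panel,
#' cross-referenced with the approved-drug index, repurposing status and the
#' extended target metadata (drug count, ChEMBL activity, synaptic and total
#' pathway counts, neurophenotype score, disease count, grant dollars, patent
#' count, HDA score, transcription-factor flag). Entities without metadata
#' are flagged (`meta_missing`) with null metrics.
#'
#' @param gw Genome-wide subset from [genome_wide_subset()].
#' @param catalog_index Index from [index_by_accession()].
#' @param meta Metadata tibble from [load_target_meta()].
#' @param labels TDL labels from [assign_tdl()].
#' @return Tibble, one row per association in the genome-wide subset.
#' @export
build_priority_table <- function(gw, catalog_index, meta, labels) {
  assoc <- gw$gw_associations
  if (nrow(assoc) == 0) {
    return(tibble(accession = character(0), symbol = character(0),
                  source = character(0)))
  }
  tab <- assoc |>
    transmute(
      accession = .data$accession,
      symbol = .data$gene_symbol,
      source = .data$analysis_kind,
      study_id = .data$study_id,
      expression_panel = .data$expression_panel,
      p_value = .data$p_value,
      neglog_p = ifelse(is.na(.data$p_value), NA_real_, -log10(.data$p_value))
    ) |>
    mutate(approved_drug_count = vapply(
      .data$accession,
      function(a) length(catalog_index[[a]] %||% character(0)), integer(1),
      USE.NAMES = FALSE)) |>
    left_join(labels, by = "accession") |>
    left_join(meta |> select(-"tdl_base"), by = "accession") |>
    mutate(meta_missing = !(.data$accession %in% meta$accession),
           neurophenotype = neurophenotype_score(.data$mp_terms)) |>
    arrange(.data$source, .data$accession, .data$study_id,
            .data$expression_panel)
  tab
}

# unique genes of a priority table (first row per accession)
dedupe_genes <- function(table) {
  table |> group_by(.data$accession) |> slice(1) |> ungroup()
}

#' Annotation tier counts over unique genes
#'
#' Unique genes with (i) any ChEMBL chemical-target interaction data
#' (activity count > 0), (ii) a mouse neurophenotype (score 1 or 2) and
#' (iii) at least one synaptic pathway annotation. Missing metadata is not
#' zero: nulls are excluded from the threshold counts.
#'
#' @param table Priority table from [build_priority_table()].
#' @param chembl_threshold Activity count strictly above which a gene counts
#'   as having chemical-target interaction data (default 0).
#' @return List `n_chembl`, `n_neuro`, `n_synaptic`.
#' @export
annotation_tier_counts <- function(table, chembl_threshold = 0) {
  g <- dedupe_genes(table)
  list(
    n_chembl = sum(g$chembl_activity_count > chembl_threshold, na.rm = TRUE),
    n_neuro = sum(g$neurophenotype %in% c(1L, 2L)),
    n_synaptic = sum(g$synaptic_pathway_count >= 1, na.rm = TRUE)
  )
}

#' Shortlist of dark-genome genes with mouse neurophenotypes
#'
#' Genes labelled `Tdark` whose neurophenotype score is 1 or 2, flagged as
#' multi-source when supported by two or more of the GWAS/TWAS/CNV sources.
#'
#' @param table Priority table.
#' @return Tibble `accession`, `symbol`, `neurophenotype`, `sources`,
#'   `multi_source`.
#' @export
shortlist_tdark_neuro <- function(table) {
  src <- table |>
    group_by(.data$accession) |>
    summarise(sources = list(sort_unique(.data$source)), .groups = "drop")
  dedupe_genes(table) |>
    filter(.data$tdl == "Tdark", .data$neurophenotype %in% c(1L, 2L)) |>
    select("accession", "symbol", "neurophenotype") |>
    left_join(src, by = "accession") |>
    mutate(multi_source = vapply(.data$sources, length, integer(1)) >= 2) |>
    arrange(.data$accession)
}

#' Shortlist of genes with low Harmonizome data-availability scores
#'
#' @param table Priority table.
#' @param threshold Genes with `hda_score` strictly below this value are
#'   retained (default 10).
#' @return Tibble of unique genes with `accession`, `symbol`, `tdl`,
#'   `hda_score`.
#' @export
shortlist_low_hda <- function(table, threshold = 10) {
  dedupe_genes(table) |>
    filter(!is.na(.data$hda_score), .data$hda_score < threshold) |>
    select("accession", "symbol", "tdl", "hda_score") |>
    arrange(.data$accession)
}

#' Multi-source intersections of the genome-wide gene sets
#'
#' @param table Priority table (or any tibble with `accession` and `source`).
#' @return List with `per_source` (named sizes), `pairwise` (tibble of
#'   pairwise unique-gene overlaps) and `all_sources` (accessions common to
#'   every source present).
#' @export
multi_source_intersection <- function(table) {
  sets <- lapply(split(table$accession, table$source), unique)
  srcs <- sort(names(sets))
  pairs <- if (length(srcs) >= 2) utils::combn(srcs, 2, simplify = FALSE) else list()
  pairwise <- tibble(
    source_a = vapply(pairs, `[`, character(1), 1),
    source_b = vapply(pairs, `[`, character(1), 2),
    n = vapply(pairs, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]])),
               integer(1))
  )
  all_sources <- if (length(sets) > 0) sort(Reduce(intersect, sets)) else character(0)
  list(per_source = vapply(sets, length, integer(1)),
       pairwise = pairwise,
       all_sources = all_sources)
}

#' Transcription factor summary
#'
#' @param table Priority table.
#' @return List `n_tf` (unique transcription-factor genes) and `n_tf_neuro`
#'   (those with a mouse neurophenotype score of 1 or 2).
#' @export
transcription_factor_summary <- function(table) {
  g <- dedupe_genes(table) |> filter(!is.na(.data$is_tf), .data$is_tf)
  list(n_tf = nrow(g), n_tf_neuro = sum(g$neurophenotype %in% c(1L, 2L)))
}
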