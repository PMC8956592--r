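# Ingest of gene-association lists from the three evidence classes
# (common, rare, expression), accession mapping and merge to gene entities.

#' Analysis kinds and their evidence classes
#'
#' The evidence class of an association is a deterministic function of the
#' analysis kind: GWAS and PheWAS probe common variation, CNV and exome
#' sequencing probe rare variation, TWAS and expression profiling probe
#' expression-related variation.
#' @return Named character vector mapping analysis kind to evidence class.
#' @export
evidence_class_map <- function() {
  c(GWAS = "common", PheWAS = "common",
    CNV = "rare", exome = "rare",
    TWAS = "expression", expression_profiling = "expression")
}

#' Parse a gene-association table
#'
#' Reads one evidence table (TSV/CSV path or data frame) into validated
#' gene associations. Rows failing validation are collected into a rejects
#' report rather than silently dropped. Duplicated rows (same gene, study and
#' expression panel) are collapsed with a warning.
#'
#' @param source Path to a TSV/CSV file, or a data frame.
#' @param schema Optional named character vector mapping canonical column
#'   names (`gene_symbol`, `analysis_kind`, `study_id`, `genome_wide`,
#'   `p_value`, `expression_panel`, `accession`) to the column names used in
#'   `source`. Defaults to identity.
#' @return A list with `associations` (tibble, one row per valid association)
#'   and `rejects` (tibble with `row`, `gene_symbol`, `reason`).
#' @export
parse_evidence_table <- function(source, schema = NULL) {
  df <- read_table_auto(source)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("evidence table: missing required column(s): ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  require_columns(df, c("gene_symbol", "analysis_kind", "study_id", "genome_wide"),
                  "evidence table")
  if (!"p_value" %in% names(df)) df$p_value <- NA_character_
  if (!"expression_panel" %in% names(df)) df$expression_panel <- NA_character_
  if (!"accession" %in% names(df)) df$accession <- NA_character_

  n <- nrow(df)
  class_map <- evidence_class_map()
  reason <- rep(NA_character_, n)

  symbol <- norm_symbol(df$gene_symbol)
  reason[is.na(reason) & is_blank(symbol)] <- "missing gene_symbol"
  kind <- trimws(df$analysis_kind)
  reason[is.na(reason) & !(kind %in% names(class_map))] <- "unknown analysis_kind"
  reason[is.na(reason) & is_blank(df$study_id)] <- "missing study_id"

  p_raw <- df$p_value
  p <- parse_num(p_raw)
  bad_p <- !is_blank(p_raw) & is.na(p)
  reason[is.na(reason) & bad_p] <- "unparseable p_value"
  out_of_range <- !is.na(p) & (p <= 0 | p > 1)
  reason[is.na(reason) & out_of_range] <- "p_value out of range (0,1]"

  gw <- parse_logical(df$genome_wide)
  reason[is.na(reason) & is.na(gw)] <- "unparseable genome_wide flag"

  keep <- is.na(reason)
  rejects <- tibble(
    row = which(!keep),
    gene_symbol = symbol[!keep],
    reason = reason[!keep]
  )

  assoc <- tibble(
    gene_symbol = symbol[keep],
    accession = ifelse(is_blank(df$accession[keep]), NA_character_,
                       trimws(df$accession[keep])),
    analysis_kind = kind[keep],
    evidence_class = unname(class_map[kind[keep]]),
    study_id = trimws(df$study_id[keep]),
    p_value = p[keep],
    expression_panel = ifelse(is_blank(df$expression_panel[keep]), NA_character_,
                              trimws(df$expression_panel[keep])),
    genome_wide = gw[keep]
  )

  dup <- duplicated(assoc[, c("gene_symbol", "study_id", "expression_panel")])
  if (any(dup)) {
    warning(sum(dup), " duplicated association row(s) (same gene, study, panel)",
            " collapsed; counts are reported after collapse", call. = FALSE)
    assoc <- assoc[!dup, , drop = FALSE]
  }
  list(associations = assoc, rejects = rejects)
}

#' Map gene symbols to protein accessions
#'
#' Every association either gains at least one accession or appears in the
#' unmapped report. Symbols mapping to several accessions expand to one
#' association per accession; the expansion multiplicity is recorded in the
#' `mapping_multiplicity` provenance column (0 = accession supplied in the
#' input, bypassing the mapping).
#'
#' @param associations Tibble from [parse_evidence_table()].
#' @param mapping Data frame or path with columns `symbol`, `accession`.
#' @return List with `mapped` (associations, all carrying an accession) and
#'   `unmapped` (report tibble).
#' @export
map_to_accessions <- function(associations, mapping) {
  map_df <- read_table_auto(mapping)
  require_columns(map_df, c("symbol", "accession"), "symbol mapping table")
  map_df <- map_df |>
    mutate(symbol = norm_symbol(.data$symbol),
           accession = trimws(.data$accession)) |>
    filter(!is_blank(.data$symbol), !is_blank(.data$accession)) |>
    distinct(.data$symbol, .data$accession)
  if (nrow(map_df) == 0) {
    stop("symbol mapping table is empty", call. = FALSE)
  }
  multiplicity <- map_df |> count(.data$symbol, name = "mapping_multiplicity")

  pre_mapped <- associations |>
    filter(!is.na(.data$accession)) |>
    mutate(mapping_multiplicity = 0L)
  to_map <- associations |> filter(is.na(.data$accession)) |> select(-"accession")

  hits <- to_map |>
    inner_join(map_df, by = c(gene_symbol = "symbol"), relationship = "many-to-many") |>
    left_join(multiplicity, by = c(gene_symbol = "symbol"))
  misses <- to_map |> anti_join(map_df, by = c(gene_symbol = "symbol"))

  mapped <- bind_rows(pre_mapped, hits) |>
    select("gene_symbol", "accession", "analysis_kind", "evidence_class",
           "study_id", "p_value", "expression_panel", "genome_wide",
           "mapping_multiplicity")
  unmapped <- misses |>
    distinct(.data$gene_symbol, .data$study_id) |>
    mutate(reason = "symbol not in mapping table")
  list(mapped = mapped, unmapped = unmapped)
}

#' Merge accession-mapped associations into gene entities
#'
#' One entity per distinct accession; `evidence_classes` is the union over
#' the entity's associations. Idempotent: merging an already merged entity
#' set returns it unchanged, and the result is invariant to the input row
#' order.
#'
#' @param mapped Tibble of accession-mapped associations.
#' @return Entity tibble with columns `accession`, `symbols` (list),
#'   `evidence_classes` (list), `n_assoc` and `associations` (nested tibble).
#' @export
merge_by_accession <- function(mapped) {
  if (all(c("evidence_classes", "associations") %in% names(mapped))) {
    return(mapped)  # already merged
  }
  if (any(is.na(mapped$accession))) {
    stop("unmapped association present: all associations must carry an accession",
         call. = FALSE)
  }
  mapped |>
    arrange(.data$accession, .data$study_id, .data$expression_panel,
            .data$gene_symbol) |>
    group_by(.data$accession) |>
    summarise(
      symbols = list(sort_unique(.data$gene_symbol)),
      evidence_classes = list(sort_unique(.data$evidence_class)),
      n_assoc = dplyr::n(),
      associations = list(pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    arrange(.data$accession)
}

#' Genome-wide significant subset of gene entities
#'
#' Retains entities having at least one genome-wide-flagged association from
#' a whitelisted study (the studies that report genome-wide significance).
#' Monotone in the whitelist and always a subset of the input.
#'
#' @param entities Entity tibble from [merge_by_accession()].
#' @param study_whitelist Character vector of study ids reporting genome-wide
#'   significance; must be non-empty.
#' @return List with `entities` (the subset), `gw_associations` (flat tibble
#'   of the genome-wide associations with their accessions) and
#'   `source_counts` (per analysis kind: association and unique-gene counts).
#' @export
genome_wide_subset <- function(entities, study_whitelist) {
  if (length(study_whitelist) == 0) {
    stop("study whitelist must be non-empty", call. = FALSE)
  }
  flat <- entities |>
    select("accession", "associations") |>
    tidyr::unnest("associations")
  gw <- flat |>
    filter(.data$genome_wide, .data$study_id %in% study_whitelist)
  source_counts <- gw |>
    group_by(source = .data$analysis_kind) |>
    summarise(n_associations = dplyr::n(),
              n_genes = dplyr::n_distinct(.data$accession), .groups = "drop") |>
    arrange(.data$source)
  list(
    entities = entities |> filter(.data$accession %in% gw$accession),
    gw_associations = gw,
    source_counts = source_counts
  )
}

#' Negative log10 transform of a P value
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @return `-log10(p)`, strictly decreasing in `p`.
#' @export
neglog_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  -log10(p)
}
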