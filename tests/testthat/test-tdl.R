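# target development levels, neurophenotype scoring, the priority table and
# its shortlists

meta_fixture <- function() {
  load_target_meta(tibble::tibble(
    accession = c("P1", "P2", "P3", "P4"),
    tdl = c("Tclin", "Tchem", "Tdark", "Tclin"),
    chembl_activity_count = c("120", "15", "0", "3"),
    selective_compound_count = "0",
    pathway_count_total = c("5", "2", "1", "4"),
    synaptic_pathway_count = c("2", "0", "0", "1"),
    disease_count = "1",
    mp_terms = c("MP:0003631;MP:0005386", "MP:0003631", "NO_DATA",
                 "MP:0001262"),
    grant_dollars = "1000", patent_count = "2",
    hda_score = c("55", "30", "4", "70"), is_tf = c("FALSE", "TRUE",
                                                    "FALSE", "FALSE")
  ))
}

test_that("TDL assignment follows approved/trial membership with precedence", {
  meta <- meta_fixture()
  labels <- assign_tdl(meta, approved_accessions = c("P1", "P4"),
                       trial_accessions = c("P1", "P9"))
  lab <- setNames(as.character(labels$tdl), labels$accession)
  expect_equal(lab[["P1"]], "Tclin_RP")  # approved and in a trial
  expect_equal(lab[["P4"]], "Tclin")     # approved only
  expect_equal(lab[["P2"]], "Tchem")     # base label
  expect_equal(lab[["P3"]], "Tdark")     # unexplored
  expect_equal(levels(labels$tdl), c("Tclin_RP", "Tclin", "Tchem", "Tbio",
                                     "Tdark"))

  # base Tclin without approved membership: membership wins, case is logged
  expect_message(
    demoted <- assign_tdl(meta, approved_accessions = "P4",
                          trial_accessions = character(0)),
    "demoted")
  expect_equal(as.character(demoted$tdl[demoted$accession == "P1"]), "Tbio")
  expect_identical(attr(demoted, "inconsistencies"), "P1")
})

test_that("the TDL distribution reports percentages and genome background", {
  labels <- tibble::tibble(accession = c("P1", "P2"),
                           tdl = factor("Tdark", levels = c(
                             "Tclin_RP", "Tclin", "Tchem", "Tbio", "Tdark")))
  d <- tdl_distribution(labels)
  expect_equal(d$summary$pct[d$summary$tdl == "Tdark"], 100)
  expect_equal(sum(d$summary$n), 2)
  expect_setequal(d$background$set, c("druggable_genome", "total_genome"))
})

test_that("the neurophenotype score counts index terms only", {
  expect_true(is.na(neurophenotype_score("NO_DATA")))
  expect_true(is.na(neurophenotype_score(NA_character_)))
  expect_equal(neurophenotype_score("MP:0003631;MP:0005386;MP:0001262"), 2)
  expect_equal(neurophenotype_score("MP:0001262"), 0)
  expect_equal(neurophenotype_score("MP:0005386"), 1)
  expect_warning(s <- neurophenotype_score("MP:0003631;bogus"), "malformed")
  expect_equal(s, 1)

  # monotone in the index-term subset, invariant to non-index terms
  set.seed(3)
  junk <- c("MP:0000001", "MP:0002066", "MP:0009999")
  for (i in 1:20) {
    base_terms <- sample(junk, sample(0:3, 1))
    s0 <- neurophenotype_score(paste(c(base_terms, "MP:0000123"),
                                     collapse = ";"))
    s1 <- neurophenotype_score(paste(c(base_terms, "MP:0003631"),
                                     collapse = ";"))
    s2 <- neurophenotype_score(paste(c(base_terms, "MP:0003631",
                                       "MP:0005386"), collapse = ";"))
    expect_equal(s0, 0)
    expect_lte(s0, s1)
    expect_lte(s1, s2)
    expect_equal(s2, 2)
  }
})

priority_fixture <- function() {
  ents <- tiny_entities()
  gw <- genome_wide_subset(ents, c("S1", "S3", "S4"))
  meta <- load_target_meta(tibble::tibble(
    accession = c("P00001", "P00002", "P00003", "P00004", "P00005"),
    tdl = c("Tclin", "Tdark", "Tchem", "Tdark", "Tbio"),
    chembl_activity_count = c("10", "0", "25", "0", "0"),
    selective_compound_count = "0", pathway_count_total = "3",
    synaptic_pathway_count = c("1", "0", "0", "0", "2"),
    disease_count = "1",
    mp_terms = c("MP:0003631", "MP:0003631;MP:0005386", "NO_DATA",
                 "MP:0001262", "MP:0005386"),
    grant_dollars = "1", patent_count = "0",
    hda_score = c("50", "3", "40", "8", "60"),
    is_tf = c("FALSE", "FALSE", "TRUE", "FALSE", "FALSE")
  ))
  idx <- list(P00001 = c("d1", "d2"))
  labels <- assign_tdl(meta, names(idx), trial_accessions = "P00001")
  list(gw = gw, meta = meta, idx = idx, labels = labels,
       table = build_priority_table(gw, idx, meta, labels))
}

test_that("the priority table has one record per association with all axes", {
  fx <- priority_fixture()
  expect_equal(nrow(fx$table), nrow(fx$gw$gw_associations))
  # two panel rows for the TWAS gene appear as discrete records
  expect_equal(sum(fx$table$accession == "P00003"), 2)
  expect_equal(fx$table$neglog_p, -log10(fx$table$p_value))
  # drug count is positive exactly for clinical-level targets
  expect_identical(fx$table$approved_drug_count > 0,
                   fx$table$tdl %in% c("Tclin", "Tclin_RP"))
  # empty genome-wide set gives an empty table
  ents <- tiny_entities()
  empty_gw <- genome_wide_subset(ents, "NOT_A_STUDY")
  expect_equal(nrow(build_priority_table(empty_gw, fx$idx, fx$meta,
                                         fx$labels)), 0)
})

test_that("tier counts deduplicate genes and treat missing as missing", {
  fx <- priority_fixture()
  tiers <- annotation_tier_counts(fx$table)
  expect_equal(tiers$n_chembl, 2)   # P00001, P00003 (counted once)
  expect_equal(tiers$n_neuro, 3)    # P00001, P00002, P00005; P00004 scores 0
  expect_equal(tiers$n_synaptic, 2)
  n_genes <- dplyr::n_distinct(fx$table$accession)
  expect_true(all(unlist(tiers) <= n_genes))

  null_meta <- fx$meta
  null_meta[, -(1:2)] <- NA
  labels <- suppressMessages(assign_tdl(null_meta, character(0), character(0)))
  tab <- suppressMessages(
    build_priority_table(fx$gw, list(), null_meta, labels))
  expect_equal(unlist(annotation_tier_counts(tab)),
               c(n_chembl = 0, n_neuro = 0, n_synaptic = 0))
})

test_that("shortlists are stable filters of the priority table", {
  fx <- priority_fixture()
  dark <- shortlist_tdark_neuro(fx$table)
  expect_equal(dark$accession, "P00002")  # Tdark with both index terms
  expect_false(dark$multi_source)         # GWAS only
  low <- shortlist_low_hda(fx$table, threshold = 10)
  expect_setequal(low$accession, c("P00002", "P00004"))
  expect_equal(nrow(shortlist_low_hda(fx$table, threshold = 0)), 0)
  # filters: output within input, invariant to row permutation
  set.seed(21)
  shuffled <- fx$table[sample.int(nrow(fx$table)), ]
  expect_identical(shortlist_tdark_neuro(shuffled), dark)
  expect_identical(shortlist_low_hda(shuffled, 10), low)
  expect_true(all(dark$accession %in% fx$table$accession))
})

test_that("source intersections and the TF summary count unique genes", {
  fx <- priority_fixture()
  ms <- multi_source_intersection(fx$table)
  expect_equal(unname(ms$per_source[c("CNV", "GWAS", "TWAS")]),
               c(2L, 2L, 1L))
  expect_length(ms$all_sources, 0)  # no gene is in all three sources
  tf <- transcription_factor_summary(fx$table)
  expect_equal(tf$n_tf, 1)          # P00003
  expect_equal(tf$n_tf_neuro, 0)    # its phenotype data are missing
  # boundary: no TFs at all
  no_tf <- fx$table
  no_tf$is_tf <- FALSE
  expect_equal(unlist(transcription_factor_summary(no_tf)),
               c(n_tf = 0, n_tf_neuro = 0))
})
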