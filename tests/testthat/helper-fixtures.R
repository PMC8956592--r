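# in-code fixtures and comparison helpers shared across the tests

# a small, fully hand-checkable evidence table
tiny_evidence <- function() {
  tibble::tribble(
    ~gene_symbol, ~analysis_kind, ~study_id, ~p_value, ~expression_panel, ~genome_wide,
    "geneA", "GWAS", "S1", "1e-9",  NA,      "TRUE",
    "GENEB", "GWAS", "S1", "2e-8",  NA,      "TRUE",
    "geneB", "exome", "S2", "0.001", NA,     "FALSE",
    "GENEC", "TWAS", "S3", "1e-10", "BRAIN", "TRUE",
    "GENEC", "TWAS", "S3", "1e-8",  "BLOOD", "TRUE",
    "GENED", "CNV",  "S4", "1e-6",  NA,      "TRUE"
  )
}

tiny_mapping <- function() {
  tibble::tribble(
    ~symbol, ~accession,
    "GENEA", "P00001",
    "GENEB", "P00002",
    "GENEC", "P00003",
    "GENED", "P00004",
    "GENED", "P00005"   # 1:2 mapping
  )
}

tiny_entities <- function() {
  parsed <- parse_evidence_table(tiny_evidence())
  mapped <- map_to_accessions(parsed$associations, tiny_mapping())
  merge_by_accession(mapped$mapped)
}

# consolidated target annotations for curation tests
make_targets <- function(accession, class_l1, rank,
                         chembl = paste0("CH_", accession)) {
  tibble::tibble(
    accession = accession, chembl_target_id = chembl,
    class_l1 = class_l1, class_l2 = NA_character_, class_l3 = NA_character_,
    organism = "human", complex_id = NA_character_,
    therapeutic_rank = as.integer(rank)
  )
}

# independent rule oracle for the <=2-entry selection: exhaustive pairwise
# comparison of candidates under the stated rule order, no sorting shared
# with the implementation
oracle_curate <- function(targets, risk_accessions) {
  n <- nrow(targets)
  if (n == 0) return(character(0))
  r <- targets$accession %in% risk_accessions
  rk <- ifelse(is.na(targets$therapeutic_rank), Inf, targets$therapeutic_rank)
  acc <- targets$accession
  ch <- targets$chembl_target_id
  better_first <- function(i, j) {
    if (r[i] != r[j]) return(r[i])
    if (rk[i] != rk[j]) return(rk[i] < rk[j])
    if (acc[i] != acc[j]) return(acc[i] < acc[j])
    ch[i] < ch[j]
  }
  first <- 1L
  for (i in seq_len(n)[-1]) if (better_first(i, first)) first <- i
  if (n == 1) return(acc[first])
  same_class <- targets$class_l1 == targets$class_l1[first]
  better_second <- function(i, j) {
    if (r[i] != r[j]) return(r[i])
    if (same_class[i] != same_class[j]) return(!same_class[i])
    if (rk[i] != rk[j]) return(rk[i] < rk[j])
    if (acc[i] != acc[j]) return(acc[i] < acc[j])
    ch[i] < ch[j]
  }
  rest <- setdiff(seq_len(n), first)
  second <- rest[1]
  for (i in rest[-1]) if (better_second(i, second)) second <- i
  c(acc[first], acc[second])
}

# full pipeline-vs-manifest comparison
expect_matches_manifest <- function(summary, manifest) {
  for (k in names(manifest$counts)) {
    expect_equal(as.numeric(summary$counts[[k]]),
                 as.numeric(manifest$counts[[k]]),
                 info = paste("count:", k))
  }
  for (k in names(manifest$sets)) {
    expect_identical(sort(unlist(summary$sets[[k]])),
                     sort(unname(unlist(manifest$sets[[k]]))),
                     info = paste("set:", k))
  }
  cmp_named <- function(a, e, nm) {
    a <- unlist(a)[order(names(unlist(a)))]
    e <- unlist(e)[order(names(unlist(e)))]
    expect_identical(as.integer(a), as.integer(e), info = nm)
    expect_identical(names(a), names(e), info = nm)
  }
  cmp_named(summary$dist_genetic, manifest$dist_genetic, "genetic distribution")
  cmp_named(summary$dist_trial, manifest$dist_trial, "trial distribution")
  cmp_named(summary$drugs_per_target, manifest$drugs_per_target,
            "drugs per target")
  for (d in names(manifest$curated)) {
    expect_identical(sort(unlist(summary$curated[[d]])),
                     sort(unname(unlist(manifest$curated[[d]]))),
                     info = paste("curated entries:", d))
  }
}

# a small config variant per seed, kept feasible by construction
varied_config <- function(seed) {
  synth_config(
    seed = seed,
    nongw_genes = c(common = 45 + seed %% 4, rare = 55, expression = 30),
    druggable = list(common_only = c(gw = 6, nongw = 3),
                     rare_only = c(gw = 2, nongw = 3),
                     expression_only = c(gw = 2, nongw = 1),
                     multi = 2 + seed %% 3),
    trial = list(n_drugs = 32, n_microbial = 3, n_remappable = 2,
                 n_multi_target = 6 + seed %% 3, n_risk_genes = 10,
                 complex_sizes = c(2, 2), n_targets = 26,
                 n_drugs_on_risk = 9 + seed %% 2)
  )
}

run_bundle <- function(cfg, dir) {
  b <- generate_bundle(cfg, dir)
  s <- run_all(run_config(bundle_dir = dir, verbose = 0))
  list(bundle = b, summary = s)
}
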