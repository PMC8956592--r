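# evidence ingest: parsing, validation, accession mapping, merge, genome-wide
# subset and the P-value transform

test_that("parsing matches a brute-force row-by-row validation oracle", {
  set.seed(41)
  n <- 100
  kinds <- c("GWAS", "PheWAS", "CNV", "exome", "TWAS", "expression_profiling")
  tbl <- tibble::tibble(
    gene_symbol = sprintf("G%03d", seq_len(n)),
    analysis_kind = sample(kinds, n, replace = TRUE),
    study_id = sample(c("S1", "S2", "S3"), n, replace = TRUE),
    p_value = as.character(signif(runif(n, 1e-12, 0.05), 4)),
    expression_panel = NA_character_,
    genome_wide = sample(c("TRUE", "FALSE"), n, replace = TRUE)
  )
  bad_rows <- c(10, 50, 90)
  tbl$p_value[bad_rows] <- c("not_a_number", "-0.5", "1.5")

  # independent oracle: validate each row with base R only
  ok <- logical(n)
  for (i in seq_len(n)) {
    p <- suppressWarnings(as.numeric(tbl$p_value[i]))
    ok[i] <- nzchar(tbl$gene_symbol[i]) &&
      tbl$analysis_kind[i] %in% kinds &&
      (!is.na(p) && p > 0 && p <= 1) &&
      tbl$genome_wide[i] %in% c("TRUE", "FALSE")
  }

  res <- parse_evidence_table(tbl)
  expect_equal(nrow(res$associations), sum(ok))
  expect_equal(nrow(res$rejects), sum(!ok))
  expect_setequal(res$rejects$row, bad_rows)
  expect_true(all(grepl("p_value", res$rejects$reason)))
})

test_that("an empty table with a valid header yields empty outputs", {
  empty <- tiny_evidence()[0, ]
  res <- parse_evidence_table(empty)
  expect_equal(nrow(res$associations), 0)
  expect_equal(nrow(res$rejects), 0)
})

test_that("evidence class is a deterministic function of analysis kind", {
  res <- parse_evidence_table(tiny_evidence())
  expect_identical(res$associations$evidence_class,
                   unname(evidence_class_map()[res$associations$analysis_kind]))
})

test_that("missing required columns and duplicated rows are handled", {
  broken <- tiny_evidence()[, -1]
  expect_error(parse_evidence_table(broken), "gene_symbol")

  dup <- dplyr::bind_rows(tiny_evidence(), tiny_evidence()[1, ])
  expect_warning(res <- parse_evidence_table(dup), "collapsed")
  expect_equal(nrow(res$associations), nrow(tiny_evidence()))
})

test_that("symbol mapping maps, reports unmapped, and expands 1:n symbols", {
  parsed <- parse_evidence_table(tiny_evidence())
  res <- map_to_accessions(parsed$associations, tiny_mapping())
  expect_true(all(!is.na(res$mapped$accession)))
  # GENED maps to two accessions: one extra row
  expect_equal(nrow(res$mapped), nrow(parsed$associations) + 1)
  expect_equal(sort(unique(
    res$mapped$mapping_multiplicity[res$mapped$gene_symbol == "GENED"])), 2)
  expect_equal(nrow(res$unmapped), 0)

  # unmapped symbols are reported, not dropped silently
  res2 <- map_to_accessions(parsed$associations, tiny_mapping()[1:2, ])
  expect_setequal(res2$unmapped$gene_symbol, c("GENEC", "GENED"))
  expect_true(all(!is.na(res2$mapped$accession)))

  expect_error(
    map_to_accessions(parsed$associations,
                      data.frame(symbol = character(0),
                                 accession = character(0))),
    "empty")
})

test_that("merge is idempotent, order-independent and counts correctly", {
  parsed <- parse_evidence_table(tiny_evidence())
  mapped <- map_to_accessions(parsed$associations, tiny_mapping())$mapped
  ents <- merge_by_accession(mapped)
  # |entities| <= |associations|, equality iff all accessions distinct
  expect_lte(nrow(ents), nrow(mapped))
  expect_equal(nrow(ents), dplyr::n_distinct(mapped$accession))
  # union of evidence classes per entity
  b <- ents[ents$accession == "P00002", ]
  expect_identical(b$evidence_classes[[1]], c("common", "rare"))
  # idempotence and permutation invariance
  expect_identical(merge_by_accession(ents), ents)
  set.seed(7)
  shuffled <- mapped[sample.int(nrow(mapped)), ]
  expect_identical(merge_by_accession(shuffled), ents)
  # unmapped rows violate the precondition
  mapped$accession[1] <- NA
  expect_error(merge_by_accession(mapped), "unmapped")
})

test_that("genome-wide subset filters by whitelist and is monotone", {
  ents <- tiny_entities()
  expect_error(genome_wide_subset(ents, character(0)), "non-empty")

  none <- genome_wide_subset(ents, "NOT_A_STUDY")
  expect_equal(nrow(none$entities), 0)

  gw <- genome_wide_subset(ents, c("S1", "S3", "S4"))
  expect_setequal(gw$entities$accession,
                  c("P00001", "P00002", "P00003", "P00004", "P00005"))
  # GENEB's exome row is not genome-wide; GENEC has two panel rows
  expect_equal(
    gw$source_counts$n_associations[gw$source_counts$source == "TWAS"], 2)
  expect_equal(
    gw$source_counts$n_genes[gw$source_counts$source == "TWAS"], 1)

  # monotone in the whitelist; always a subset of the input
  sub1 <- genome_wide_subset(ents, "S1")$entities$accession
  sub13 <- genome_wide_subset(ents, c("S1", "S3"))$entities$accession
  expect_true(all(sub1 %in% sub13))
  expect_true(all(sub13 %in% ents$accession))
})

test_that("the negative log10 transform matches its closed form", {
  expect_equal(neglog_p(1), 0)
  expect_equal(neglog_p(0.05), 1.3010, tolerance = 1e-4)
  expect_equal(neglog_p(5e-8), 7.3010, tolerance = 1e-4)
  expect_true(neglog_p(0.01) > neglog_p(0.02))  # strictly decreasing
  expect_error(neglog_p(0), "0, 1")
  expect_error(neglog_p(1.2), "0, 1")
})
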