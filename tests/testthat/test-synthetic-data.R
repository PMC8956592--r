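# the synthetic-data generator: determinism, feasibility validation,
# boundary configs and monotonicity probes

test_that("identical seeds give byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synth_config(seed = 5)
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  for (f in setdiff(names(b1$paths), "manifest")) {
    expect_identical(unname(tools::md5sum(b1$paths[[f]])),
                     unname(tools::md5sum(b2$paths[[f]])), info = f)
  }
  expect_identical(b1$manifest, b2$manifest)
  # a different seed changes the bundle
  b3 <- generate_bundle(synth_config(seed = 6), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(b1$paths$evidence)),
                         unname(tools::md5sum(b3$paths$evidence))))
})

test_that("infeasible configurations fail validation before generation", {
  expect_error(synth_config(gw_overlap = c(gwas_twas = 60, gwas_cnv = 8,
                                           twas_cnv = 6, triple = 4)),
               "infeasible")
  expect_error(synth_config(gw_overlap = c(gwas_twas = 25, gwas_cnv = 8,
                                           twas_cnv = 6, triple = 10)),
               "infeasible")
  expect_error(synth_config(druggable = list(
    common_only = c(gw = 6, nongw = 3), rare_only = c(gw = 2, nongw = 3),
    expression_only = c(gw = 2, nongw = 1), multi = 40)), "infeasible")
  expect_error(synth_config(trial = list(
    n_drugs = 32, n_microbial = 3, n_remappable = 5, n_multi_target = 8,
    n_risk_genes = 10, complex_sizes = c(2, 2), n_targets = 26,
    n_drugs_on_risk = 9)), "infeasible")
  expect_error(synth_config(trial = list(
    n_drugs = 32, n_microbial = 3, n_remappable = 2, n_multi_target = 8,
    n_risk_genes = 10, complex_sizes = c(2, 2), n_targets = 200,
    n_drugs_on_risk = 9)), "infeasible")
})

zero_druggable_config <- function(seed = 2) {
  synth_config(
    seed = seed,
    druggable = list(common_only = c(gw = 0, nongw = 0),
                     rare_only = c(gw = 0, nongw = 0),
                     expression_only = c(gw = 0, nongw = 0), multi = 0),
    trial = list(n_drugs = 20, n_microbial = 2, n_remappable = 1,
                 n_multi_target = 5, n_risk_genes = 0,
                 complex_sizes = integer(0), n_targets = 14,
                 n_drugs_on_risk = 0),
    tdl_gw = NULL
  )
}

test_that("a zero druggable overlap gives an empty druggable set end to end", {
  d <- withr::local_tempdir()
  b <- generate_bundle(zero_druggable_config(), d)
  expect_equal(b$manifest$counts$n_druggable_genes, 0)
  expect_length(b$manifest$sets$druggable, 0)
  s <- run_all(run_config(bundle_dir = d, verbose = 0))
  expect_equal(s$counts$n_druggable_genes, 0)
  expect_equal(s$counts$n_tclin_rp + s$counts$n_tclin, 0)
  expect_equal(s$counts$n_supported_targets, 0)
})

test_that("planting more overlap never shrinks the downstream sets", {
  base <- varied_config(1)
  more_druggable <- synth_config(
    seed = 1,
    nongw_genes = base$nongw_genes,
    druggable = list(common_only = c(gw = 9, nongw = 3),
                     rare_only = c(gw = 4, nongw = 3),
                     expression_only = c(gw = 3, nongw = 1), multi = 3),
    n_drugs_risk = 30,
    trial = base$trial
  )
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b_base <- generate_bundle(base, d1)
  b_more <- generate_bundle(more_druggable, d2)
  expect_gte(b_more$manifest$counts$n_druggable_genes,
             b_base$manifest$counts$n_druggable_genes)

  more_trial <- synth_config(
    seed = 1,
    nongw_genes = base$nongw_genes,
    druggable = base$druggable,
    trial = modifyList(base$trial, list(n_risk_genes = 14,
                                        n_drugs_on_risk = 13,
                                        n_targets = 28))
  )
  d3 <- withr::local_tempdir()
  b_trial <- generate_bundle(more_trial, d3)
  expect_gte(b_trial$manifest$counts$n_tclin_rp,
             b_base$manifest$counts$n_tclin_rp)
})

test_that("the paper-scale profile plants the published study conditions", {
  d <- withr::local_tempdir()
  b <- generate_bundle(paper_scale_profile(seed = 4), d)
  ev <- readr::read_tsv(file.path(d, "evidence.tsv"), show_col_types = FALSE)
  cls <- evidence_class_map()[ev$analysis_kind]
  expect_equal(as.integer(table(cls)[c("common", "rare", "expression")]),
               c(435L, 246L, 338L))
  trial <- readr::read_tsv(file.path(d, "trial_drugs.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(trial), 89)
  # unique-gene count within 10% of the published 748, per the manifest
  expect_lt(abs(b$manifest$counts$n_unique_genes - 748) / 748, 0.10)
  # the planted GWAS discrepancy: 416 genome-wide associations, 414 genes
  expect_equal(b$manifest$counts$gw_assoc_GWAS, 416)
  expect_equal(b$manifest$counts$gw_genes_GWAS, 414)
})
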