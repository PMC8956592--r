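# approved-drug catalog parsing and the trial-drug curation rules

make_catalog <- function() {
  tibble::tibble(
    drug_name = c("DrugA", "DrugA", "DrugB", "DrugC", "DrugC"),
    molecule_type = "small molecule",
    moa = "x",
    accession = c("P1", "P2", "P3", NA, "M1"),
    chembl_target_id = c("C1", "C2", "C3", "C4", "C5"),
    class_l1 = c("ion channel", "enzyme", "enzyme", "enzyme", "enzyme"),
    class_l2 = NA, class_l3 = NA,
    organism = c("human", "human", "human", "human", "microbial"),
    complex_id = NA, atc = "X", approval_year = "2000",
    therapeutic_rank = c("1", "2", "1", "1", "1")
  )
}

test_that("catalog parsing groups targets per drug with a recount oracle", {
  res <- parse_drug_catalog(make_catalog())
  # row 4 is a human annotation without an accession -> reject
  expect_equal(res$rejects$reason, "human annotation without accession")
  # group-by oracle with base table()
  expected <- table(make_catalog()$drug_name[-4])
  got <- res$drugs$n_targets[match(names(expected), res$drugs$drug_name)]
  expect_equal(got, as.integer(expected))

  empty <- parse_drug_catalog(make_catalog()[0, ])
  expect_equal(nrow(empty$targets), 0)

  bad <- make_catalog()
  bad$molecule_type[2] <- "biologic"
  expect_error(parse_drug_catalog(bad), "conflicting molecule_type")
})

test_that("the accession index covers human annotations only", {
  res <- parse_drug_catalog(make_catalog())
  idx <- index_by_accession(res$targets)
  expect_setequal(names(idx), c("P1", "P2", "P3"))
  # a drug with two targets appears under both keys
  expect_identical(idx$P1, "DrugA")
  expect_identical(idx$P2, "DrugA")
  # microbial-only annotations contribute no keys
  expect_false("M1" %in% names(idx))
  # recount oracle
  human <- make_catalog()[-c(4, 5), ]
  expect_equal(sort(names(idx)), sort(unique(human$accession)))
})

trial_fixture <- function() {
  catalog <- tibble::tibble(
    drug_name = c("mino", "arte", "plain"),
    molecule_type = "small molecule", moa = "x",
    accession = c("M1", "M2", "P9"),
    chembl_target_id = c("C1", "C2", "C9"),
    class_l1 = "enzyme", class_l2 = NA, class_l3 = NA,
    organism = c("microbial", "microbial", "human"),
    complex_id = NA, atc = "X", approval_year = "2000", therapeutic_rank = "1"
  )
  trial <- load_trial_list(tibble::tibble(
    drug_name = c("mino", "arte", "plain"), n_trial_listings = c("2", "1", "3")
  ))
  targets <- parse_drug_catalog(catalog)$targets
  attach_trial_targets(trial, targets)
}

test_that("microbial remapping appends human targets or excludes", {
  moa <- tibble::tibble(drug_name = "mino", accession = "P7",
                        chembl_target_id = "C7", class_l1 = "enzyme",
                        class_l2 = NA, class_l3 = NA, therapeutic_rank = "1")
  out <- remap_microbial(trial_fixture(), moa)
  # present in the MOA table: human target appended, not excluded
  mino <- out[out$drug_name == "mino", ]
  expect_false(mino$excluded)
  expect_true("P7" %in% mino$targets[[1]]$accession)
  # absent from the MOA table: excluded with the defined reason
  arte <- out[out$drug_name == "arte", ]
  expect_true(arte$excluded)
  expect_equal(arte$exclusion_reason, "no human target")
  # a drug already carrying human targets is unchanged
  plain <- out[out$drug_name == "plain", ]
  expect_false(plain$excluded)
  expect_identical(plain$targets[[1]], trial_fixture()$targets[[3]])
  # idempotence
  out2 <- remap_microbial(out, moa)
  expect_identical(out2$excluded, out$excluded)
  expect_identical(out2$targets, out$targets)
})

test_that("subunit consolidation collapses complexes and keeps order", {
  subunits <- make_targets(paste0("P", 5:1), "ion channel", 1)
  subunits$complex_id <- "CPLX1"
  one <- consolidate_subunits(subunits)
  expect_equal(nrow(one), 1)
  expect_equal(one$accession, "P1")        # lexicographically smallest
  expect_equal(one$n_subunits, 5)
  expect_identical(one$subunit_accessions[[1]], paste0("P", 1:5))

  distinct <- make_targets(c("P1", "P2"), c("enzyme", "ion channel"), 1:2)
  expect_equal(nrow(consolidate_subunits(distinct)), 2)

  # group-by oracle on a mixed list, and first-appearance order
  mixed <- make_targets(c("P3", "P4", "P1", "P2"),
                        c("enzyme", "enzyme", "ion channel", "ion channel"),
                        c(1, 1, 2, 2))
  mixed$complex_id <- c("A", "A", NA, NA)
  got <- consolidate_subunits(mixed)
  expect_equal(nrow(got), 3)  # {P3,P4} collapse; P1, P2 distinct chembl ids
  expect_identical(got$accession, c("P3", "P1", "P2"))
  expect_lte(nrow(got), nrow(mixed))
})

test_that("entry selection follows the stated rule order", {
  # single target: kept with the "sole target" reason
  sole <- curate_multi_target(make_targets("P1", "enzyme", 1), character(0))
  expect_equal(sole$selection_reason, "sole target")

  # one risk-gene target among four is ranked first despite a worse rank
  four <- make_targets(paste0("P", 1:4),
                       c("enzyme", "enzyme", "ion channel", "transporter"),
                       c(1, 2, 3, 4))
  cur <- curate_multi_target(four, risk_accessions = "P3")
  expect_equal(cur$accession[1], "P3")
  expect_equal(cur$selection_reason[1], "risk gene match")
  # second entry prefers a different level-1 class (not another ion channel)
  expect_equal(cur$accession[2], "P1")
  expect_lte(nrow(cur), 2)

  # excluded drugs come back empty
  expect_equal(nrow(curate_multi_target(four, "P3", excluded = TRUE)), 0)
})

test_that("curation equals exhaustive rule application on random drugs", {
  set.seed(99)
  classes <- protein_class_vocabulary()
  for (i in 1:20) {
    k <- sample(2:6, 1)
    tg <- make_targets(sample(sprintf("P%02d", 1:40), k),
                       sample(classes, k, replace = TRUE),
                       sample(c(1:4, NA), k, replace = TRUE))
    risk <- sample(tg$accession, sample(0:2, 1))
    got <- curate_multi_target(tg, risk)$accession
    expect_identical(got, oracle_curate(tg, risk), label = paste("drug", i))
    # deterministic and invariant to input target order
    shuffled <- tg[sample.int(k), ]
    expect_identical(curate_multi_target(shuffled, risk)$accession, got)
  }
})

test_that("drug-per-target counts conserve the curated entries", {
  expect_equal(nrow(drugs_per_target(
    tibble::tibble(drug_name = character(0), accession = character(0),
                   chembl_target_id = character(0),
                   class_l1 = character(0)))), 0)
  curated <- tibble::tibble(
    drug_name = c("d1", "d1", "d2", "d3"),
    accession = c("P1", "P2", "P1", "P1"),
    chembl_target_id = "C", class_l1 = "enzyme"
  )
  dpt <- drugs_per_target(curated)
  expect_equal(sum(dpt$n_drugs), nrow(curated))
  expect_equal(dpt$n_drugs[dpt$accession == "P1"], 3)
})
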