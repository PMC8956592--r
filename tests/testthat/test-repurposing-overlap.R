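# cross-referencing: druggable set, evidence partition, repurposing status,
# class distributions and their comparison

test_that("druggable genes are the catalog-index intersection", {
  ents <- tiny_entities()
  # disjoint inputs give the empty pair
  none <- druggable_genes(ents, structure(list(), names = character(0)))
  expect_equal(nrow(none$genes), 0)
  expect_length(none$drugs, 0)

  idx <- list(P00001 = c("d1", "d2"), P00003 = "d2", ZZZ = "d9")
  dg <- druggable_genes(ents, idx)
  expect_setequal(dg$genes$accession, c("P00001", "P00003"))
  expect_setequal(dg$drugs, c("d1", "d2"))
  expect_equal(dg$genes$n_drugs[dg$genes$accession == "P00001"], 2)
})

test_that("the evidence partition is disjoint and covers the input", {
  ents <- tiny_entities()
  part <- partition_by_evidence(ents)
  expect_true("P00002" %in% part$sets$multi_class)  # common + rare
  expect_true("P00001" %in% part$sets$unique_common)
  # disjointness and coverage, also under random subsets
  set.seed(5)
  for (i in 1:10) {
    sub <- ents[sample.int(nrow(ents), sample(nrow(ents), 1)), ]
    p <- partition_by_evidence(sub)
    all_members <- unname(unlist(p$sets))
    expect_equal(sort(all_members), sort(sub$accession))
    expect_equal(anyDuplicated(all_members), 0)
    expect_equal(sum(p$table$n), nrow(sub))
  }
})

test_that("repurposing status conserves the druggable set", {
  accs <- c("P1", "P2", "P3")
  all_clin <- repurposing_status(accs, character(0))
  expect_true(all(all_clin$status == "T_clinical"))
  st <- repurposing_status(accs, c("P2", "P9"))
  expect_equal(sum(st$status == "T_clinical_repurposing"), 1)
  expect_equal(nrow(st), length(accs))
  # supported trial targets are a subset of both inputs
  sup <- genetically_supported_trial_targets(c("P2", "P9"), accs)
  expect_identical(sup, "P2")
})

test_that("class distributions normalise and handle boundaries", {
  one <- genetic_distribution(tibble::tibble(
    accession = "P1", class_l1 = "ion channel", class_l2 = NA, class_l3 = NA))
  expect_equal(one$proportion, 1)

  empty <- trial_distribution(tibble::tibble(
    drug_name = character(0), accession = character(0),
    class_l1 = character(0), class_l2 = character(0)))
  expect_equal(nrow(empty), 0)

  # proportions sum to 1 within 0.01 for random class assignments
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    d <- genetic_distribution(tibble::tibble(
      accession = sprintf("P%02d", 1:n),
      class_l1 = sample(protein_class_vocabulary(), n, replace = TRUE),
      class_l2 = NA_character_, class_l3 = NA_character_))
    expect_equal(sum(d$proportion), 1, tolerance = 0.01)
  }
})

test_that("7TM receptors are broken out of the membrane receptor class", {
  lab <- class_label(c("membrane receptor", "membrane receptor", "enzyme"),
                     c("7TM", "catalytic receptor", NA))
  expect_identical(lab, c("7TM", "membrane receptor", "enzyme"))
})

test_that("conflicting class paths resolve to the most frequent path", {
  targets <- tibble::tibble(
    drug_name = c("d1", "d2", "d3"),
    accession = "P1", chembl_target_id = "C1",
    class_l1 = c("enzyme", "enzyme", "ion channel"),
    class_l2 = NA_character_, class_l3 = NA_character_,
    organism = "human", complex_id = NA_character_,
    therapeutic_rank = 1L
  )
  expect_message(res <- gene_class_assignments("P1", targets), "conflict")
  expect_equal(res$class_l1, "enzyme")
  expect_true(res$class_conflict)
})

test_that("distribution comparison is elementwise with zero imputation", {
  a <- genetic_distribution(tibble::tibble(
    accession = c("P1", "P2"), class_l1 = c("enzyme", "ion channel"),
    class_l2 = NA, class_l3 = NA))
  expect_silent(cmp_same <- compare_distributions(a, a))
  expect_true(all(cmp_same$difference == 0))

  b <- trial_distribution(tibble::tibble(
    drug_name = c("d1", "d2"), accession = c("T1", "T2"),
    class_l1 = c("enzyme", "transporter"), class_l2 = NA))
  expect_warning(cmp <- compare_distributions(a, b), "weighting")
  # the class missing on one side is imputed as zero
  expect_equal(cmp$proportion_a[cmp$class == "transporter"], 0)
  expect_equal(cmp$proportion_b[cmp$class == "ion channel"], 0)
  expect_equal(cmp$difference,
               cmp$proportion_a - cmp$proportion_b)
  # ordered by decreasing absolute difference
  expect_true(!is.unsorted(rev(abs(cmp$difference))))
})
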