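test_that("classification follows the purity-cutoff rule with reclassify precedence", {
  prof <- generate_cell_profiles(small_cfg())$profiles
  cfg <- qc_config(prof, purity_cutoff = 0.7, exempt_cell_types = "nRBC")
  est <- c(A = 0.95, B = 0.03, C = 0.01, D = 0.01)
  expect_equal(classify_sample(est, "A", cfg)$action, "keep")
  # below cutoff, nothing else dominant: removed
  est2 <- c(A = 0.55, B = 0.05, C = 0.05, D = 0.05)
  expect_equal(classify_sample(est2, "A", cfg)$action, "remove")
  # a different type above cutoff wins over removal
  est3 <- c(A = 0.15, B = 0.78, C = 0.02, D = 0.01)
  d3 <- classify_sample(est3, "A", cfg)
  expect_equal(d3$action, "reclassify")
  expect_equal(d3$new_type, "B")
  # the strict variant removes instead of relabeling
  cfg_strict <- qc_config(prof, purity_cutoff = 0.7, reclassify = FALSE)
  expect_equal(classify_sample(est3, "A", cfg_strict)$action, "remove")
  # boundary: exactly at the cutoff is kept (removal is strict <)
  est4 <- c(A = 0.7, B = 0.1, C = 0.1, D = 0.1)
  expect_equal(classify_sample(est4, "A", cfg)$action, "keep")
  # exempt types bypass everything
  expect_equal(classify_sample(est2, "nRBC", cfg)$action, "exempt")
  # unknown non-exempt expected type is an error
  expect_error(classify_sample(est, "Treg", cfg), "absent from the QC reference")
  # pure function: repeated calls identical
  expect_identical(classify_sample(est3, "A", cfg), classify_sample(est3, "A", cfg))
})

test_that("at a cutoff above 0.5 at most one cell type can trigger reclassification", {
  expect_warning(qc_config(generate_cell_profiles(small_cfg())$profiles,
                           purity_cutoff = 0.4), "more than one")
})

test_that("planted contaminated and mislabeled samples are filtered exactly", {
  prof <- generate_cell_profiles(small_cfg(seed = 11))$profiles
  plan <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    true_type = c("A", "B", "C", "D", "A", "B", "C", "D", "A", "B"),
    label     = c("A", "B", "C", "D", "A", "B", "C", "A", "B", "B"),
    purity    = c(1, 1, 1, 0.6, 0.6, 0.6, 0.6, 0.9, 0.9, 0.6),
    contaminant = c("B", "C", "D", "A", "B", "C", "D", "B", "C", "A"),
    stringsAsFactors = FALSE)
  # s4-s7, s10: purity 0.6 -> remove; s8, s9: 0.9 of a different type -> reclassify
  ref <- planted_reference(prof, plan)
  out <- filter_reference(ref$betas, ref$sheet,
                          qc_config(prof, purity_cutoff = 0.7))
  expect_equal(out$decisions$action,
               c("keep", "keep", "keep", "remove", "remove", "remove",
                 "remove", "reclassify", "reclassify", "remove"))
  expect_equal(out$decisions$new_type[8:9], c("D", "A"))
  expect_equal(out$sheet$cell_type[out$sheet$sample_id %in% c("s08", "s09")],
               c("D", "A"))
  expect_equal(ncol(out$betas), 5)
  # estimates recorded in the audit trail are the projection output
  expect_true(all(paste0("est_", colnames(prof)) %in% names(out$decisions)))
  expect_equal(out$decisions$est_A[1], 1, tolerance = 1e-6)
})

test_that("exempt nRBC-labeled samples are never removed or relabeled", {
  cfg <- small_cfg(cell_types = c("A", "B", "C", "nRBC"), seed = 21)
  prof <- generate_cell_profiles(cfg)$profiles
  qc_ref <- prof[, c("A", "B", "C")]  # adult-like reference lacks nRBC
  plan <- data.frame(sample_id = c("n1", "n2"), true_type = "nRBC",
                     label = "nRBC", purity = c(1, 0.5), contaminant = "A",
                     stringsAsFactors = FALSE)
  ref <- planted_reference(prof, plan)
  out <- filter_reference(ref$betas, ref$sheet, qc_config(qc_ref))
  expect_equal(out$decisions$action, c("exempt", "exempt"))
  expect_equal(ncol(out$betas), 2)
})

test_that("projection estimates reflect the planted composition", {
  prof <- generate_cell_profiles(small_cfg(seed = 31))$profiles
  cfg <- qc_config(prof)
  y <- 0.6 * prof[, "C"] + 0.4 * prof[, "D"]
  est <- project_composition(y, cfg)
  expect_equal(unname(est[c("C", "D")]), c(0.6, 0.4), tolerance = 1e-6)
  expect_true(all(est >= -1e-10) && sum(est) <= 1 + 1e-8)
  expect_error(project_composition(y[1:3], cfg), "fewer probes")
})

test_that("warning when a cell type loses all its samples", {
  prof <- generate_cell_profiles(small_cfg(seed = 41))$profiles
  plan <- data.frame(sample_id = c("a1", "b1"), true_type = c("A", "B"),
                     label = c("A", "B"), purity = c(1, 0.5),
                     contaminant = c("B", "C"), stringsAsFactors = FALSE)
  ref <- planted_reference(prof, plan)
  expect_warning(filter_reference(ref$betas, ref$sheet, qc_config(prof)),
                 "all samples removed.*B")
})

test_that("combining references pools, averages and guards sample identity", {
  cfg1 <- small_cfg(seed = 51, ref_noise_sd = 0.2)
  prof <- generate_cell_profiles(cfg1)$profiles
  ss1 <- generate_sorted_samples(prof, cfg1, dataset = "d1")
  cfg2 <- small_cfg(seed = 52, ref_noise_sd = 0.2)
  ss2 <- generate_sorted_samples(prof, cfg2, dataset = "d2")
  comb <- combine_references(list(ss1[c("betas", "sheet")],
                                  ss2[c("betas", "sheet")]))
  expect_equal(ncol(comb$betas), ncol(ss1$betas) + ncol(ss2$betas))
  expect_setequal(unique(comb$sheet$dataset), c("d1", "d2"))
  # single reference: the signature matrix is its own per-type mean
  one <- combine_references(list(ss1[c("betas", "sheet")]))
  for (k in colnames(prof)) {
    own <- rowMeans(ss1$betas[rownames(one$reference),
                              ss1$sheet$cell_type == k])
    expect_equal(unname(one$reference[, k]), unname(own), tolerance = 1e-12)
  }
  # pooling two noisy references lands closer to the generating truth
  err1 <- mean(abs(one$reference - prof[rownames(one$reference), ]))
  err12 <- mean(abs(comb$reference - prof[rownames(comb$reference), ]))
  expect_lt(err12, err1)
  # duplicate sample IDs across datasets are refused
  ss_dup <- ss2
  ss_dup$betas <- ss1$betas
  ss_dup$sheet <- ss1$sheet
  expect_error(combine_references(list(ss1[c("betas", "sheet")],
                                       ss_dup[c("betas", "sheet")])),
               "duplicate sample IDs")
})
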