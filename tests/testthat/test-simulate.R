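test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  a <- generate_cell_profiles(cfg)
  b <- generate_cell_profiles(cfg)
  expect_identical(a, b)
  sa <- generate_sorted_samples(a$profiles, cfg)
  sb <- generate_sorted_samples(a$profiles, cfg)
  expect_identical(sa, sb)
  ma <- generate_mixtures(a$profiles, cfg)
  expect_identical(ma, generate_mixtures(a$profiles, cfg))
  pa <- split_platforms(a$profiles, cfg)
  expect_identical(pa, split_platforms(a$profiles, cfg))
  # different seeds change the draw
  cfg2 <- small_cfg(seed = 43)
  expect_false(identical(generate_cell_profiles(cfg2), a))
})

test_that("planted markers match the recorded truth map exactly", {
  cfg <- small_cfg(n_probes = 300, cell_types = c("A", "B", "C"),
                   n_dmr_per_type = 20, dmr_effect = 0.4)
  out <- generate_cell_profiles(cfg)
  prof <- out$profiles
  map <- out$dmr_map
  expect_equal(nrow(map), 60)
  expect_equal(anyDuplicated(map$probe_id), 0)
  # marker probes: target column differs from all others by exactly the effect
  for (i in seq_len(nrow(map))) {
    row <- prof[map$probe_id[i], ]
    k <- map$cell_type[i]
    delta <- row[[k]] - row[setdiff(names(row), k)]
    expect_equal(unname(delta),
                 rep(if (map$direction[i] == "hyper") 0.4 else -0.4, 2),
                 tolerance = 1e-12)
  }
  # non-marker probes are identical across cell types
  null_probes <- setdiff(rownames(prof), map$probe_id)
  expect_equal(max(apply(prof[null_probes, ], 1, function(r) diff(range(r)))), 0)
  # no-signal limit: all columns identical
  cfg0 <- small_cfg(n_dmr_per_type = 0)
  p0 <- generate_cell_profiles(cfg0)$profiles
  expect_equal(max(abs(p0 - p0[, 1])), 0)
  expect_null(generate_cell_profiles(cfg0)$dmr_map)
  # impossible request is a config error
  expect_error(small_cfg(n_probes = 50, n_dmr_per_type = 20), "exceeds n_probes")
})

test_that("pure noiseless sorted samples reproduce their reference column", {
  cfg <- small_cfg(purity = 1, ref_noise_sd = 0, n_ref_samples_per_type = 2)
  prof <- generate_cell_profiles(cfg)$profiles
  ss <- generate_sorted_samples(prof, cfg)
  for (j in seq_len(ncol(ss$betas)))
    expect_equal(unname(ss$betas[, j]),
                 unname(prof[, ss$sheet$cell_type[j]]), tolerance = 1e-12)
})

test_that("contamination and mislabeling are planted as configured", {
  cfg <- small_cfg(contaminated_fraction = 0.25, contaminated_purity = 0.6,
                   mislabel_fraction = 0.125, n_ref_samples_per_type = 8)
  prof <- generate_cell_profiles(cfg)$profiles
  ss <- generate_sorted_samples(prof, cfg)
  tab <- table(ss$truth$status)
  expect_equal(unname(tab[["contaminated"]]), 4 * 2)
  expect_equal(unname(tab[["mislabeled"]]), 4 * 1)
  expect_true(all(ss$truth$purity[ss$truth$status == "contaminated"] == 0.6))
  mis <- ss$truth[ss$truth$status == "mislabeled", ]
  expect_true(all(mis$true_type != mis$labeled_type))
  # labels in the sheet are the intended (possibly wrong) types
  expect_identical(ss$sheet$cell_type,
                   ss$truth$labeled_type[match(ss$sheet$sample_id,
                                               ss$truth$sample_id)])
})

test_that("mixtures carry exact Dirichlet truth and admit exact recovery", {
  cfg <- small_cfg(mixture_noise_sd = 0, n_mixtures = 10)
  out <- generate_cell_profiles(cfg)
  mx <- generate_mixtures(out$profiles, cfg)
  expect_equal(unname(rowSums(mx$proportions)), rep(1, 10), tolerance = 1e-12)
  # noise-free: constrained projection over all probes recovers truth
  for (j in 1:10) {
    w <- solve_constrained_projection(mx$betas[, j], out$profiles)$w
    expect_lt(max(abs(w - mx$proportions[j, ])), 1e-6)
  }
  # vertex of the simplex: concentrated alpha reproduces one column
  cfgv <- small_cfg(mixture_noise_sd = 0, n_mixtures = 3,
                    mixture_alpha = c(5000, 0.001, 0.001, 0.001))
  mv <- generate_mixtures(out$profiles, cfgv)
  expect_lt(max(abs(mv$betas[, 1] - out$profiles[, 1])), 0.01)
})

test_that("Dirichlet draws average to alpha over many mixtures", {
  cfg <- small_cfg(n_mixtures = 4000, mixture_noise_sd = 0)
  prof <- generate_cell_profiles(cfg)$profiles
  mx <- generate_mixtures(prof, cfg)
  expected <- cfg$mixture_alpha / sum(cfg$mixture_alpha)
  expect_lt(max(abs(colMeans(mx$proportions) - expected)), 0.015)
})

test_that("platform split honours the overlap fraction", {
  cfg <- small_cfg(platform_overlap_fraction = 0.5, n_probes = 100,
                   n_dmr_per_type = 5)
  prof <- generate_cell_profiles(cfg)$profiles
  sp <- split_platforms(prof, cfg)
  common <- intersect(rownames(sp$a), rownames(sp$b))
  expect_equal(length(common), 50)
  expect_equal(nrow(intersect_probes(list(sp$a, sp$b))[[1]]), 50)
  # full overlap: identical probe sets
  cfg1 <- small_cfg(platform_overlap_fraction = 1)
  prof1 <- generate_cell_profiles(cfg1)$profiles
  sp1 <- split_platforms(prof1, cfg1)
  expect_identical(rownames(sp1$a), rownames(sp1$b))
})
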