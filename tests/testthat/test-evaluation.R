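prop_mat <- function(v, types = c("A", "B"), ids = NULL) {
  m <- matrix(v, ncol = length(types),
              dimnames = list(ids %||% sprintf("s%d", seq_len(length(v) / length(types))),
                              types))
  m
}

test_that("perfect agreement scores R^2 = 1 and RMSE = 0", {
  truth <- prop_mat(c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6))
  rep <- evaluate_proportions(truth, truth)
  expect_equal(rep$r_squared, c(1, 1))
  expect_equal(rep$rmse, c(0, 0), ignore_attr = TRUE)
  expect_equal(attr(rep, "mean_rmse"), 0)
})

test_that("a constant bias dissociates R^2 from RMSE", {
  truth <- prop_mat(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.4, 0.3, 0.2))
  est <- truth + 0.05
  rep <- evaluate_proportions(est, truth, scale = "percent")
  expect_equal(rep$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(rep$rmse, c(5, 5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rep$bias, c(5, 5), tolerance = 1e-10, ignore_attr = TRUE)
  # the identity-line variant does punish the bias
  rep_id <- evaluate_proportions(est, truth, r2_method = "identity")
  expect_true(all(rep_id$r_squared < 1))
})

test_that("the four-sample toy matches hand-computed Pearson r^2 and RMSE", {
  truth <- prop_mat(c(0.10, 0.20, 0.30, 0.40), types = "A")
  est <- prop_mat(c(0.12, 0.18, 0.33, 0.37), types = "A")
  rep <- evaluate_proportions(est, truth, scale = "percent")
  # hand computation from the sum formulas
  x <- c(12, 18, 33, 37); y <- c(10, 20, 30, 40)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2 <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep$r_squared, r2, tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(mean((x - y)^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("R^2 is affine-invariant while RMSE is not", {
  set.seed(61)
  truth <- prop_mat(runif(20, 0.1, 0.4), types = c("A", "B"))
  est <- truth + matrix(rnorm(20, 0, 0.02), 10)
  r0 <- evaluate_proportions(est, truth)
  r1 <- evaluate_proportions(0.5 * est + 0.1, truth)
  expect_equal(r1$r_squared, r0$r_squared, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(r1$rmse, r0$rmse)))
})

test_that("evaluation is invariant to sample and column permutations", {
  set.seed(62)
  truth <- prop_mat(runif(30), types = c("A", "B", "C"))
  est <- pmin(pmax(truth + rnorm(30, 0, 0.05), 0), 1)
  r0 <- evaluate_proportions(est, truth)
  perm <- sample(nrow(truth))
  r1 <- evaluate_proportions(est[perm, ], truth)
  expect_equal(as.data.frame(r0), as.data.frame(r1))
  r2 <- evaluate_proportions(est[, c(3, 1, 2)], truth[, c(3, 1, 2)])
  expect_equal(r2[match(r0$cell_type, r2$cell_type), ], r0, ignore_attr = TRUE)
})

test_that("degenerate truth flags undefined correlation instead of guessing", {
  truth <- prop_mat(rep(0.25, 8))
  est <- prop_mat(runif(8))
  rep <- evaluate_proportions(est, truth)
  expect_true(all(rep$r2_undefined))
  expect_true(all(is.na(rep$r_squared)))
  expect_error(evaluate_proportions(est[1:2, ], truth[1:2, ]), "fewer than 3")
})

test_that("signed errors and their quartiles track the planted offset", {
  truth <- prop_mat(seq(0.1, 0.8, length.out = 8))
  est <- truth + 0.03
  d <- absolute_errors(est, truth)
  expect_equal(unname(as.vector(d)), rep(0.03, 8), tolerance = 1e-12)
  expect_equal(unname(attr(d, "quartiles")["50%", ]), c(0.03, 0.03),
               tolerance = 1e-12)
  expect_equal(unname(as.vector(absolute_errors(truth, truth))), rep(0, 8))
})

test_that("Bland-Altman statistics follow the textbook definition", {
  a <- prop_mat(c(0.2, 0.3, 0.4, 0.5, 0.3, 0.2, 0.4, 0.1))
  expect_equal(bland_altman(a, a)$mean_difference, c(0, 0), ignore_attr = TRUE)
  expect_equal(bland_altman(a, a)$sd_difference, c(0, 0), ignore_attr = TRUE)
  b <- a - 0.1
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_difference, c(0.1, 0.1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ba$loa_lower, ba$loa_upper, tolerance = 1e-12)
  # against truth, the mean difference equals the mean signed error
  set.seed(63)
  est <- prop_mat(runif(40), types = c("A", "B"))
  truth <- prop_mat(runif(40), types = c("A", "B"))
  ba2 <- bland_altman(est, truth)
  expect_equal(ba2$mean_difference, colMeans(absolute_errors(est, truth)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # ~95% of differences inside the limits at large n
  set.seed(64)
  big_a <- prop_mat(runif(2000, 0.2, 0.6), types = "A")
  big_b <- pmin(pmax(big_a + rnorm(2000, 0, 0.03), 0), 1)
  ba3 <- bland_altman(big_a, big_b)
  p <- attr(ba3, "pairs")
  inside <- mean(p$difference > ba3$loa_lower & p$difference < ba3$loa_upper)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("leave-one-out produces one report per left-out reference plus baseline", {
  cfg <- small_cfg(seed = 71, ref_noise_sd = 0.1)
  prof <- generate_cell_profiles(cfg)$profiles
  refs <- list(r1 = generate_sorted_samples(prof, small_cfg(seed = 71),
                                            dataset = "r1")[c("betas", "sheet")],
               r2 = generate_sorted_samples(prof, small_cfg(seed = 72),
                                            dataset = "r2")[c("betas", "sheet")])
  mx <- generate_mixtures(prof, small_cfg(seed = 73, n_mixtures = 10,
                                          mixture_noise_sd = 0.01))
  out <- leave_one_out(refs, mx$betas, mx$proportions,
                       select_fun = function(b, s)
                         select_automatic(b, s, n_per_type = 20))
  expect_named(out, c("all", "without_r1", "without_r2"))
  # two equivalent references: leaving either out changes little
  expect_equal(attr(out$without_r1, "mean_rmse"),
               attr(out$without_r2, "mean_rmse"), tolerance = 0.5)
  expect_length(attr(out$all, "missing_cell_types"), 0)
})

test_that("losing the only reference for a cell type is flagged and degrades it", {
  cfg_full <- small_cfg(seed = 81)
  prof <- generate_cell_profiles(cfg_full)$profiles
  r1 <- generate_sorted_samples(prof, small_cfg(seed = 81), dataset = "r1")
  r2 <- generate_sorted_samples(prof[, c("A", "B", "C")],
                                small_cfg(seed = 82,
                                          cell_types = c("A", "B", "C")),
                                dataset = "r2")
  mx <- generate_mixtures(prof, small_cfg(seed = 83, n_mixtures = 10,
                                          mixture_noise_sd = 0.01))
  out <- leave_one_out(list(r1 = r1[c("betas", "sheet")],
                            r2 = r2[c("betas", "sheet")]),
                       mx$betas, mx$proportions,
                       select_fun = function(b, s)
                         select_automatic(b, s, n_per_type = 20))
  # r1 is the sole carrier of cell type D
  expect_identical(attr(out$without_r1, "missing_cell_types"), "D")
  base_rmse <- attr(out$all, "mean_rmse")
  expect_gt(attr(out$without_r1, "mean_rmse"), base_rmse)
})
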