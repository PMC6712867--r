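# IDOL-style library optimisation: a candidate pool of direction-extreme
# one-vs-rest t probes is searched, per requested library size, by a seeded
# stochastic subset search scored by deconvolving training mixtures with
# known proportions (mean per-cell-type R^2, ties broken by mean RMSE).

#' IDOL candidate probe pool
#'
#' Per cell type, the `m_top` probes with the largest and the `m_top` with
#' the smallest one-vs-rest Welch t statistics (ties broken lexicographically
#' by probe ID), unioned and deduplicated; pool size is therefore at most
#' `2 * m_top * K`.
#'
#' @param betas sorted-reference beta matrix.
#' @param sheet sample sheet for `betas`.
#' @param m_top probes taken per direction per cell type (default 150).
#' @param stats optional precomputed [per_probe_statistics()].
#' @return an L-DMR library data.frame (the candidate pool).
#' @export
idol_candidate_set <- function(betas, sheet, m_top = 150, stats = NULL) {
  if (is.null(stats)) stats <- per_probe_statistics(betas, sheet)
  types <- stats$cell_types
  pick <- list()
  for (k in types) {
    tk <- stats$t[, k]
    d <- data.frame(probe_id = rownames(stats$t), t = tk, p = stats$t_p[, k],
                    stringsAsFactors = FALSE)
    top <- utils::head(d[order(-d$t, d$probe_id), , drop = FALSE], m_top)
    bot <- utils::head(d[order(d$t, d$probe_id), , drop = FALSE], m_top)
    top$direction <- "hyper"
    bot$direction <- "hypo"
    sel <- rbind(top, bot)
    pick[[k]] <- data.frame(probe_id = sel$probe_id, target_cell_type = k,
                            direction = sel$direction, statistic = sel$t,
                            p_value = sel$p, stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, c(pick, list(make.row.names = FALSE)))
  lib <- lib[order(-abs(lib$statistic), lib$probe_id), , drop = FALSE]
  lib <- lib[!duplicated(lib$probe_id), , drop = FALSE]
  lib <- lib[order(lib$target_cell_type, -abs(lib$statistic), lib$probe_id), ,
             drop = FALSE]
  rownames(lib) <- NULL
  validate_library(lib)
}

# Score a probe subset: deconvolve the mixtures over it and compare to truth.
# Returns c(r2 = mean per-type R^2, rmse = mean per-type RMSE in percent).
score_subset <- function(probes, reference, mix_betas, mix_truth, tol = 1e-6) {
  fit <- deconvolve(mix_betas, reference, probes, tol = tol)
  est <- coef(fit)
  truth <- mix_truth[rownames(est), colnames(est), drop = FALSE]
  d <- est - truth
  rmse <- sqrt(colMeans(d^2)) * 100
  r2 <- vapply(seq_len(ncol(est)), function(k) {
    if (stats::sd(truth[, k]) == 0 || stats::sd(est[, k]) == 0) return(0)
    stats::cor(est[, k], truth[, k])^2
  }, numeric(1))
  c(r2 = mean(r2), rmse = mean(rmse))
}

# Lexicographic comparison with a minimum meaningful improvement: tiny gains
# on a small training set are noise, and chasing them swaps informative
# probes for chance-aligned ones.
score_better <- function(a, b, margin = 0) {
  if (is.null(b)) return(TRUE)
  if (a["r2"] > b["r2"] + margin) return(TRUE)
  if (a["r2"] < b["r2"] - margin) return(FALSE)
  a["rmse"] < b["rmse"] - margin * 100
}

#' IDOL-style iterative library optimisation
#'
#' For each requested library size L, runs a seeded stochastic search over
#' size-L subsets of the candidate pool, scoring each subset by deconvolving
#' the training mixtures and comparing the estimates to the known training
#' proportions (objective: mean per-cell-type squared Pearson correlation,
#' ties broken by mean RMSE). The search starts from the per-cell-type
#' balanced top-|t| subset of the pool and proposes weighted random swap
#' moves: per-candidate inclusion weights (initialised proportional to |t|)
#' are multiplicatively up-weighted (x1.1) for members of subsets that beat
#' the incumbent and down-weighted (x0.95) for members of subsets scoring in
#' the worst decile seen so far. The best subset per size is then scored on
#' the held-out test mixtures; the returned library is the size/subset with
#' the highest mean test R^2 (lowest test RMSE on ties).
#'
#' @param candidates candidate pool from [idol_candidate_set()].
#' @param reference probes x K signature matrix used for the CP/QP scoring
#'   fits.
#' @param train_betas,train_truth training mixtures and their true
#'   proportions (samples x K).
#' @param test_betas,test_truth held-out mixtures and truth.
#' @param library_sizes integer vector of sizes to try (default 150 to 700
#'   in steps of 50, cut to the pool size).
#' @param n_iterations search iterations per size (default 500).
#' @param seed integer seed for the stochastic search.
#' @param swap_fraction fraction of the subset replaced per proposal (at
#'   least one probe). Small values make the hill climb selective: a probe
#'   only enters if its own swap improves the training objective.
#' @param min_improvement minimum gain in mean training R^2 for a proposal
#'   to replace the incumbent (guards against overfitting the small training
#'   set with chance-aligned probes).
#' @return object of class `idol_result`: `best_library` (library
#'   data.frame), `best_size`, `per_size` (data.frame of train/test mean R^2
#'   and RMSE per size), `trace` (per size, incumbent objective by
#'   iteration).
#' @export
idol_optimize <- function(candidates, reference, train_betas, train_truth,
                          test_betas, test_truth,
                          library_sizes = seq(150, 700, by = 50),
                          n_iterations = 500, seed = 1L,
                          swap_fraction = 0.01, min_improvement = 5e-4) {
  candidates <- validate_library(candidates)
  pool <- candidates$probe_id
  npool <- length(pool)
  library_sizes <- sort(unique(as.integer(library_sizes)))
  if (any(library_sizes < ncol(reference)))
    stop("library sizes below the number of cell types")
  if (max(library_sizes) > npool)
    stop("candidate pool (", npool, ") smaller than largest requested size (",
         max(library_sizes), ")")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (anyNA(train_truth) || anyNA(test_truth)) stop("truth contains NA")
  const_truth <- all(apply(train_truth, 2L, stats::sd) == 0)
  if (const_truth)
    warning("constant training proportions: R^2 undefined, scoring by RMSE alone")

  # balanced per-type |t| ranking used for the initial subset and weights
  ord <- order(-abs(candidates$statistic), candidates$probe_id)
  by_type <- split(ord, candidates$target_cell_type[ord])
  balanced <- integer(0)
  for (r in seq_len(max(lengths(by_type))))
    for (tt in names(by_type))
      if (r <= length(by_type[[tt]])) balanced <- c(balanced, by_type[[tt]][r])

  per_size <- list()
  traces <- list()
  best_by_size <- list()
  for (L in library_sizes) {
    search_seed <- (seed %% 100000L) * 7919L + L
    res <- with_seed(search_seed, {
      # inclusion weights seeded by one-vs-rest evidence (finite-capped)
      weights <- pmin(abs(candidates$statistic), 1e3) + 1e-6
      weights <- weights / sum(weights)
      incumbent <- sort(balanced[seq_len(L)])
      inc_score <- score_subset(pool[incumbent], reference,
                                train_betas, train_truth)
      if (const_truth) inc_score["r2"] <- 0
      history <- inc_score["r2"] - 1e-9 * inc_score["rmse"]
      trace <- numeric(n_iterations)
      if (L < npool) {
        n_swap <- max(1L, round(swap_fraction * L))
        for (it in seq_len(n_iterations)) {
          out_idx <- sample(incumbent, n_swap)
          avail <- setdiff(seq_len(npool), incumbent)
          in_idx <- if (length(avail) <= n_swap) avail
                    else sample(avail, n_swap, prob = weights[avail])
          proposal <- sort(c(setdiff(incumbent, out_idx), in_idx))
          sc <- score_subset(pool[proposal], reference,
                             train_betas, train_truth)
          if (const_truth) sc["r2"] <- 0
          key <- sc["r2"] - 1e-9 * sc["rmse"]
          if (score_better(sc, inc_score, margin = min_improvement)) {
            incumbent <- proposal
            inc_score <- sc
            weights[in_idx] <- weights[in_idx] * 1.1
          } else if (length(history) >= 10 &&
                     key <= stats::quantile(history, 0.1)) {
            weights[proposal] <- weights[proposal] * 0.95
          }
          weights <- weights / sum(weights)
          history <- c(history, key)
          trace[it] <- inc_score["r2"]
        }
      } else {
        trace[] <- inc_score["r2"]  # pool size == L: forced selection
      }
      list(subset = incumbent, train = inc_score, trace = trace)
    })
    test_score <- score_subset(pool[res$subset], reference,
                               test_betas, test_truth)
    per_size[[as.character(L)]] <- data.frame(
      size = L, train_r2 = unname(res$train["r2"]),
      train_rmse = unname(res$train["rmse"]),
      test_r2 = unname(test_score["r2"]),
      test_rmse = unname(test_score["rmse"]))
    best_by_size[[as.character(L)]] <- res$subset
    traces[[as.character(L)]] <- res$trace
  }
  per_size <- do.call(rbind, c(per_size, list(make.row.names = FALSE)))
  ord2 <- order(-per_size$test_r2, per_size$test_rmse)
  best_size <- per_size$size[ord2[1L]]
  best_idx <- best_by_size[[as.character(best_size)]]
  best_library <- candidates[match(pool[best_idx], candidates$probe_id), ,
                             drop = FALSE]
  rownames(best_library) <- NULL
  structure(list(best_library = best_library, best_size = best_size,
                 per_size = per_size, trace = traces, seed = seed),
            class = "idol_result")
}

#' @export
print.idol_result <- function(x, ...) {
  cat("IDOL-style library optimisation\n")
  cat(sprintf("  best size: %d probes\n", x$best_size))
  print(transform(x$per_size,
                  train_r2 = round(train_r2, 3), train_rmse = round(train_rmse, 3),
                  test_r2 = round(test_r2, 3), test_rmse = round(test_rmse, 3)))
  invisible(x)
}
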