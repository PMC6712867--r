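# Validation panel: per-cell-type R^2 and RMSE against known proportions,
# signed absolute errors, Bland-Altman agreement, and leave-one-out
# reference comparison.

align_proportions <- function(est, truth) {
  if (inherits(est, "cpqp_fit")) est <- est$proportions
  if (inherits(truth, "cpqp_fit")) truth <- truth$proportions
  samp <- intersect(rownames(est), rownames(truth))
  types <- intersect(colnames(est), colnames(truth))
  if (length(types) == 0L) stop("no cell types in common")
  mism <- length(setdiff(rownames(est), samp)) +
    length(setdiff(rownames(truth), samp))
  if (mism > 0)
    message(mism, " sample(s) without a match dropped from the comparison")
  list(est = est[samp, types, drop = FALSE],
       truth = truth[samp, types, drop = FALSE])
}

#' Evaluate proportion estimates against known truth
#'
#' Per cell type: R-squared (squared Pearson correlation between estimated
#' and true columns, or optionally an identity-line R-squared), RMSE, mean
#' absolute error and bias. R-squared and RMSE dissociate deliberately: a
#' constant bias leaves the correlation at 1 while the RMSE reports the full
#' offset — the property used to adjudicate between library-selection
#' methods.
#'
#' @param est estimated proportion matrix (samples x cell types) or a
#'   `cpqp_fit`.
#' @param truth true proportion matrix; samples matched by name (inner
#'   join, >= 3 required).
#' @param scale `"percent"` (RMSE/MAE/bias in percentage points, default) or
#'   `"fraction"`.
#' @param r2_method `"pearson"` (squared correlation, default) or
#'   `"identity"` (`1 - SS_res / SS_tot` about the truth mean; differs for
#'   biased estimators).
#' @return object of class `eval_report`: data.frame with one row per cell
#'   type (`r_squared`, `rmse`, `mean_abs_error`, `bias`, `r2_undefined`
#'   flag) and attributes `mean_r2`, `mean_rmse`, `n_samples`, `scale`.
#' @export
evaluate_proportions <- function(est, truth, scale = c("percent", "fraction"),
                                 r2_method = c("pearson", "identity")) {
  scale <- match.arg(scale)
  r2_method <- match.arg(r2_method)
  al <- align_proportions(est, truth)
  est <- al$est; truth <- al$truth
  if (nrow(est) < 3L)
    stop("fewer than 3 matched samples: correlation is meaningless")
  mult <- if (scale == "percent") 100 else 1
  d <- (est - truth) * mult
  per <- data.frame(cell_type = colnames(est),
                    r_squared = NA_real_,
                    rmse = sqrt(colMeans(d^2)),
                    mean_abs_error = colMeans(abs(d)),
                    bias = colMeans(d),
                    r2_undefined = FALSE,
                    row.names = NULL)
  for (k in seq_len(ncol(est))) {
    tv <- truth[, k]; ev <- est[, k]
    if (stats::sd(tv) == 0) {
      per$r2_undefined[k] <- TRUE
      next
    }
    per$r_squared[k] <- if (r2_method == "pearson") {
      if (stats::sd(ev) == 0) { per$r2_undefined[k] <- TRUE; NA_real_ }
      else stats::cor(ev, tv)^2
    } else 1 - sum((ev - tv)^2) / sum((tv - mean(tv))^2)
  }
  structure(per, class = c("eval_report", "data.frame"),
            mean_r2 = mean(per$r_squared, na.rm = TRUE),
            mean_rmse = mean(per$rmse),
            n_samples = nrow(est), scale = scale, r2_method = r2_method)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Deconvolution evaluation (%d samples, %s scale)\n",
              attr(x, "n_samples"), attr(x, "scale")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df)
  cat(sprintf("mean R^2 = %.4f   mean RMSE = %.4f\n",
              attr(x, "mean_r2"), attr(x, "mean_rmse")))
  invisible(x)
}

#' Signed per-sample errors
#'
#' @param est,truth proportion matrices (samples matched by name).
#' @return matrix of `est - truth` with attribute `quartiles` (per-cell-type
#'   0/25/50/75/100% quantiles of the signed error).
#' @export
absolute_errors <- function(est, truth) {
  al <- align_proportions(est, truth)
  d <- al$est - al$truth
  attr(d, "quartiles") <- apply(d, 2L, stats::quantile)
  d
}

#' Bland-Altman agreement statistics
#'
#' Per cell type: mean and SD of the per-sample differences `a - b` and the
#' conventional 1.96-SD limits of agreement; the per-sample (mean,
#' difference) pairs are kept for plotting.
#'
#' @param a,b proportion matrices from two methods (or estimate vs truth),
#'   matched by sample name; >= 2 samples.
#' @return object of class `bland_altman`: data.frame per cell type
#'   (`mean_difference`, `sd_difference`, `loa_lower`, `loa_upper`) with
#'   attribute `pairs` (long data.frame sample / cell_type / mean /
#'   difference).
#' @export
bland_altman <- function(a, b) {
  al <- align_proportions(a, b)
  if (nrow(al$est) < 2L) stop("need at least 2 matched samples")
  d <- al$est - al$truth
  m <- (al$est + al$truth) / 2
  md <- colMeans(d)
  sdd <- apply(d, 2L, stats::sd)
  out <- data.frame(cell_type = colnames(d), mean_difference = md,
                    sd_difference = sdd,
                    loa_lower = md - 1.96 * sdd,
                    loa_upper = md + 1.96 * sdd, row.names = NULL)
  pairs <- data.frame(sample_id = rep(rownames(d), ncol(d)),
                      cell_type = rep(colnames(d), each = nrow(d)),
                      mean = as.vector(m), difference = as.vector(d),
                      stringsAsFactors = FALSE)
  structure(out, class = c("bland_altman", "data.frame"), pairs = pairs)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df)
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, cell_type = NULL, ...) {
  p <- attr(x, "pairs")
  if (!is.null(cell_type)) p <- p[p$cell_type %in% cell_type, , drop = FALSE]
  graphics::plot(p$mean, p$difference, xlab = "mean of methods",
                 ylab = "difference", pch = 19, col = "grey30", ...)
  graphics::abline(h = 0, col = "red")
  for (k in unique(p$cell_type)) {
    row <- x[x$cell_type == k, ]
    graphics::abline(h = c(row$mean_difference, row$loa_lower, row$loa_upper),
                     lty = c(1, 2, 2), col = "blue")
  }
  invisible(x)
}

#' Leave-one-out reference comparison
#'
#' For each reference dataset: combine all the others, select a library,
#' deconvolve the mixtures and evaluate against truth; an all-references
#' baseline is included, so the output has `length(refs) + 1` reports.
#'
#' @param refs named list of `list(betas, sheet)` cleaned references.
#' @param mix_betas,mix_truth evaluation mixtures and their true
#'   proportions.
#' @param select_fun function `(betas, sheet) -> library` used for
#'   selection; defaults to [select_automatic()] with its defaults.
#' @param ... passed to [evaluate_proportions()].
#' @return named list of `eval_report`s (`all`, then `without_<name>`),
#'   each carrying attribute `missing_cell_types` naming truth cell types
#'   absent from that run's reference (flagged, not silently dropped).
#' @export
leave_one_out <- function(refs, mix_betas, mix_truth,
                          select_fun = NULL, ...) {
  if (length(refs) < 2L) stop("need at least two references")
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  if (is.null(select_fun))
    select_fun <- function(betas, sheet) select_automatic(betas, sheet)
  run_one <- function(subset) {
    comb <- combine_references(refs[subset])
    lib <- select_fun(comb$betas, comb$sheet)
    fit <- deconvolve(mix_betas, comb$reference, lib)
    rep <- evaluate_proportions(coef(fit), mix_truth, ...)
    attr(rep, "missing_cell_types") <-
      setdiff(colnames(mix_truth), colnames(comb$reference))
    rep
  }
  out <- list(all = run_one(seq_along(refs)))
  for (i in seq_along(refs))
    out[[paste0("without_", names(refs)[i])]] <- run_one(setdiff(seq_along(refs), i))
  out
}
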