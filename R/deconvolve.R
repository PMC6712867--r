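#' Estimate cell-type proportions by constrained projection
#'
#' The central fitting function: for each sample, solves the CP/QP problem
#' `min ||X w - y||^2` s.t. `w >= 0`, `sum(w) <= 1`, where `X` is the
#' reference signature matrix restricted to the library probes and `y` the
#' sample's beta values over those probes. Library probes missing in a sample
#' are dropped for that sample (complete-case, no imputation).
#'
#' @param samples beta matrix (probes x samples) to deconvolve.
#' @param reference probes x K matrix of cell-type mean signatures.
#' @param library L-DMR library data.frame (see [validate_library()]) or a
#'   character vector of probe IDs; `NULL` uses every shared probe.
#' @param tol KKT tolerance passed to [solve_constrained_projection()].
#' @return object of class `cpqp_fit` with components `proportions`
#'   (samples x K), `residual_norm`, `probes_dropped`, `library_size_used`
#'   per sample, `degenerate` flags, plus the reference/library used.
#'   Samples sharing fewer probes than cell types get `NA` rows and an entry
#'   in `errors`; the run continues.
#' @seealso [rescale_excluding()], [predict.cpqp_fit()]
#' @export
deconvolve <- function(samples, reference, library = NULL, tol = 1e-8) {
  samples <- validate_beta_matrix(samples)
  if (is.data.frame(reference)) reference <- as.matrix(reference)
  K <- ncol(reference)
  types <- colnames(reference)
  lib_probes <- if (is.null(library)) rownames(reference)
                else if (is.character(library)) library
                else validate_library(library)$probe_id
  miss_ref <- setdiff(lib_probes, rownames(reference))
  if (length(miss_ref))
    stop(length(miss_ref), " library probe(s) absent from the reference")
  lib_probes <- intersect(lib_probes, rownames(samples))
  lib_size <- length(lib_probes)
  if (lib_size < K)
    stop("samples share fewer library probes (", lib_size,
         ") than cell types (", K, ")")
  X <- reference[lib_probes, , drop = FALSE]
  Y <- samples[lib_probes, , drop = FALSE]

  n <- ncol(Y)
  props <- matrix(NA_real_, n, K, dimnames = list(colnames(Y), types))
  rn <- used <- rep(NA_real_, n)
  degen <- rep(FALSE, n)
  errors <- character(0)
  for (j in seq_len(n)) {
    y <- Y[, j]
    ok <- !is.na(y)
    if (sum(ok) < K) {
      errors[colnames(Y)[j]] <-
        sprintf("only %d non-missing library probes (< %d cell types)",
                sum(ok), K)
      next
    }
    fit <- solve_constrained_projection(y, X, tol = tol)
    props[j, ] <- fit$w
    rn[j] <- fit$residual_norm
    used[j] <- fit$n_probes_used
    degen[j] <- fit$degenerate
  }
  structure(list(proportions = props,
                 residual_norm = stats::setNames(rn, colnames(Y)),
                 library_size_used = stats::setNames(used, colnames(Y)),
                 probes_dropped = stats::setNames(lib_size - used, colnames(Y)),
                 degenerate = stats::setNames(degen, colnames(Y)),
                 errors = errors,
                 reference = X, full_reference = reference,
                 library = lib_probes,
                 call = match.call()),
            class = "cpqp_fit")
}

#' @export
coef.cpqp_fit <- function(object, ...) object$proportions

#' @export
fitted.cpqp_fit <- function(object, ...) {
  f <- object$reference %*% t(object$proportions)
  colnames(f) <- rownames(object$proportions)
  f
}

#' Residuals of a constrained-projection fit
#'
#' Requires the original sample betas over the library probes.
#'
#' @param object a `cpqp_fit`.
#' @param samples the beta matrix that was deconvolved.
#' @param ... unused.
#' @return probes x samples matrix `y - X w`.
#' @export
residuals.cpqp_fit <- function(object, samples, ...) {
  Y <- samples[object$library, rownames(object$proportions), drop = FALSE]
  Y - fitted(object)
}

#' Deconvolve new samples with a fitted reference/library
#'
#' @param object a `cpqp_fit`.
#' @param newdata beta matrix of new samples.
#' @param ... passed to [deconvolve()].
#' @return a new `cpqp_fit`.
#' @export
predict.cpqp_fit <- function(object, newdata, ...) {
  deconvolve(newdata, object$full_reference, object$library, ...)
}

#' Simulate beta values from a fitted composition
#'
#' Draws `X w + noise` over the library probes, with Gaussian noise scaled to
#' the fit's per-sample residual standard deviation, clipped to \[0, 1\].
#'
#' @param object a `cpqp_fit`.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` beta matrices.
#' @export
simulate.cpqp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sds <- object$residual_norm / sqrt(pmax(object$library_size_used, 1))
  lapply(seq_len(nsim), function(i) {
    eps <- sweep(matrix(stats::rnorm(length(mu)), nrow(mu)), 2L, sds, `*`)
    validate_beta_matrix(pmin(pmax(mu + eps, 0), 1))
  })
}

#' @export
print.cpqp_fit <- function(x, ...) {
  cat("Constrained-projection (CP/QP) deconvolution fit\n")
  cat(sprintf("  %d sample(s), %d cell types, library of %d probes\n",
              nrow(x$proportions), ncol(x$proportions), length(x$library)))
  if (length(x$errors))
    cat(sprintf("  %d sample(s) failed (too few shared probes)\n",
                length(x$errors)))
  cat("Mean estimated proportions:\n")
  print(round(colMeans(x$proportions, na.rm = TRUE), 4))
  invisible(x)
}

#' @export
summary.cpqp_fit <- function(object, ...) {
  p <- object$proportions
  s <- data.frame(cell_type = colnames(p),
                  mean = colMeans(p, na.rm = TRUE),
                  min = suppressWarnings(apply(p, 2L, min, na.rm = TRUE)),
                  max = suppressWarnings(apply(p, 2L, max, na.rm = TRUE)),
                  row.names = NULL)
  out <- list(cell_types = s,
              n_samples = nrow(p),
              library_size = length(object$library),
              mean_residual_norm = mean(object$residual_norm, na.rm = TRUE),
              row_sums = range(rowSums(p), na.rm = TRUE),
              n_degenerate = sum(object$degenerate),
              n_failed = length(object$errors))
  class(out) <- "summary.cpqp_fit"
  out
}

#' @export
print.summary.cpqp_fit <- function(x, ...) {
  cat("CP/QP deconvolution summary\n")
  cat(sprintf("  samples: %d   library probes: %d   mean residual norm: %.4g\n",
              x$n_samples, x$library_size, x$mean_residual_norm))
  cat(sprintf("  row sums in [%.4f, %.4f]   degenerate: %d   failed: %d\n",
              x$row_sums[1], x$row_sums[2], x$n_degenerate, x$n_failed))
  print(transform(x$cell_types, mean = round(mean, 4), min = round(min, 4),
                  max = round(max, 4)))
  invisible(x)
}

#' @export
plot.cpqp_fit <- function(x, ...) {
  p <- t(x$proportions)
  graphics::barplot(p, col = grDevices::hcl.colors(nrow(p), "Dark 3"),
                    las = 2, ylab = "estimated proportion",
                    legend.text = rownames(p),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(x)
}

#' Rescale proportions after excluding cell types
#'
#' Drops the excluded columns and renormalises each remaining row to sum to
#' one — used to make estimates comparable to leukocyte-only FACS panels that
#' lack, e.g., nucleated red blood cells.
#'
#' @param p proportion matrix (samples x cell types) or a `cpqp_fit`.
#' @param exclude character vector of cell types to drop (may be empty; must
#'   be a proper subset of the columns).
#' @return proportion matrix over the remaining types, rows summing to one;
#'   samples whose remaining sum is zero become `NA` rows, with their IDs in
#'   attribute `zero_rows`.
#' @export
rescale_excluding <- function(p, exclude = character(0)) {
  if (inherits(p, "cpqp_fit")) p <- p$proportions
  if (!all(exclude %in% colnames(p)))
    stop("exclude contains unknown cell type(s)")
  keep <- setdiff(colnames(p), exclude)
  if (length(keep) == 0L) stop("cannot exclude every cell type")
  q <- p[, keep, drop = FALSE]
  s <- rowSums(q)
  zero <- !is.na(s) & s <= 0
  q <- q / s
  q[zero, ] <- NA_real_
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero remaining proportion")
    attr(q, "zero_rows") <- rownames(p)[zero]
  }
  q
}
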