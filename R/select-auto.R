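#' Automatic top-N L-DMR library selection
#'
#' The automatic selection rule popularised by array deconvolution tooling:
#' per cell type, probes passing the one-way ANOVA F-test threshold are
#' ranked by one-vs-rest evidence (|Welch t|, ties broken lexicographically
#' by probe ID) and the top `n_per_type` are taken. Mode `"any"` ignores the
#' direction of the methylation difference; mode `"both"` takes the top
#' `n_per_type/2` hypermethylated (t > 0) and `n_per_type/2` hypomethylated
#' (t < 0) probes per type. The per-type lists are unioned (deduplicated,
#' keeping the strongest claim per probe), so the final size is at most
#' `K * n_per_type`.
#'
#' @param betas sorted-reference beta matrix (probes x samples).
#' @param sheet sample sheet for `betas`.
#' @param n_per_type probes selected per cell type (default 100).
#' @param p_threshold F-test p-value cutoff (default 1e-8).
#' @param mode `"any"` (direction-agnostic) or `"both"` (balanced
#'   hyper/hypo).
#' @param rank_by `"t"` ranks candidates within a type by |t| (default);
#'   `"p"` ranks by t-test p-value.
#' @param stats optional precomputed [per_probe_statistics()] result.
#' @return an L-DMR library data.frame (probe_id, target_cell_type,
#'   direction, statistic, p_value), ordered by cell type then rank. Warns
#'   when fewer probes than requested pass the threshold.
#' @export
select_automatic <- function(betas, sheet, n_per_type = 100,
                             p_threshold = 1e-8,
                             mode = c("any", "both"),
                             rank_by = c("t", "p"),
                             stats = NULL) {
  mode <- match.arg(mode)
  rank_by <- match.arg(rank_by)
  if (mode == "both" && n_per_type < 2L)
    stop("mode 'both' needs n_per_type >= 2")
  if (is.null(stats)) stats <- per_probe_statistics(betas, sheet)
  types <- stats$cell_types
  pass <- stats$f_p < p_threshold
  pick <- list()
  for (k in types) {
    tk <- stats$t[, k]
    ord_key <- if (rank_by == "t") -abs(tk) else stats$t_p[, k]
    cand <- data.frame(probe_id = rownames(stats$t), t = tk,
                       p = stats$t_p[, k], key = ord_key,
                       stringsAsFactors = FALSE)[pass, , drop = FALSE]
    cand <- cand[order(cand$key, cand$probe_id), , drop = FALSE]
    if (mode == "any") {
      sel <- utils::head(cand, n_per_type)
      if (nrow(sel) < n_per_type)
        warning(sprintf("cell type %s: only %d probes pass p < %g (requested %d)",
                        k, nrow(sel), p_threshold, n_per_type))
      sel$direction <- ifelse(sel$t >= 0, "hyper", "hypo")
    } else {
      n_half <- n_per_type %/% 2L
      hyper <- utils::head(cand[cand$t > 0, , drop = FALSE], n_half)
      hypo <- utils::head(cand[cand$t < 0, , drop = FALSE], n_half)
      if (nrow(hyper) < n_half || nrow(hypo) < n_half)
        warning(sprintf("cell type %s: only %d hyper / %d hypo probes pass (requested %d each)",
                        k, nrow(hyper), nrow(hypo), n_half))
      hyper$direction <- "hyper"
      hypo$direction <- "hypo"
      sel <- rbind(hyper, hypo)
    }
    if (nrow(sel))
      pick[[k]] <- data.frame(probe_id = sel$probe_id, target_cell_type = k,
                              direction = sel$direction, statistic = sel$t,
                              p_value = sel$p, stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, c(pick, list(make.row.names = FALSE)))
  if (is.null(lib) || nrow(lib) == 0L)
    stop("no probe passed the F-test threshold for any cell type")
  # deduplicate across cell types, keeping the strongest |t| claim
  lib <- lib[order(-abs(lib$statistic), lib$probe_id), , drop = FALSE]
  lib <- lib[!duplicated(lib$probe_id), , drop = FALSE]
  lib <- lib[order(lib$target_cell_type, -abs(lib$statistic), lib$probe_id), ,
             drop = FALSE]
  rownames(lib) <- NULL
  validate_library(lib)
}

#' Probe overlap between L-DMR libraries
#'
#' @param libs named list (>= 2) of libraries (data.frames or probe-ID
#'   vectors).
#' @return list with `sizes`, `pairwise` (symmetric intersection-count
#'   matrix) and `total` (size of the multi-way intersection).
#' @export
library_overlap <- function(libs) {
  if (length(libs) < 2L) stop("need at least two libraries")
  ids <- lapply(libs, function(l) {
    if (is.character(l)) unique(l) else validate_library(l)$probe_id
  })
  if (is.null(names(ids)) || any(names(ids) == ""))
    names(ids) <- paste0("lib", seq_along(ids))
  n <- length(ids)
  pw <- matrix(0L, n, n, dimnames = list(names(ids), names(ids)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  list(sizes = vapply(ids, length, integer(1)),
       pairwise = pw,
       total = length(Reduce(intersect, ids)))
}
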