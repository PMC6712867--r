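# Projection-based QC of sorted reference samples: estimate each sample's
# composition against an external reference (in real studies an adult
# flow-sorted reference; in simulation the generator's true profiles), then
# keep / remove / reclassify by a purity cutoff.

#' QC configuration
#'
#' @param qc_reference probes x K signature matrix the samples are projected
#'   against (e.g. an adult flow-sorted reference).
#' @param qc_library probe IDs or library data.frame used for the projection;
#'   `NULL` uses all reference probes.
#' @param purity_cutoff inclusion cutoff on the expected cell type's raw
#'   projection estimate (default 0.70). Values > 0.5 recommended: then at
#'   most one cell type can exceed the cutoff.
#' @param exempt_cell_types labels that bypass QC entirely (default `"nRBC"`,
#'   which has no adult counterpart).
#' @param reclassify if `TRUE` (default) a sample whose estimate exceeds the
#'   cutoff for a *different* cell type is relabeled to that type; if `FALSE`
#'   (the strict variant) such samples are removed instead.
#' @return classed list of settings.
#' @export
qc_config <- function(qc_reference, qc_library = NULL, purity_cutoff = 0.70,
                      exempt_cell_types = "nRBC", reclassify = TRUE) {
  if (is.data.frame(qc_reference)) qc_reference <- as.matrix(qc_reference)
  if (purity_cutoff <= 0 || purity_cutoff > 1)
    stop("purity_cutoff must be in (0, 1]")
  if (purity_cutoff <= 0.5)
    warning("purity_cutoff <= 0.5: more than one cell type can exceed it")
  probes <- if (is.null(qc_library)) rownames(qc_reference)
            else if (is.character(qc_library)) qc_library
            else validate_library(qc_library)$probe_id
  if (!all(probes %in% rownames(qc_reference)))
    stop("qc_library contains probes absent from qc_reference")
  structure(list(qc_reference = qc_reference, qc_probes = probes,
                 purity_cutoff = purity_cutoff,
                 exempt_cell_types = exempt_cell_types,
                 reclassify = reclassify),
            class = "qc_config")
}

#' Project a sorted sample onto the QC reference
#'
#' Raw (unrescaled) CP/QP composition estimate of one sample over the QC
#' reference cell types.
#'
#' @param y named beta vector (or single-column matrix) for the sample.
#' @param cfg a [qc_config()].
#' @return named proportion vector (non-negative, sum <= 1).
#' @export
project_composition <- function(y, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  if (is.matrix(y)) y <- stats::setNames(y[, 1L], rownames(y))
  shared <- intersect(cfg$qc_probes, names(y)[!is.na(y)])
  K <- ncol(cfg$qc_reference)
  if (length(shared) < K)
    stop("sample shares fewer probes (", length(shared),
         ") with the QC library than cell types (", K, ")")
  solve_constrained_projection(y[shared],
                               cfg$qc_reference[shared, , drop = FALSE])$w
}

#' Classify a reference sample from its projection estimate
#'
#' Exempt cell types bypass QC. Otherwise reclassification takes precedence:
#' if any non-expected cell type's estimate is strictly above the cutoff the
#' sample is relabeled to that type (removed instead when
#' `cfg$reclassify = FALSE`); else if the expected type's estimate is
#' strictly below the cutoff the sample is removed; else it is kept.
#'
#' @param est named proportion vector from [project_composition()].
#' @param expected_type the label the sample carries.
#' @param cfg a [qc_config()].
#' @return data.frame row: expected_type, action (`keep` / `remove` /
#'   `reclassify` / `exempt`), new_type (`NA` unless reclassified), plus the
#'   estimates as `est_<type>` columns.
#' @export
classify_sample <- function(est, expected_type, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  types <- colnames(cfg$qc_reference)
  exempt <- expected_type %in% cfg$exempt_cell_types
  if (!exempt && !(expected_type %in% types))
    stop("expected cell type '", expected_type,
         "' absent from the QC reference and not exempt")
  action <- "keep"; new_type <- NA_character_
  if (exempt) {
    action <- "exempt"
  } else {
    others <- setdiff(types, expected_type)
    over <- others[est[others] > cfg$purity_cutoff]
    if (length(over)) {
      if (cfg$reclassify) {
        action <- "reclassify"
        new_type <- over[which.max(est[over])]
      } else action <- "remove"
    } else if (est[[expected_type]] < cfg$purity_cutoff) {
      action <- "remove"
    }
  }
  out <- data.frame(expected_type = expected_type, action = action,
                    new_type = new_type, stringsAsFactors = FALSE)
  est_df <- as.data.frame(as.list(est))
  names(est_df) <- paste0("est_", names(est))
  cbind(out, est_df)
}

#' Filter a sorted reference dataset by projection QC
#'
#' Projects every sample onto the QC reference, applies [classify_sample()],
#' drops removed samples and relabels reclassified ones in the sample sheet.
#'
#' @param betas sorted-reference beta matrix.
#' @param sheet sample sheet for `betas`.
#' @param cfg a [qc_config()].
#' @return list with `betas` (cleaned), `sheet` (updated labels),
#'   `decisions` (one audit row per input sample, with the full estimate
#'   vector). Warns when every sample of some cell type is removed.
#' @export
filter_reference <- function(betas, sheet, cfg) {
  betas <- validate_beta_matrix(betas)
  sheet <- validate_sample_sheet(sheet)
  idx <- match(colnames(betas), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from the sample sheet")
  sheet <- sheet[idx, , drop = FALSE]
  decisions <- vector("list", ncol(betas))
  for (j in seq_len(ncol(betas))) {
    dec <- classify_sample(project_composition(betas[, j], cfg),
                           sheet$cell_type[j], cfg)
    decisions[[j]] <- cbind(sample_id = colnames(betas)[j], dec)
  }
  decisions <- do.call(rbind, c(decisions, list(make.row.names = FALSE)))
  keep <- decisions$action != "remove"
  new_sheet <- sheet[keep, , drop = FALSE]
  recl <- decisions$action[keep] == "reclassify"
  new_sheet$cell_type[recl] <- decisions$new_type[keep][recl]
  lost <- setdiff(unique(sheet$cell_type), unique(new_sheet$cell_type))
  if (length(lost))
    warning("all samples removed for cell type(s): ",
            paste(lost, collapse = ", "))
  list(betas = betas[, keep, drop = FALSE], sheet = new_sheet,
       decisions = decisions)
}

#' Combine cleaned reference datasets
#'
#' Restricts all datasets to their common complete-case probes (see
#' [intersect_probes()]), pools the samples (dataset provenance retained in
#' the sheet) and averages per cell type into a pooled signature matrix.
#'
#' @param refs list of `list(betas, sheet)` cleaned references; sample IDs
#'   must be globally unique across datasets.
#' @return list with `betas` (pooled probes x samples), `sheet` (pooled),
#'   `reference` (probes x K per-type mean matrix) and `n_per_type`.
#' @export
combine_references <- function(refs) {
  if (length(refs) < 1L) stop("need at least one reference")
  sheets <- lapply(refs, function(r) validate_sample_sheet(r$sheet))
  ids <- unlist(lapply(sheets, `[[`, "sample_id"))
  if (anyDuplicated(ids))
    stop("duplicate sample IDs across datasets; use dataset-prefixed IDs")
  mats <- intersect_probes(lapply(refs, `[[`, "betas"))
  betas <- do.call(cbind, mats)
  common <- Reduce(intersect, lapply(sheets, names))
  sheet <- do.call(rbind, c(lapply(sheets, function(s)
    s[, common, drop = FALSE]), list(make.row.names = FALSE)))
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  types <- sort(unique(sheet$cell_type))
  ind <- outer(sheet$cell_type, types, `==`) * 1
  n_per <- colSums(ind)
  reference <- betas %*% sweep(ind, 2L, n_per, `/`)
  dimnames(reference) <- list(rownames(betas), types)
  list(betas = betas, sheet = sheet, reference = reference,
       n_per_type = stats::setNames(as.integer(n_per), types))
}
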