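#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with probes as rows and samples as
#' columns; row names are probe IDs (e.g. Illumina "cg..." strings, treated as
#' opaque), column names are sample IDs. Entries are methylation fractions in
#' \[0, 1\]; missing measurements are `NA`. Values within `clip_tol` of the
#' boundary are clipped (float noise); larger excursions are errors.
#'
#' @param x numeric matrix, probes x samples, with unique dimnames.
#' @param clip_tol boundary tolerance below/above which values are clipped
#'   rather than rejected.
#' @return the validated (possibly clipped) matrix, invisibly classed as-is.
#' @export
validate_beta_matrix <- function(x, clip_tol = 1e-9) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix (probes x samples)")
  if (nrow(x) > 0 && is.null(rownames(x)))
    stop("beta matrix must carry probe IDs as rownames")
  if (ncol(x) > 0 && is.null(colnames(x)))
    stop("beta matrix must carry sample IDs as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicated probe IDs in beta matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample IDs in beta matrix")
  v <- x[!is.na(x)]
  if (length(v)) {
    if (min(v) < -clip_tol || max(v) > 1 + clip_tol) {
      bad <- which(x < -clip_tol | x > 1 + clip_tol, arr.ind = TRUE)[1L, ]
      stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s'",
                   rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
    }
    x[!is.na(x) & x < 0] <- 0
    x[!is.na(x) & x > 1] <- 1
  }
  x
}

#' Read a beta-value matrix from CSV/TSV
#'
#' Expects probes as rows: first column probe IDs, header row sample IDs.
#' Empty cells are read as missing (`NA`), never as zero.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param sep optional field separator override.
#' @return validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, colClasses = NA,
                          na.strings = c("", "NA"), comment.char = "")
  m <- as.matrix(df)
  if (ncol(m) > 0 && !is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2L, as.numeric))) & !is.na(m),
                 arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    storage.mode(m) <- "double"
  }
  if (ncol(m) == 0) storage.mode(m) <- "double"
  validate_beta_matrix(m)
}

#' Write a beta-value matrix to CSV/TSV
#'
#' Probes as rows, input ordering preserved; missing values written as empty
#' fields so a round trip reproduces them as `NA`.
#'
#' @param m validated beta matrix.
#' @param path output path; separator inferred as in [read_beta_matrix()].
#' @param digits number of significant digits written (default keeps full
#'   double precision).
#' @export
write_beta_matrix <- function(m, path, digits = 15) {
  m <- validate_beta_matrix(m)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(signif(m, digits), check.names = FALSE)
  df <- cbind(probe_id = rownames(m), df)
  tryCatch(
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE, na = ""),
    error = function(e) stop("cannot write beta matrix to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with mandatory columns `sample_id` and `cell_type`; optional `dataset`,
#' `platform`, `sex`. Sample IDs must be unique.
#'
#' @param path CSV file path.
#' @param cell_type_levels optional declared label universe; labels outside it
#'   are an error.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path, cell_type_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, cell_type_levels)
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet, cell_type_levels = NULL) {
  need <- c("sample_id", "cell_type")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id in sample sheet")
  if (!is.null(cell_type_levels)) {
    bad <- setdiff(unique(sheet$cell_type), cell_type_levels)
    if (length(bad))
      stop("cell_type label(s) outside declared universe: ",
           paste(bad, collapse = ", "))
  }
  sheet
}

#' Restrict beta matrices to their common probe set
#'
#' Used to combine reference datasets measured on different platforms: all
#' matrices are cut down to the probes shared by every input, complete-case
#' (a probe with any missing value in any matrix is dropped), and returned in
#' one identical lexicographic probe order so columns can be stacked.
#'
#' @param matrices list of beta matrices.
#' @return list of beta matrices over the common probes, same order.
#' @export
intersect_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need a non-empty list of beta matrices")
  matrices <- lapply(matrices, validate_beta_matrix)
  common <- Reduce(intersect, lapply(matrices, rownames))
  for (m in matrices) {
    if (length(common) == 0L) break
    keep <- !apply(is.na(m[common, , drop = FALSE]), 1L, any)
    common <- common[keep]
  }
  if (length(common) == 0L)
    stop("probe intersection across inputs is empty")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Read / write an L-DMR library
#'
#' A library is a data.frame with columns `probe_id`, `target_cell_type`,
#' `direction` (`hyper`, `hypo` or `any`), `statistic` and `p_value`;
#' `probe_id` is unique.
#'
#' @param path CSV file path.
#' @return library data.frame.
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_library(df)
}

#' @rdname read_library
#' @param lib library data.frame.
#' @export
write_library <- function(lib, path) {
  lib <- validate_library(lib)
  utils::write.csv(lib, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_library
#' @export
validate_library <- function(lib) {
  need <- c("probe_id", "target_cell_type", "direction", "statistic", "p_value")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop("library missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(lib$probe_id)) stop("duplicated probe_id in library")
  if (!all(lib$direction %in% c("hyper", "hypo", "any")))
    stop("library direction must be one of hyper/hypo/any")
  p <- lib$p_value[!is.na(lib$p_value)]
  if (length(p) && (min(p) < 0 || max(p) > 1)) stop("library p_value outside [0,1]")
  lib
}

#' Read / write a proportion matrix
#'
#' Samples as rows, cell types as columns, CSV with a `sample_id` first
#' column.
#'
#' @param path CSV file path.
#' @return numeric matrix, samples x cell types.
#' @export
read_proportions <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_proportions
#' @param p proportion matrix (samples x cell types, named dims).
#' @export
write_proportions <- function(p, path) {
  df <- cbind(sample_id = rownames(p),
              as.data.frame(p, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
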