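# End-to-end seeded study: simulate references and mixtures, QC-filter,
# combine, select libraries (automatic and IDOL-style), deconvolve held-out
# mixtures and evaluate the four arms (auto/IDOL x raw/filtered).

# Rolling polynomial hash over the deparsed config: cheap provenance tag.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic study (its seed is
#'   overridden by `seed`).
#' @param arms subset of `c("auto_raw", "auto_filtered", "idol_raw",
#'   "idol_filtered")`.
#' @param n_datasets number of independent sorted-reference datasets to
#'   simulate (pooled via [combine_references()]).
#' @param purity_cutoff,exempt_cell_types,reclassify QC settings (see
#'   [qc_config()]). The QC projection uses the generator's true profiles as
#'   the external reference, restricted to the planted marker probes.
#' @param auto_n_per_type,auto_p_threshold,auto_mode automatic-selection
#'   settings (see [select_automatic()]).
#' @param idol_m_top,idol_sizes,idol_iterations IDOL settings; sizes above
#'   the candidate pool are dropped.
#' @param train_fraction fraction of mixtures used to train the IDOL
#'   optimiser; the remainder is the held-out evaluation set for all arms.
#' @param seed global seed.
#' @param out_dir output directory for stage artifacts (`NULL` = keep in
#'   memory only).
#' @return classed list of settings.
#' @export
pipeline_config <- function(sim = sim_config(),
                            arms = c("auto_raw", "auto_filtered",
                                     "idol_raw", "idol_filtered"),
                            n_datasets = 2,
                            purity_cutoff = 0.70,
                            exempt_cell_types = "nRBC",
                            reclassify = TRUE,
                            auto_n_per_type = 100,
                            auto_p_threshold = 1e-8,
                            auto_mode = "any",
                            idol_m_top = 150,
                            idol_sizes = seq(150, 700, by = 50),
                            idol_iterations = 500,
                            train_fraction = 0.5,
                            seed = 1L,
                            out_dir = NULL) {
  all_arms <- c("auto_raw", "auto_filtered", "idol_raw", "idol_filtered")
  arms <- match.arg(arms, all_arms, several.ok = TRUE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(sim = sim, arms = arms, n_datasets = as.integer(n_datasets),
                 purity_cutoff = purity_cutoff,
                 exempt_cell_types = exempt_cell_types,
                 reclassify = reclassify,
                 auto_n_per_type = auto_n_per_type,
                 auto_p_threshold = auto_p_threshold,
                 auto_mode = auto_mode,
                 idol_m_top = idol_m_top, idol_sizes = idol_sizes,
                 idol_iterations = idol_iterations,
                 train_fraction = train_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full synthetic deconvolution study
#'
#' Stages: (1) simulate true cell profiles with planted markers; (2)
#' simulate `n_datasets` sorted-reference datasets (with whatever
#' contamination / mislabeling the sim config plants) and the mixtures;
#' (3) QC-filter each dataset by projection against the true profiles;
#' (4) combine raw and filtered references; (5) per arm, select a library
#' (automatic or IDOL trained on the training mixtures) and deconvolve the
#' held-out mixtures; (6) evaluate every arm against the known truth.
#' Identical seeds give identical summaries.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `summary` (per arm: mean R^2, mean RMSE, library size),
#'   `evaluations` (per-arm `eval_report`s), `qc` (per-dataset decisions),
#'   `libraries`, `fits`, `truth`, `provenance` (seed + config hash). When
#'   `cfg$out_dir` is set, every stage artifact is also written there as
#'   CSV/JSON.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim
  sim$seed <- cfg$seed
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit_csv <- function(obj, name, writer = utils::write.csv, ...) {
    if (!is.null(out)) writer(obj, file.path(out, name), ...)
  }

  prof <- generate_cell_profiles(sim)
  dmr_probes <- unique(prof$dmr_map$probe_id)
  emit_csv(prof$dmr_map, "dmr_map.csv", row.names = FALSE)

  datasets <- lapply(seq_len(cfg$n_datasets), function(i) {
    d <- sim
    d$seed <- sim$seed + 1000L * i
    generate_sorted_samples(prof$profiles, d, dataset = sprintf("ds%d", i))
  })
  names(datasets) <- sprintf("ds%d", seq_len(cfg$n_datasets))

  mix <- generate_mixtures(prof$profiles, sim)
  n_mix <- ncol(mix$betas)
  n_train <- max(1L, round(cfg$train_fraction * n_mix))
  train_idx <- with_seed(sim$seed + 77L, sample.int(n_mix, n_train))
  train_ids <- colnames(mix$betas)[sort(train_idx)]
  test_ids <- setdiff(colnames(mix$betas), train_ids)
  if (length(test_ids) < 3L) stop("too few held-out mixtures to evaluate")
  emit_csv(mix$proportions, "mixture_truth.csv", writer = write_proportions)

  qcc <- qc_config(prof$profiles, dmr_probes,
                   purity_cutoff = cfg$purity_cutoff,
                   exempt_cell_types = cfg$exempt_cell_types,
                   reclassify = cfg$reclassify)
  filtered <- lapply(datasets, function(d) filter_reference(d$betas, d$sheet, qcc))
  qc_decisions <- do.call(rbind, c(
    lapply(names(filtered), function(nm)
      cbind(dataset = nm, filtered[[nm]]$decisions)),
    list(make.row.names = FALSE)))
  emit_csv(qc_decisions, "qc_decisions.csv", row.names = FALSE)

  raw_comb <- combine_references(lapply(datasets, `[`, c("betas", "sheet")))
  filt_comb <- combine_references(lapply(filtered, `[`, c("betas", "sheet")))

  select_for <- function(arm) {
    comb <- if (grepl("filtered", arm)) filt_comb else raw_comb
    st <- per_probe_statistics(comb$betas, comb$sheet)
    if (startsWith(arm, "auto")) {
      lib <- select_automatic(comb$betas, comb$sheet,
                              n_per_type = cfg$auto_n_per_type,
                              p_threshold = cfg$auto_p_threshold,
                              mode = cfg$auto_mode, stats = st)
      list(library = lib, reference = comb$reference, idol = NULL)
    } else {
      cand <- idol_candidate_set(comb$betas, comb$sheet,
                                 m_top = cfg$idol_m_top, stats = st)
      sizes <- cfg$idol_sizes[cfg$idol_sizes <= nrow(cand)]
      if (!length(sizes)) sizes <- nrow(cand)
      res <- idol_optimize(cand, comb$reference,
                           mix$betas[, train_ids, drop = FALSE],
                           mix$proportions[train_ids, , drop = FALSE],
                           mix$betas[, test_ids, drop = FALSE],
                           mix$proportions[test_ids, , drop = FALSE],
                           library_sizes = sizes,
                           n_iterations = cfg$idol_iterations,
                           seed = cfg$seed)
      list(library = res$best_library, reference = comb$reference, idol = res)
    }
  }

  libraries <- evaluations <- fits <- list()
  summary_rows <- list()
  for (arm in cfg$arms) {
    sel <- tryCatch(select_for(arm), error = function(e)
      stop("pipeline stage 'select:", arm, "' failed: ", conditionMessage(e)))
    fit <- deconvolve(mix$betas[, test_ids, drop = FALSE], sel$reference,
                      sel$library)
    rep <- evaluate_proportions(coef(fit),
                                mix$proportions[test_ids, , drop = FALSE])
    libraries[[arm]] <- sel$library
    fits[[arm]] <- fit
    evaluations[[arm]] <- rep
    summary_rows[[arm]] <- data.frame(
      arm = arm, library_size = nrow(sel$library),
      mean_r2 = attr(rep, "mean_r2"), mean_rmse = attr(rep, "mean_rmse"))
    emit_csv(sel$library, paste0("library_", arm, ".csv"),
             writer = write_library)
    emit_csv(coef(fit), paste0("proportions_", arm, ".csv"),
             writer = write_proportions)
    emit_csv(as.data.frame(rep), paste0("evaluation_", arm, ".csv"),
             row.names = FALSE)
  }
  summary_df <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  hashed <- unclass(cfg)
  hashed$out_dir <- NULL  # the output path is not part of the science
  provenance <- list(seed = cfg$seed, config_hash = config_hash(hashed))
  result <- list(summary = summary_df, evaluations = evaluations,
                 libraries = libraries, fits = fits,
                 qc = qc_decisions, truth = mix$proportions,
                 test_samples = test_ids, provenance = provenance)
  if (!is.null(out)) {
    js <- list(provenance = provenance,
               arms = stats::setNames(
                 lapply(seq_len(nrow(summary_df)), function(i)
                   as.list(summary_df[i, -1L])), summary_df$arm),
               qc = list(n_removed = sum(qc_decisions$action == "remove"),
                         n_reclassified = sum(qc_decisions$action == "reclassify")))
    jsonlite::write_json(js, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
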