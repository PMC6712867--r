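# Row-wise differential-methylation statistics across cell types, vectorised
# over probes: for each probe, a Welch two-sample t per cell type (that type
# vs all remaining samples pooled) and a one-way ANOVA F across the K groups.

#' Per-probe differential-methylation statistics
#'
#' For every probe, computes a Welch (unequal-variance) one-vs-rest t
#' statistic for each cell type — comparing the type's samples against all
#' remaining samples pooled — and a one-way ANOVA F statistic across the K
#' cell-type groups, with two-sided p-values. These are the inputs of both
#' library-selection strategies.
#'
#' @param betas beta matrix (probes x samples), no missing values.
#' @param sheet sample sheet mapping every column of `betas` to a cell type;
#'   every cell type needs >= 2 samples for variance estimation.
#' @return object of class `probe_stats`: list with `t` and `t_p`
#'   (probes x K matrices), `f` and `f_p` (per-probe vectors), `cell_types`,
#'   `n_per_type`. Probes that are constant within and across groups get
#'   t = 0, F = 0 and p = 1 (no signal).
#' @export
per_probe_statistics <- function(betas, sheet) {
  betas <- validate_beta_matrix(betas)
  sheet <- validate_sample_sheet(sheet)
  if (anyNA(betas)) stop("betas contain missing values; intersect probes first")
  idx <- match(colnames(betas), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from the sample sheet")
  grp <- sheet$cell_type[idx]
  types <- sort(unique(grp))
  K <- length(types)
  ng <- as.numeric(table(factor(grp, levels = types)))
  if (any(ng < 2L))
    stop("cell type(s) with < 2 samples: ",
         paste(types[ng < 2L], collapse = ", "))
  N <- ncol(betas)
  ind <- outer(grp, types, `==`) * 1  # samples x K indicator
  Sg <- betas %*% ind                 # per-group sums, probes x K
  SSg <- (betas^2) %*% ind
  S <- rowSums(betas)
  SS <- rowSums(betas^2)
  Mg <- sweep(Sg, 2L, ng, `/`)
  Vg <- sweep(SSg - sweep(Mg^2, 2L, ng, `*`), 2L, ng - 1, `/`)
  Vg[Vg < 0] <- 0  # float guard
  nr <- N - ng
  Mr <- sweep(S - Sg, 2L, nr, `/`)
  Vr <- sweep((SS - SSg) - sweep(Mr^2, 2L, nr, `*`), 2L, nr - 1, `/`)
  Vr[Vr < 0] <- 0

  se2 <- sweep(Vg, 2L, ng, `/`) + sweep(Vr, 2L, nr, `/`)
  diff <- Mg - Mr
  tstat <- diff / sqrt(se2)
  tstat[se2 == 0 & diff == 0] <- 0
  tstat[se2 == 0 & diff != 0] <- sign(diff[se2 == 0 & diff != 0]) * Inf
  # Welch-Satterthwaite df
  a <- sweep(Vg, 2L, ng, `/`); b <- sweep(Vr, 2L, nr, `/`)
  df <- se2^2 / (sweep(a^2, 2L, ng - 1, `/`) + sweep(b^2, 2L, nr - 1, `/`))
  tp <- 2 * stats::pt(-abs(tstat), df)
  tp[tstat == 0] <- 1
  tp[is.infinite(tstat)] <- 0
  dimnames(tstat) <- dimnames(tp) <- list(rownames(betas), types)

  # one-way ANOVA from group sums
  grand <- S / N
  ssb <- rowSums(sweep((Mg - grand)^2, 2L, ng, `*`))
  ssw <- rowSums(sweep(Vg, 2L, ng - 1, `*`))
  fstat <- (ssb / (K - 1)) / (ssw / (N - K))
  fp <- stats::pf(fstat, K - 1, N - K, lower.tail = FALSE)
  zero_b <- ssb <= 0
  fstat[zero_b] <- 0; fp[zero_b] <- 1
  inf_f <- !zero_b & ssw <= 0
  fstat[inf_f] <- Inf; fp[inf_f] <- 0
  names(fstat) <- names(fp) <- rownames(betas)

  structure(list(t = tstat, t_p = tp, f = fstat, f_p = fp,
                 cell_types = types,
                 n_per_type = stats::setNames(ng, types)),
            class = "probe_stats")
}

#' @export
print.probe_stats <- function(x, ...) {
  cat(sprintf("Per-probe statistics: %d probes, %d cell types (%s)\n",
              nrow(x$t), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}
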