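# Synthetic methylome generator: cell-type-specific beta profiles with planted
# hyper/hypomethylated marker probes, sorted reference samples of variable
# purity (optionally contaminated or mislabeled), and whole-blood mixtures with
# Dirichlet-distributed known proportions. One global seed drives a derived
# per-operation seed so stages reproduce independently.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic methylome generator. Defaults emulate a
#' cord-blood study: seven cell types including nucleated red blood cells
#' (nRBC), sorted references of high but imperfect purity, and mixtures whose
#' expected composition follows typical cord-blood differentials
#' (granulocyte-dominated, nRBC a few percent).
#'
#' @param n_probes number of probes.
#' @param cell_types character vector of K >= 2 cell-type labels.
#' @param n_dmr_per_type planted marker probes per cell type (half shifted up,
#'   half down in that type only); `n_dmr_per_type * K <= n_probes`.
#' @param dmr_effect beta-scale shift at planted markers, in (0, 1].
#' @param n_ref_samples_per_type sorted reference samples generated per type.
#' @param ref_noise_sd logit-scale replicate noise SD for sorted samples.
#' @param purity per-sample purity of sorted samples: a scalar, a vector
#'   recycled within each cell type, or a function of n returning purities.
#' @param contaminated_fraction fraction of sorted samples per type replaced
#'   by contaminated samples of purity `contaminated_purity`.
#' @param contaminated_purity purity assigned to contaminated samples.
#' @param mislabel_fraction fraction of sorted samples per type whose true
#'   profile is a different cell type (label kept = mislabeling).
#' @param mixture_alpha Dirichlet concentration, length K. The default scales
#'   typical cord-blood mean fractions (Gran-dominated, small nRBC pool) by a
#'   total concentration of 15, giving realistic between-sample spread.
#' @param n_mixtures number of whole-blood mixtures.
#' @param mixture_noise_sd additive Gaussian measurement noise SD on mixture
#'   betas (clipped back to \[0, 1\]).
#' @param platform_overlap_fraction fraction of probes shared by the two
#'   pseudo-platforms produced by [split_platforms()].
#' @param seed integer global seed.
#' @return classed list of validated settings.
#' @export
sim_config <- function(n_probes = 2000,
                       cell_types = c("Bcell", "CD4T", "CD8T", "Gran",
                                      "Mono", "NK", "nRBC"),
                       n_dmr_per_type = 40,
                       dmr_effect = 0.4,
                       n_ref_samples_per_type = 12,
                       ref_noise_sd = 0.15,
                       purity = 0.98,
                       contaminated_fraction = 0,
                       contaminated_purity = 0.6,
                       mislabel_fraction = 0,
                       mixture_alpha = NULL,
                       n_mixtures = 24,
                       mixture_noise_sd = 0.015,
                       platform_overlap_fraction = 0.9,
                       seed = 1L) {
  K <- length(cell_types)
  if (K < 2L) stop("need at least two cell types")
  if (anyDuplicated(cell_types)) stop("duplicated cell-type labels")
  if (n_dmr_per_type * K > n_probes)
    stop("n_dmr_per_type * K exceeds n_probes: not enough probes to plant markers")
  if (dmr_effect <= 0 || dmr_effect > 1) stop("dmr_effect must be in (0, 1]")
  if (ref_noise_sd < 0 || mixture_noise_sd < 0) stop("noise SDs must be >= 0")
  if (is.null(mixture_alpha)) {
    base <- c(Bcell = 0.07, CD4T = 0.15, CD8T = 0.05, Gran = 0.55,
              Mono = 0.08, NK = 0.05, nRBC = 0.05)
    w <- if (all(cell_types %in% names(base))) base[cell_types] else rep(1, K)
    mixture_alpha <- 15 * unname(w / sum(w))
  }
  if (length(mixture_alpha) != K || any(mixture_alpha <= 0))
    stop("mixture_alpha must be K positive reals")
  if (platform_overlap_fraction <= 0 || platform_overlap_fraction > 1)
    stop("platform_overlap_fraction must be in (0, 1]")
  if (contaminated_fraction < 0 || contaminated_fraction > 1 ||
      mislabel_fraction < 0 || mislabel_fraction > 1)
    stop("fractions must be in [0, 1]")
  structure(list(n_probes = as.integer(n_probes), cell_types = cell_types,
                 n_dmr_per_type = as.integer(n_dmr_per_type),
                 dmr_effect = dmr_effect,
                 n_ref_samples_per_type = as.integer(n_ref_samples_per_type),
                 ref_noise_sd = ref_noise_sd, purity = purity,
                 contaminated_fraction = contaminated_fraction,
                 contaminated_purity = contaminated_purity,
                 mislabel_fraction = mislabel_fraction,
                 mixture_alpha = mixture_alpha,
                 n_mixtures = as.integer(n_mixtures),
                 mixture_noise_sd = mixture_noise_sd,
                 platform_overlap_fraction = platform_overlap_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derived per-operation seed: stage-level reproducibility when stages rerun
# independently. Kept below 2^31.
op_seed <- function(cfg, op) {
  ops <- c(profiles = 11L, sorted = 23L, mixtures = 37L, platforms = 53L)
  (cfg$seed %% 100000L) * 10007L + ops[[op]]
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate cell-type-specific reference profiles with planted markers
#'
#' Baseline probe means are drawn from an equal-weight mixture of Beta(2, 10)
#' and Beta(10, 2) (the genome-wide bimodality of methylation), clipped to
#' \[0.01, 0.99\]. For each cell type, `n_dmr_per_type` disjoint probes are
#' shifted by `+dmr_effect` (hyper) or `-dmr_effect` (hypo), half each, in
#' that type only; hyper markers are planted on background-unmethylated
#' probes and hypo markers on methylated ones so the planted contrast is the
#' full `dmr_effect`.
#'
#' @param cfg a [sim_config()].
#' @return list with `profiles` (probes x K matrix of true cell-type means)
#'   and `dmr_map` (data.frame probe_id / cell_type / direction of planted
#'   truth).
#' @export
generate_cell_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(op_seed(cfg, "profiles"), {
    P <- cfg$n_probes
    K <- length(cfg$cell_types)
    probe_ids <- sprintf("cg%07d", seq_len(P))
    lo <- stats::rbeta(P, 2, 10)
    hi <- stats::rbeta(P, 10, 2)
    base <- ifelse(stats::runif(P) < 0.5, lo, hi)
    base <- pmin(pmax(base, 0.01), 0.99)
    profiles <- matrix(base, nrow = P, ncol = K,
                       dimnames = list(probe_ids, cfg$cell_types))
    dmr_map <- NULL
    if (cfg$n_dmr_per_type > 0) {
      # hyper markers are planted on probes unmethylated in the background
      # and hypo markers on methylated ones (how real cell-type markers
      # look), so every planted shift is the full dmr_effect, unclipped
      n_hyper <- ceiling(cfg$n_dmr_per_type / 2)
      n_hypo <- cfg$n_dmr_per_type - n_hyper
      elig_hyper <- which(base <= 0.99 - cfg$dmr_effect)
      elig_hypo <- which(base >= 0.01 + cfg$dmr_effect)
      if (length(elig_hyper) < n_hyper * K || length(elig_hypo) < n_hypo * K)
        stop("too few probes away from the boundaries to plant markers; ",
             "lower dmr_effect or raise n_probes")
      hyper_pick <- matrix(sample(elig_hyper, n_hyper * K), n_hyper, K)
      remaining <- setdiff(elig_hypo, hyper_pick)
      if (length(remaining) < n_hypo * K)
        stop("too few probes away from the boundaries to plant markers; ",
             "lower dmr_effect or raise n_probes")
      hypo_pick <- matrix(sample(remaining, n_hypo * K), max(n_hypo, 0), K)
      dirs <- rep(c("hyper", "hypo"), c(n_hyper, n_hypo))
      picked <- rbind(hyper_pick, hypo_pick)
      for (k in seq_len(K)) {
        shift <- ifelse(dirs == "hyper", cfg$dmr_effect, -cfg$dmr_effect)
        profiles[picked[, k], k] <- profiles[picked[, k], k] + shift
      }
      dmr_map <- data.frame(probe_id = probe_ids[as.vector(picked)],
                            cell_type = rep(cfg$cell_types,
                                            each = cfg$n_dmr_per_type),
                            direction = rep(dirs, K),
                            stringsAsFactors = FALSE)
    }
    list(profiles = profiles, dmr_map = dmr_map)
  })
}

resolve_purity <- function(purity, n) {
  p <- if (is.function(purity)) purity(n) else rep_len(purity, n)
  if (any(p < 0 | p > 1)) stop("purity values must lie in [0, 1]")
  p
}

#' Generate sorted reference samples of variable purity
#'
#' Each sorted sample is `purity * own profile + (1 - purity) * contaminant`,
#' where the contaminant is a single random other cell type (the failure mode
#' seen in real sorted references), followed by logit-scale Gaussian replicate
#' noise. A `contaminated_fraction` of samples per type is generated at
#' `contaminated_purity` instead; a `mislabel_fraction` keeps the intended
#' label but draws the profile from a different cell type at the base purity
#' (a mislabeled tube).
#'
#' @param profiles probes x K matrix of true cell-type means.
#' @param cfg a [sim_config()].
#' @param dataset dataset tag recorded in the sample sheet (also prefixes
#'   sample IDs so pooled datasets never collide).
#' @param platform platform tag recorded in the sample sheet.
#' @return list with `betas` (probes x samples), `sheet` (sample sheet with
#'   the intended labels) and `truth` (per-sample true type, labeled type,
#'   purity, contaminant).
#' @export
generate_sorted_samples <- function(profiles, cfg, dataset = "sim",
                                    platform = "450K") {
  stopifnot(inherits(cfg, "sim_config"))
  K <- ncol(profiles)
  types <- colnames(profiles)
  n_per <- cfg$n_ref_samples_per_type
  with_seed(op_seed(cfg, "sorted") + as.integer(sum(utf8ToInt(dataset)) %% 997L), {
    cols <- vector("list", K * n_per)
    truth <- vector("list", K * n_per)
    s <- 0L
    for (k in seq_len(K)) {
      pur <- resolve_purity(cfg$purity, n_per)
      n_cont <- round(cfg$contaminated_fraction * n_per)
      n_mis <- round(cfg$mislabel_fraction * n_per)
      if (n_cont + n_mis > n_per)
        stop("contaminated_fraction + mislabel_fraction exceed samples per type")
      flag <- rep("clean", n_per)
      if (n_cont > 0) flag[seq_len(n_cont)] <- "contaminated"
      if (n_mis > 0) flag[n_cont + seq_len(n_mis)] <- "mislabeled"
      pur[flag == "contaminated"] <- cfg$contaminated_purity
      for (i in seq_len(n_per)) {
        s <- s + 1L
        true_k <- if (flag[i] == "mislabeled")
          sample(setdiff(seq_len(K), k), 1L) else k
        contam_k <- sample(setdiff(seq_len(K), true_k), 1L)
        y <- pur[i] * profiles[, true_k] + (1 - pur[i]) * profiles[, contam_k]
        if (cfg$ref_noise_sd > 0)
          y <- stats::plogis(stats::qlogis(y) +
                               stats::rnorm(nrow(profiles), 0, cfg$ref_noise_sd))
        cols[[s]] <- y
        truth[[s]] <- data.frame(
          sample_id = sprintf("%s_%s_%02d", dataset, types[k], i),
          labeled_type = types[k], true_type = types[true_k],
          purity = pur[i], contaminant = types[contam_k], status = flag[i],
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    betas <- do.call(cbind, cols)
    dimnames(betas) <- list(rownames(profiles), truth$sample_id)
    sheet <- data.frame(sample_id = truth$sample_id,
                        cell_type = truth$labeled_type,
                        dataset = dataset, platform = platform,
                        stringsAsFactors = FALSE)
    list(betas = validate_beta_matrix(betas), sheet = sheet, truth = truth)
  })
}

#' Generate whole-blood mixtures with known proportions
#'
#' True mixing fractions are drawn from a Dirichlet with concentration
#' `cfg$mixture_alpha`; each mixture beta vector is the proportion-weighted
#' average of the cell-type profiles plus additive Gaussian measurement noise,
#' clipped to \[0, 1\].
#'
#' @param profiles probes x K matrix of true cell-type means.
#' @param cfg a [sim_config()].
#' @param prefix sample-ID prefix.
#' @return list with `betas` (probes x n_mixtures) and `proportions`
#'   (n_mixtures x K true fractions, rows summing to one).
#' @export
generate_mixtures <- function(profiles, cfg, prefix = "mix") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(op_seed(cfg, "mixtures") + as.integer(sum(utf8ToInt(prefix)) %% 997L), {
    n <- cfg$n_mixtures
    w <- rdirichlet(n, cfg$mixture_alpha)
    dimnames(w) <- list(sprintf("%s_%03d", prefix, seq_len(n)),
                        colnames(profiles))
    y <- profiles %*% t(w)
    if (cfg$mixture_noise_sd > 0)
      y <- y + matrix(stats::rnorm(length(y), 0, cfg$mixture_noise_sd),
                      nrow = nrow(y))
    y <- pmin(pmax(y, 0), 1)
    colnames(y) <- rownames(w)
    list(betas = validate_beta_matrix(y), proportions = w)
  })
}

#' Split a beta matrix into two pseudo-platforms
#'
#' Emulates the 450K / EPIC probe-universe mismatch: returns two probe subsets
#' whose intersection is `platform_overlap_fraction` of the probes, with the
#' remaining probes split evenly between the two platforms.
#'
#' @param m beta matrix.
#' @param cfg a [sim_config()].
#' @return list of two beta matrices (`a`, `b`).
#' @export
split_platforms <- function(m, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(op_seed(cfg, "platforms"), {
    P <- nrow(m)
    n_shared <- round(cfg$platform_overlap_fraction * P)
    if (n_shared < 1L) stop("platform overlap would be empty")
    perm <- sample.int(P)
    shared <- perm[seq_len(n_shared)]
    rest <- perm[-seq_len(n_shared)]
    a_only <- rest[seq_len(floor(length(rest) / 2))]
    b_only <- setdiff(rest, a_only)
    list(a = m[sort(c(shared, a_only)), , drop = FALSE],
         b = m[sort(c(shared, b_only)), , drop = FALSE])
  })
}
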