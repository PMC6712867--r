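# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet_test <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

# Coarse-to-fine grid search over {w >= 0, sum(w) <= 1}, final step <= 1e-4.
# Independent of the package's KKT solver; zooming is sound because the
# least-squares objective is convex.
grid_oracle <- function(y, X, final_step = 1e-4) {
  K <- ncol(X)
  center <- rep(1 / (2 * K), K)
  h <- 1
  repeat {
    step <- h / 10
    grids <- lapply(seq_len(K), function(k)
      seq(max(0, center[k] - h), min(1, center[k] + h), by = step))
    W <- as.matrix(expand.grid(grids))
    W <- W[rowSums(W) <= 1 + 1e-12, , drop = FALSE]
    W <- rbind(W, center)  # keep the current best in play
    obj <- colSums((X %*% t(W) - y)^2)
    center <- W[which.min(obj), ]
    if (step <= final_step) return(unname(center))
    h <- 3 * step
  }
}

# Small default simulation for module tests: 4 leukocyte-like types, strong
# planted markers, quiet references.
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_probes = 400, cell_types = c("A", "B", "C", "D"),
                   n_dmr_per_type = 20, dmr_effect = 0.4,
                   n_ref_samples_per_type = 8, ref_noise_sd = 0.1,
                   n_mixtures = 12, mixture_noise_sd = 0.01, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a sorted-reference dataset by hand from true profiles so every QC
# decision has a known correct answer. `plan` columns: sample_id, true_type,
# label, purity, contaminant.
planted_reference <- function(profiles, plan) {
  cols <- mapply(function(true_type, purity, contam) {
    profiles[, true_type] * purity + profiles[, contam] * (1 - purity)
  }, plan$true_type, plan$purity, plan$contaminant)
  colnames(cols) <- plan$sample_id
  list(betas = validate_beta_matrix(cols),
       sheet = data.frame(sample_id = plan$sample_id,
                          cell_type = plan$label, stringsAsFactors = FALSE))
}

random_beta_matrix <- function(P = 6, n = 4, na = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(P * n), P, n,
              dimnames = list(sprintf("cg%03d", seq_len(P)),
                              sprintf("s%02d", seq_len(n))))
  if (na > 0) m[sample(length(m), na)] <- NA
  m
}
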