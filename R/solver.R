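# Constrained projection (CP/QP): least squares under w >= 0, sum(w) <= 1.
#
# The problem is a tiny convex QP (K <= ~7 cell types), so it is solved
# exactly by enumerating candidate active sets in increasing size and
# returning the first (hence smallest-active-set) point satisfying the full
# KKT conditions; for a convex objective any KKT point is the global optimum.
# The unconstrained minimiser is tried first, which resolves most calls in a
# single K x K solve.

pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# All index subsets of 1..K ordered by size (small active sets first).
active_subsets <- function(K) {
  out <- list(integer(0))
  for (size in seq_len(K))
    out <- c(out, utils::combn(K, size, simplify = FALSE))
  out
}

#' Solve the constrained projection problem
#'
#' Estimates mixing fractions `w` minimising `||X w - y||^2` subject to
#' `w >= 0` and `sum(w) <= 1` — the Houseman-style constrained projection /
#' quadratic programming (CP/QP) estimator used for reference-based cell-type
#' deconvolution. The solution is exact (KKT-verified); for rank-deficient
#' `X` a minimum-norm optimiser is returned and flagged degenerate.
#'
#' @param y numeric vector of beta values over the library probes (aligned to
#'   the rows of `X`); `NA` entries are dropped together with their rows.
#' @param X probes x K reference signature matrix.
#' @param tol KKT feasibility/stationarity tolerance.
#' @return list with `w` (named proportion vector), `residual_norm`
#'   (Euclidean norm of `y - X w` over the probes used), `degenerate` flag,
#'   and `n_probes_used`.
#' @export
solve_constrained_projection <- function(y, X, tol = 1e-8) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  K <- ncol(X)
  if (nrow(X) < K)
    stop("fewer probes (", nrow(X), ") than cell types (", K, ")")
  if (anyNA(X)) stop("reference matrix contains missing values")
  Q <- crossprod(X)
  cvec <- drop(crossprod(X, y))
  sol <- cpqp_core(Q, cvec, tol)
  w <- sol$w
  names(w) <- colnames(X)
  list(w = w,
       residual_norm = sqrt(max(0, sum((drop(X %*% w) - y)^2))),
       degenerate = sol$degenerate,
       n_probes_used = nrow(X))
}

# Q = X'X, cvec = X'y. Returns list(w, degenerate).
# For full-rank Q the first KKT point found is returned (convexity makes it
# the global optimum). For rank-deficient Q the optimum may be non-unique:
# every active set is examined and the minimum-norm optimiser returned,
# flagged degenerate.
cpqp_core <- function(Q, cvec, tol = 1e-8) {
  K <- length(cvec)
  feas_tol <- tol
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  rank_deficient <- min(ev) <= 1e-10 * max(ev, 1)
  solve_or_pinv <- function(A, b) {
    out <- tryCatch(list(x = solve(A, b), deg = FALSE),
                    error = function(e) NULL)
    if (is.null(out)) out <- list(x = drop(pinv(A) %*% b), deg = TRUE)
    out
  }
  best <- NULL
  for (sum_active in c(FALSE, TRUE)) {
    for (A in active_subsets(K)) {
      Fset <- setdiff(seq_len(K), A)
      nf <- length(Fset)
      if (nf == 0L && sum_active) next  # sum(w)=1 with all w=0 infeasible
      w <- numeric(K)
      lambda <- 0
      deg <- FALSE
      if (nf > 0L) {
        if (sum_active) {
          M <- rbind(cbind(Q[Fset, Fset, drop = FALSE], 1),
                     c(rep(1, nf), 0))
          sv <- solve_or_pinv(M, c(cvec[Fset], 1))
          w[Fset] <- sv$x[seq_len(nf)]
          lambda <- sv$x[nf + 1L]
          deg <- sv$deg
        } else {
          sv <- solve_or_pinv(Q[Fset, Fset, drop = FALSE], cvec[Fset])
          w[Fset] <- sv$x
          deg <- sv$deg
        }
      }
      # primal feasibility
      if (any(w < -feas_tol)) next
      if (!sum_active && sum(w) > 1 + feas_tol) next
      if (sum_active && abs(sum(w) - 1) > feas_tol) next
      g <- drop(Q %*% w) - cvec
      # stationarity on free coords (guards pseudo-inverse solutions)
      if (nf > 0L && max(abs(g[Fset] + if (sum_active) lambda else 0)) >
            tol * max(1, max(abs(cvec)))) next
      # dual feasibility
      if (sum_active && lambda < -tol) next
      mu <- g[A] + if (sum_active) lambda else 0
      if (length(mu) && any(mu < -tol * max(1, max(abs(cvec))))) next
      w[w < 0] <- 0
      cand <- list(w = w,
                   obj = 0.5 * sum(w * drop(Q %*% w)) - sum(cvec * w))
      if (!rank_deficient && !deg)
        return(list(w = cand$w, degenerate = FALSE))
      # non-unique optimum possible: keep the minimum-norm optimiser
      if (is.null(best) || cand$obj < best$obj - 1e-12 ||
          (abs(cand$obj - best$obj) <= 1e-12 && sum(w^2) < sum(best$w^2)))
        best <- cand
    }
  }
  if (is.null(best))
    stop("constrained projection failed to find a KKT point")
  list(w = best$w, degenerate = rank_deficient)
}
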