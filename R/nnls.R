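# Exact non-negative least squares for systems with few columns, vectorised
# over many right-hand sides.
#
# For p columns there are 2^p - 1 candidate active sets plus the zero
# solution; for each set S the equality-constrained optimum solves
# A_S' A_S w_S = A_S' b, and the KKT conditions for min ||Aw - b||^2, w >= 0
# are: w_S >= 0 and (A'A w - A'b)_j >= 0 for j outside S. With a full-rank
# basis the optimum is unique, so scanning all subsets and keeping, per
# column of B, the first KKT-feasible solution is exact NNLS. With p = 4
# kinetic classes this is 15 small solves shared across ~10^4 voxels, far
# cheaper than per-voxel iterative solvers.
#
# A: n x p design (p <= ~8); B: n x m right-hand sides.
# Returns a p x m matrix of non-negative weights.
nnls_multi <- function(A, B, tol = 1e-9) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  p <- ncol(A)
  m <- ncol(B)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  scale <- max(abs(AtB), 1)
  W <- matrix(0, p, m, dimnames = list(colnames(A), colnames(B)))
  # zero solution is optimal where all gradients -A'b are already >= 0
  unsolved <- apply(AtB > tol * scale, 2, any)
  subsets <- unlist(lapply(seq_len(p), function(k) {
    asplit(utils::combn(p, k), 2)
  }), recursive = FALSE)
  for (S in subsets) {
    if (!any(unsolved)) break
    idx <- which(unsolved)
    sol <- tryCatch(solve(AtA[S, S, drop = FALSE], AtB[S, idx, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    grad_ok <- rep(TRUE, length(idx))
    comp <- setdiff(seq_len(p), S)
    if (length(comp) > 0) {
      # gradient on the complement: A'A_S w_S - A'b
      g <- AtA[comp, S, drop = FALSE] %*% sol - AtB[comp, idx, drop = FALSE]
      grad_ok <- colSums(g < -tol * scale) == 0
    }
    feas <- colSums(sol < -tol * scale) == 0 & grad_ok
    if (any(feas)) {
      hit <- idx[feas]
      W[S, hit] <- pmax(sol[, feas, drop = FALSE], 0)
      unsolved[hit] <- FALSE
    }
  }
  if (any(unsolved)) {
    stop("NNLS failed for ", sum(unsolved), " columns (singular basis?)")
  }
  W
}

# Single right-hand-side convenience wrapper.
nnls_single <- function(A, b, tol = 1e-9) {
  drop(nnls_multi(A, matrix(b, ncol = 1), tol = tol))
}
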