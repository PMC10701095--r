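# Internal numerics: topological sort, weighted delete-one-block jackknife
# (Busing-Meijer-van der Leeden formulae, the ADMIXTOOLS convention), and a
# guarded non-negative least-squares solve.

# per-block sums over 1..nb blocks, zero-filled for empty blocks
# (rowsum() silently drops groups with no members)
.blockSums <- function(x, b, nb) {
  x <- as.matrix(x)
  agg <- rowsum(x, b)
  out <- matrix(0, nb, ncol(x))
  out[as.integer(rownames(agg)), ] <- agg
  colnames(out) <- colnames(x)
  out
}

# topological order of nodes given an edge data.frame(from, to); NA if cyclic
topoSortNodes <- function(edges) {
  nodes <- union(edges$from, edges$to)
  indeg <- table(factor(edges$to, levels = nodes))
  order <- character(0)
  active <- names(indeg)[indeg == 0L]
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  e_from <- edges$from; e_to <- edges$to
  while (length(active)) {
    v <- active[1L]; active <- active[-1L]
    order <- c(order, v)
    ch <- e_to[e_from == v]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) active <- c(active, c)
    }
  }
  if (length(order) != length(nodes)) return(NA_character_)
  order
}

# Weighted delete-one-block jackknife for a ratio-of-sums estimator.
#   sums:  B x K matrix of per-block numerator sums
#   wts:   length-B denominators (SNP counts per block)
# The estimate is colSums(sums)/sum(wts). Returns estimate, per-statistic SE,
# covariance matrix and the leave-one-out estimates.
jackknifeRatio <- function(sums, wts) {
  sums <- as.matrix(sums)
  used <- wts > 0
  sums <- sums[used, , drop = FALSE]
  w <- wts[used]
  B <- length(w)
  if (B < 2L) stop("need at least 2 non-empty blocks for the jackknife")
  W <- sum(w)
  tot <- colSums(sums)
  est <- tot / W
  loo <- (matrix(tot, B, length(tot), byrow = TRUE) - sums) / (W - w)
  # pseudovalues with unequal block weights
  h <- W / w
  ps <- outer(h, est) - (h - 1) * loo
  center <- colSums((1 - w / W) * loo)
  thetaJ <- B * est - center
  dev <- sweep(ps, 2L, thetaJ)
  covmat <- crossprod(dev / sqrt(h - 1)) / B
  list(estimate = est, se = sqrt(pmax(diag(covmat), 0)), cov = covmat,
       loo = loo, nBlocks = B, thetaJ = thetaJ)
}

# min ||d - C x||^2 + ridge*||x||^2 over x >= 0 (C, d pre-whitened).
# The tiny ridge makes the problem strictly convex: admixture-graph designs
# are structurally rank-deficient (e.g. the two root edges are collinear in
# every f2 contrast). Solved on the normal equations (k is small) with an
# unconstrained fast path and a Lawson-Hanson active set otherwise; this
# sits in the optimizer's inner loop, hence the hand-rolled solver
# (cross-checked against pracma::lsqnonneg in the test suite).
nnlsSolve <- function(C, d, ridge = 1e-8) {
  A <- crossprod(C)
  diag(A) <- diag(A) + ridge * max(diag(A), 1e-300)
  b <- as.numeric(crossprod(C, d))
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(x) && all(x >= -1e-10)) return(pmax(x, 0))
  nnlsActiveSet(A, b)
}

# Lawson-Hanson NNLS on normal equations: min x'Ax/2 - b'x, x >= 0, A SPD
nnlsActiveSet <- function(A, b, maxiter = 50L * length(b)) {
  k <- length(b)
  tol <- 1e-12 * max(abs(b), 1)
  P <- logical(k)
  x <- numeric(k)
  w <- b
  iter <- 0L
  while (any(!P & w > tol) && iter < maxiter) {
    cand <- which(!P & w > tol)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      iter <- iter + 1L
      s <- numeric(k)
      s[P] <- solve(A[P, P, drop = FALSE], b[P])
      if (all(s[P] > tol)) { x <- s; break }
      Q <- P & (s <= tol)
      step <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + step * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
      if (iter >= maxiter) break
    }
    w <- b - as.numeric(A %*% x)
  }
  pmax(x, 0)
}

# regularized inverse-cholesky whitener for a covariance matrix:
# returns U with U'U = (Q + eps*mean(diag)*I)^{-1}
covWhitener <- function(Q, eps = 1e-4) {
  Qr <- Q + diag(eps * mean(diag(Q)), nrow(Q))
  R <- chol(Qr)        # Q = R'R
  backsolve(R, diag(nrow(Q)))  # R^{-1}; (R^{-1})' x gives whitened coords
}

# whitened residual transform: given R_inv from covWhitener, w(v) = t(R_inv) %*% v
whiten <- function(R_inv, v) crossprod(R_inv, v)
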