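# Graph fitting on the f2 basis.
#
# The observed statistic vector is f2 of all leaf pairs, estimated on the
# SNPs where every population has data, with a block-jackknife covariance.
# Branch lengths enter the expectation linearly given the mixing
# proportions, so the generalized least-squares objective is profiled: an
# exact non-negative LS solve over drift lengths inside a low-dimensional
# optimization over the alphas.

#' Per-block f2 moment cache
#'
#' Precomputes, per jackknife block, the cross-moments of population allele
#' frequencies and the heterozygosity-correction sums from which every f2
#' (and f4) block sum is a linear combination. This is the cached basis that
#' full fits, jackknife errors and bootstrap replicates all reuse.
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param blocks a \linkS4class{BlockPartition}
#' @param pops populations to include (default all).
#' @param min_n minimum called chromosomes per population per SNP (default 1:
#'   single pseudo-haploid chromosomes participate; see \code{\link{f2Stat}}).
#' @return an object of class \code{f2basis} (list: populations, per-block
#'   moment matrices, SNP counts).
#' @export
f2Basis <- function(ft, blocks, pops = NULL, min_n = 1L) {
  if (is.null(pops)) pops <- popNames(ft)
  p <- freq(ft)[, pops, drop = FALSE]
  n <- calledTotals(ft)[, pops, drop = FALSE]
  usable <- rowSums(n >= min_n) == length(pops)
  if (!any(usable)) stop("no SNPs with data for all populations")
  p <- p[usable, , drop = FALSE]
  n <- n[usable, , drop = FALSE]
  b <- blockId(blocks)[usable]
  nb <- nBlocks(blocks)
  P <- length(pops)
  pairIdx <- which(upper.tri(diag(P), diag = TRUE), arr.ind = TRUE)
  prods <- p[, pairIdx[, 1L], drop = FALSE] * p[, pairIdx[, 2L], drop = FALSE]
  M <- .blockSums(prods, b, nb)                # B x P(P+1)/2 cross-moments
  corr <- .heterCorr(p, n)
  C <- .blockSums(corr, b, nb)                 # B x P correction sums
  cnt <- tabulate(b, nb)
  idx <- matrix(0L, P, P)
  idx[pairIdx] <- seq_len(nrow(pairIdx))
  idx <- pmax(idx, t(idx))
  dimnames(idx) <- list(pops, pops)
  structure(list(pops = pops, M = M, C = C, n = cnt, idx = idx,
                 nSnps = sum(cnt), pairs = t(combn(pops, 2L))),
            class = "f2basis")
}

#' @export
print.f2basis <- function(x, ...) {
  cat("f2 basis:", length(x$pops), "populations,", x$nSnps, "SNPs,",
      sum(x$n > 0), "non-empty blocks\n")
  invisible(x)
}

# per-block f2 sums for given pairs (2-col matrix), over given block rows
.basisF2Sums <- function(basis, pairs = basis$pairs, rows = NULL) {
  i <- match(pairs[, 1L], basis$pops)
  j <- match(pairs[, 2L], basis$pops)
  M <- basis$M; C <- basis$C
  if (!is.null(rows)) { M <- M[rows, , drop = FALSE]; C <- C[rows, , drop = FALSE] }
  out <- M[, basis$idx[cbind(i, i)], drop = FALSE] +
    M[, basis$idx[cbind(j, j)], drop = FALSE] -
    2 * M[, basis$idx[cbind(i, j)], drop = FALSE] -
    C[, i, drop = FALSE] - C[, j, drop = FALSE]
  colnames(out) <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  out
}

# per-block f4 sums for quadruples (4-col matrix): (a-b)(c-d) terms
.basisF4Sums <- function(basis, quads, rows = NULL) {
  a <- match(quads[, 1L], basis$pops); b <- match(quads[, 2L], basis$pops)
  c_ <- match(quads[, 3L], basis$pops); d <- match(quads[, 4L], basis$pops)
  M <- basis$M
  if (!is.null(rows)) M <- M[rows, , drop = FALSE]
  M[, basis$idx[cbind(a, c_)], drop = FALSE] -
    M[, basis$idx[cbind(a, d)], drop = FALSE] -
    M[, basis$idx[cbind(b, c_)], drop = FALSE] +
    M[, basis$idx[cbind(b, d)], drop = FALSE]
}

#' Observed f2 vector and jackknife covariance from a basis
#'
#' @param basis an \code{f2basis} from \code{\link{f2Basis}}.
#' @param rows optional block indices (with multiplicity) to aggregate over,
#'   e.g. a bootstrap resample; default all blocks.
#' @return list(est = named f2 vector over leaf pairs, cov = jackknife
#'   covariance, n = SNPs).
#' @export
f2Observed <- function(basis, rows = NULL) {
  S <- .basisF2Sums(basis, rows = rows)
  w <- if (is.null(rows)) basis$n else basis$n[rows]
  jk <- jackknifeRatio(S, w)
  list(est = setNames(jk$estimate, colnames(S)), cov = jk$cov,
       n = sum(w), nBlocks = jk$nBlocks)
}

# Precompile a graph + pair set into integer structures so the per-eval
# design computation is pure numeric work (the optimizer calls it hundreds
# of times per fit).
.compileGraph <- function(graph, pairs) {
  e <- graph@edges
  ord <- topoSortNodes(e)
  nid <- seq_along(ord); names(nid) <- ord
  leaves <- graph@leaves
  steps <- list()
  for (v in rev(ord)) {
    idx <- which(e$to == v)
    if (!length(idx)) next
    if (length(idx) == 2L) {
      arow <- match(v, graph@admix$node)
      steps[[length(steps) + 1L]] <- list(
        vi = nid[[v]], kind = 2L, eidx = idx,
        from = nid[e$from[idx]], aidx = arow,
        isp1 = e$from[idx] == graph@admix$parent1[arow])
    } else {
      steps[[length(steps) + 1L]] <- list(
        vi = nid[[v]], kind = 1L, eidx = idx, from = nid[[e$from[idx]]])
    }
  }
  list(nNodes = length(ord), nEdges = nrow(e), steps = steps,
       leafIds = nid[leaves], leaves = leaves,
       driftIdx = which(e$type == "drift"),
       pi = match(pairs[, 1L], leaves), pj = match(pairs[, 2L], leaves))
}

# design matrix (npairs x ndrift) for given alpha vector, from a compiled graph
.designFromCompiled <- function(cg, alphas) {
  nl <- length(cg$leafIds)
  U <- matrix(0, cg$nNodes, nl)
  U[cbind(cg$leafIds, seq_len(nl))] <- 1
  W <- matrix(0, cg$nEdges, nl)
  for (s in cg$steps) {
    uv <- U[s$vi, ]
    if (s$kind == 2L) {
      a <- alphas[s$aidx]
      wt <- ifelse(s$isp1, a, 1 - a)
      W[s$eidx[1L], ] <- wt[1L] * uv
      W[s$eidx[2L], ] <- wt[2L] * uv
      U[s$from[1L], ] <- U[s$from[1L], ] + wt[1L] * uv
      U[s$from[2L], ] <- U[s$from[2L], ] + wt[2L] * uv
    } else {
      W[s$eidx, ] <- uv
      U[s$from, ] <- U[s$from, ] + uv
    }
  }
  Wd <- W[cg$driftIdx, , drop = FALSE]
  t((Wd[, cg$pi, drop = FALSE] - Wd[, cg$pj, drop = FALSE])^2)
}

# GLS objective factory for a fixed whitened observation
.graphObjective <- function(graph, pairs, dw, Wt) {
  cg <- .compileGraph(graph, pairs)
  anames <- graph@admix$node
  function(theta) {
    alphas <- setNames(stats::plogis(theta), anames)
    D <- .designFromCompiled(cg, alphas)
    Cw <- Wt %*% D
    x <- nnlsSolve(Cw, dw)
    r <- dw - Cw %*% x
    structure(sum(r * r), x = x, alphas = alphas)
  }
}

.fitOnce <- function(obj, theta0, maxit, reltol = 1e-9) {
  if (!length(theta0))
    return(list(value = as.numeric(obj(numeric(0))), theta = numeric(0),
                convergence = 0L))
  if (length(theta0) == 1L) {
    op <- optim(theta0, function(t) as.numeric(obj(t)), method = "Brent",
                lower = -8, upper = 8)
    return(list(value = op$value, theta = op$par, convergence = op$convergence))
  }
  op <- optim(theta0, function(t) as.numeric(obj(t)), method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = reltol))
  list(value = op$value, theta = op$par, convergence = op$convergence)
}

#' Fit an admixture graph to observed f2 statistics
#'
#' Minimizes \code{(f_obs - f_exp(theta))' Q^-1 (f_obs - f_exp(theta))} over
#' drift lengths >= 0 and mixing proportions in [0,1] (multi-start local
#' optimization over the logit-alphas; exact non-negative generalized LS over
#' lengths). The covariance is diagonal-regularized before inversion.
#'
#' @param graph an \linkS4class{AdmixtureGraph}; any stored parameter values
#'   seed one of the starts.
#' @param f2_obs named f2 vector covering all leaf pairs (names "A|B"), or a
#'   list with elements \code{est} and \code{cov} as returned by
#'   \code{\link{f2Observed}}.
#' @param Q covariance matrix of f2_obs (ignored when f2_obs is a list).
#' @param basis optional \code{f2basis}; when supplied, the worst f4
#'   residual Z over all leaf quadruples is computed.
#' @param n_starts random multi-starts over the alphas (default 10).
#' @param seed RNG seed for the starts (default 1).
#' @param maxit per-start optimizer iterations (default 300).
#' @return a \linkS4class{GraphFit}.
#' @export
fitGraph <- function(graph, f2_obs, Q = NULL, basis = NULL, n_starts = 10,
                     seed = 1, maxit = 300) {
  if (is.list(f2_obs) && !is.null(f2_obs$est)) { Q <- f2_obs$cov; f2_obs <- f2_obs$est }
  if (is.null(Q)) stop("covariance Q is required")
  pr <- strsplit(names(f2_obs), "|", fixed = TRUE)
  pairs <- cbind(vapply(pr, `[`, "", 1L), vapply(pr, `[`, "", 2L))
  missing <- setdiff(graph@leaves, unique(c(pairs)))
  if (length(missing)) stop("f2_obs lacks leaf(s): ", paste(missing, collapse = ", "))
  R_inv <- covWhitener(Q)
  Wt <- t(R_inv)
  dw <- as.numeric(Wt %*% f2_obs)
  obj <- .graphObjective(graph, pairs, dw, Wt)
  nAdm <- nrow(graph@admix)
  starts <- list()
  if (nAdm) {
    if (!all(is.na(graph@admix$alpha))) {
      a0 <- ifelse(is.na(graph@admix$alpha), 0.5, graph@admix$alpha)
      starts <- c(starts, list(stats::qlogis(pmin(pmax(a0, 0.02), 0.98))))
    }
    withr_seed <- function(expr) { set.seed(seed); expr }
    starts <- c(starts, withr_seed(
      lapply(seq_len(max(n_starts - length(starts), 1L)),
             function(i) stats::qlogis(runif(nAdm, 0.05, 0.95)))))
  } else starts <- list(numeric(0))
  best <- NULL
  for (s in starts) {
    r <- .fitOnce(obj, s, maxit)
    if (is.null(best) || r$value < best$value) best <- r
  }
  o <- obj(best$theta)
  x <- attr(o, "x")
  alphas <- attr(o, "alphas")
  drift <- graph@edges$type == "drift"
  lengths <- setNames(as.numeric(x), .edgeKeys(graph)[drift])
  gfit <- setGraphParams(graph, lengths = lengths,
                         alphas = if (nAdm) alphas else NULL)
  fitted <- as.numeric(graphF2Design(graph, pairs, alphas) %*% x)
  names(fitted) <- names(f2_obs)
  wz <- NA_real_
  f4tab <- NULL
  if (!is.null(basis)) {
    wr <- .worstF4Z(gfit, basis)
    wz <- wr$worstZ; f4tab <- wr$table
  }
  new("GraphFit", graph = gfit, score = as.numeric(o), worstZ = wz,
      converged = best$convergence == 0L,
      alphas = if (nAdm) alphas else setNames(numeric(0), character(0)),
      lengths = lengths,
      details = list(observed = f2_obs, fitted = fitted, f4 = f4tab))
}

# worst |Z| over all leaf f4 quadruples: observed vs model-implied f4
# (the model f4 follows from fitted f2 by the combination identity, in which
# per-leaf sampling inflation cancels)
.worstF4Z <- function(graph, basis) {
  leaves <- graph@leaves
  sets <- combn(leaves, 4L)
  quads <- do.call(rbind, lapply(seq_len(ncol(sets)), function(k) {
    q <- sets[, k]
    rbind(q[c(1, 2, 3, 4)], q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)])
  }))
  S <- .basisF4Sums(basis, quads)
  jk <- jackknifeRatio(S, basis$n)
  F2 <- expectedF2Matrix(graph)
  fitted <- (F2[quads[, c(1, 4)]] + F2[quads[, c(2, 3)]] -
             F2[quads[, c(1, 3)]] - F2[quads[, c(2, 4)]]) / 2
  z <- (jk$estimate - fitted) / jk$se
  tab <- data.frame(A = quads[, 1L], B = quads[, 2L], C = quads[, 3L],
                    D = quads[, 4L], observed = jk$estimate, fitted = fitted,
                    se = jk$se, z = z)
  list(worstZ = max(abs(z)), table = tab)
}

#' Jackknife standard errors of fitted graph parameters
#'
#' Groups the jackknife blocks into \code{n_groups} consecutive super-blocks,
#' refits the graph (warm-started at the full fit) leaving each group out,
#' and applies the weighted delete-one jackknife to the mixing proportions.
#'
#' @param fit a \linkS4class{GraphFit} from \code{\link{fitGraph}}.
#' @param basis the \code{f2basis} the fit used.
#' @param n_groups jackknife groups (default 50).
#' @param maxit optimizer iterations per refit (default 60).
#' @return named numeric: jackknife SE per admixture node.
#' @export
graphAlphaSE <- function(fit, basis, n_groups = 50, maxit = 60) {
  graph <- fit@graph
  if (!nrow(graph@admix)) return(setNames(numeric(0), character(0)))
  nonempty <- which(basis$n > 0)
  n_groups <- min(n_groups, length(nonempty))
  grp <- cut(seq_along(nonempty), n_groups, labels = FALSE)
  theta0 <- stats::qlogis(pmin(pmax(fit@alphas, 1e-6), 1 - 1e-6))
  pairs <- basis$pairs
  loo <- matrix(NA_real_, n_groups, length(theta0))
  wts <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    rows <- nonempty[grp != g]
    ob <- f2Observed(basis, rows = rows)
    R_inv <- covWhitener(ob$cov)
    Wt <- t(R_inv)
    obj <- .graphObjective(graph, pairs, as.numeric(Wt %*% ob$est), Wt)
    r <- .fitOnce(obj, theta0, maxit)
    loo[g, ] <- stats::plogis(r$theta)
    wts[g] <- sum(basis$n[nonempty[grp == g]])
  }
  est <- fit@alphas
  W <- sum(wts)
  h <- W / wts
  ps <- outer(h, est) - (h - 1) * loo
  thetaJ <- n_groups * est - colSums((1 - wts / W) * loo)
  dev <- sweep(ps, 2L, thetaJ)
  se <- sqrt(pmax(colSums(dev^2 / (h - 1)) / n_groups, 0))
  setNames(se, names(fit@alphas))
}

#' Leaf-attachment search on a fitted backbone
#'
#' Enumerates every way of attaching a new leaf to a drift edge of the
#' backbone (splitting the edge at a new node), and optionally every ordered
#' attachment + gene-flow-source edge pair (the new leaf becomes a two-parent
#' admixture node), fits each candidate and ranks by score.
#'
#' @param backbone an \linkS4class{AdmixtureGraph} or \linkS4class{GraphFit}.
#' @param new_leaf population to attach (must be present in the basis).
#' @param basis an \code{f2basis} including the new leaf.
#' @param max_admixture_edges 0 (tree attachments only) or 1.
#' @param n_starts,maxit passed to \code{\link{fitGraph}}.
#' @return data.frame of candidates (attach_edge, flow_edge, score, worst_z)
#'   sorted by score, with the fits in attribute "fits".
#' @export
searchAttachments <- function(backbone, new_leaf, basis,
                              max_admixture_edges = 1, n_starts = 4,
                              maxit = 200) {
  if (is(backbone, "GraphFit")) backbone <- backbone@graph
  ob <- f2Observed(basis)
  de <- which(backbone@edges$type == "drift")
  keys <- .edgeKeys(backbone)
  splitEdge <- function(graph, i, newnode) {
    e <- graph@edges
    mid <- data.frame(from = c(e$from[i], newnode), to = c(newnode, e$to[i]),
                      length = NA_real_, type = "drift")
    drift <- e[-i, , drop = FALSE][e$type[-i] == "drift",
                                   c("from", "to", "length")]
    list(drift = rbind(drift[, c("from", "to")], mid[, c("from", "to")]),
         admix = graph@admix[, c("node", "parent1", "parent2", "alpha")])
  }
  cands <- list(); rows <- list()
  for (i in de) {
    parts <- splitEdge(backbone, i, "ATT")
    drift <- rbind(parts$drift, data.frame(from = "ATT", to = new_leaf))
    g <- admixtureGraph(drift, if (nrow(parts$admix)) parts$admix else NULL)
    cands[[length(cands) + 1L]] <- g
    rows[[length(rows) + 1L]] <- data.frame(attach_edge = keys[i],
                                            flow_edge = NA_character_)
  }
  if (max_admixture_edges >= 1) {
    for (i in de) for (j in de) {
      if (i == j) next
      e <- backbone@edges
      mid <- data.frame(from = c(e$from[i], "ATT", e$from[j], "FLW"),
                        to = c("ATT", e$to[i], "FLW", e$to[j]))
      drift <- rbind(e[-c(i, j), ][e$type[-c(i, j)] == "drift",
                                   c("from", "to")],
                     mid, data.frame(from = "NLMIX", to = new_leaf))
      admix <- rbind(backbone@admix[, c("node", "parent1", "parent2", "alpha")],
                     data.frame(node = "NLMIX", parent1 = "ATT",
                                parent2 = "FLW", alpha = NA_real_))
      g <- tryCatch(admixtureGraph(drift, admix), error = function(e) NULL)
      if (is.null(g)) next
      cands[[length(cands) + 1L]] <- g
      rows[[length(rows) + 1L]] <- data.frame(attach_edge = keys[i],
                                              flow_edge = keys[j])
    }
  }
  fits <- vector("list", length(cands))
  tab <- do.call(rbind, rows)
  tab$score <- tab$worst_z <- NA_real_
  for (k in seq_along(cands)) {
    f <- tryCatch(fitGraph(cands[[k]], ob, basis = basis, n_starts = n_starts,
                           maxit = maxit, seed = k),
                  error = function(e) NULL)
    fits[[k]] <- f
    if (!is.null(f)) { tab$score[k] <- f@score; tab$worst_z[k] <- f@worstZ }
  }
  ord <- order(tab$score)
  tab <- tab[ord, ]
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Bootstrap out-of-bag comparison of two admixture graphs
#'
#' Per replicate: resample jackknife blocks with replacement, refit both
#' graphs on the in-bag blocks (warm-started at the full-data fits), then
#' evaluate each fitted graph's generalized least-squares objective on the
#' out-of-bag blocks (observed f2 and covariance recomputed from those
#' blocks). The empirical P-value is the proportion of replicates in which
#' graph A's out-of-bag objective is at most graph B's (ties favour A, the
#' simpler model by convention).
#'
#' @param graphA,graphB \linkS4class{AdmixtureGraph}s sharing the leaf set
#'   (A conventionally the simpler model).
#' @param basis the shared \code{f2basis}.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param fitA,fitB optional full-data \linkS4class{GraphFit}s used as warm
#'   starts (computed here when absent).
#' @param maxit_replicate optimizer iterations per replicate fit (default 40).
#' @param inbag_cov use in-bag covariance when scoring out-of-bag blocks
#'   instead of the out-of-bag covariance (default FALSE).
#' @return a \linkS4class{ModelComparison}.
#' @export
bootstrapCompare <- function(graphA, graphB, basis, n_replicates = 1000,
                             seed = 1, fitA = NULL, fitB = NULL,
                             maxit_replicate = 40, inbag_cov = FALSE) {
  if (!setequal(graphA@leaves, graphB@leaves))
    stop("graphs must share their leaf set")
  ob <- f2Observed(basis)
  if (is.null(fitA)) fitA <- fitGraph(graphA, ob, seed = seed)
  if (is.null(fitB)) fitB <- fitGraph(graphB, ob, seed = seed + 1L)
  sc <- bootstrapScores(list(A = graphA, B = graphB), basis, n_replicates,
                        seed = seed, fits = list(fitA, fitB),
                        maxit_replicate = maxit_replicate,
                        inbag_cov = inbag_cov)
  new("ModelComparison", labelA = "A", labelB = "B",
      scoresA = sc[, 1L], scoresB = sc[, 2L],
      empiricalP = mean(sc[, 1L] <= sc[, 2L]),
      nReplicates = as.integer(n_replicates))
}

#' Out-of-bag bootstrap scores for a set of graphs on shared replicates
#'
#' The engine behind \code{\link{bootstrapCompare}}: one block-bootstrap
#' replicate stream scored for every graph, so multi-way comparisons (e.g.
#' B-1 against both gene-flow topologies) share their resamples.
#'
#' @param graphs named list of \linkS4class{AdmixtureGraph}s on one leaf set.
#' @param basis the shared \code{f2basis}.
#' @param n_replicates bootstrap replicates.
#' @param seed RNG seed.
#' @param fits list of full-data \linkS4class{GraphFit}s (warm starts),
#'   aligned with \code{graphs}; computed when NULL.
#' @param maxit_replicate optimizer iterations per replicate fit.
#' @param inbag_cov score out-of-bag blocks under the in-bag covariance.
#' @return matrix n_replicates x graphs of out-of-bag objectives
#'   (lower = better).
#' @export
bootstrapScores <- function(graphs, basis, n_replicates, seed = 1,
                            fits = NULL, maxit_replicate = 40,
                            inbag_cov = FALSE) {
  nonempty <- which(basis$n > 0)
  if (length(nonempty) < 10L) stop("need at least 10 non-empty blocks")
  ob <- f2Observed(basis)
  pairs <- matrixPairsFromNames(names(ob$est))
  if (is.null(fits))
    fits <- lapply(seq_along(graphs), function(i)
      fitGraph(graphs[[i]], ob, seed = seed + i))
  pre <- lapply(seq_along(graphs), function(i) {
    list(cg = .compileGraph(graphs[[i]], pairs),
         anames = graphs[[i]]@admix$node,
         th = stats::qlogis(pmin(pmax(fits[[i]]@alphas, 1e-6), 1 - 1e-6)))
  })
  set.seed(seed)
  scores <- matrix(NA_real_, n_replicates, length(graphs),
                   dimnames = list(NULL, names(graphs)))
  redraws <- 0L
  for (r in seq_len(n_replicates)) {
    repeat {
      idx <- sample(nonempty, length(nonempty), replace = TRUE)
      oob <- setdiff(nonempty, unique(idx))
      if (length(oob) >= 2L) break
      redraws <- redraws + 1L
    }
    inb <- f2Observed(basis, rows = idx)
    Wt <- t(covWhitener(inb$cov))
    dwin <- as.numeric(Wt %*% inb$est)
    outb <- f2Observed(basis, rows = oob)
    Wto <- t(covWhitener(if (inbag_cov) inb$cov else outb$cov))
    dwout <- as.numeric(Wto %*% outb$est)
    for (i in seq_along(pre)) {
      p <- pre[[i]]
      obj <- function(theta) {
        alphas <- stats::plogis(theta)
        D <- .designFromCompiled(p$cg, alphas)
        Cw <- Wt %*% D
        x <- nnlsSolve(Cw, dwin)
        structure(sum((dwin - Cw %*% x)^2), x = x, alphas = alphas)
      }
      # small jitter decorrelates optimizer noise between graphs, so the
      # self-comparison of a graph against itself centres at P ~ 0.5
      th0 <- p$th + rnorm(length(p$th), 0, 0.05)
      fr <- .fitOnce(obj, th0, maxit_replicate, reltol = 1e-8)
      o <- obj(fr$theta)
      D <- .designFromCompiled(p$cg, attr(o, "alphas"))
      r2 <- dwout - as.numeric(Wto %*% (D %*% attr(o, "x")))
      scores[r, i] <- sum(r2 * r2)
    }
  }
  if (redraws) message(redraws, " replicate(s) redrawn for empty out-of-bag sets")
  scores
}

# "A|B" names -> 2-column matrix
matrixPairsFromNames <- function(nm) {
  pr <- strsplit(nm, "|", fixed = TRUE)
  cbind(vapply(pr, `[`, "", 1L), vapply(pr, `[`, "", 2L))
}
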