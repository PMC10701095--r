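# qpAdm-style admixture-weight estimation.
#
# For target T, sources s_1..s_m and references r_0..r_{n-1}, the statistic
# matrix is X_ij = f4(s_i, T; r_j, r_0), j = 1..n-1. If T is an m-way
# mixture of the sources' ancestries, there is a weight vector w (summing
# to 1) with E[w'X] = 0. Weights minimize the generalized quadratic form of
# w'X under the block-jackknife covariance (iteratively reweighted closed
# form); the minimized form is the rank-test chi-squared statistic with
# n - m degrees of freedom.

# block sums and usable-count bookkeeping for the f4 battery
.qpadmBlockSums <- function(ft, target, sources, references, blocks) {
  m <- length(sources); n <- length(references)
  specs <- list()
  for (j in 2:n) for (i in seq_len(m))
    specs[[length(specs) + 1L]] <- c("f4", sources[i], target,
                                     references[j], references[1L])
  tms <- lapply(specs, function(s) .fstatTerms(ft, "f4", s[-1L], 1L))
  usable <- Reduce(`&`, lapply(tms, `[[`, "usable"))
  if (!any(usable)) stop("no SNPs usable for the qpAdm f4 battery")
  nb <- nBlocks(blocks)
  b <- blockId(blocks)[usable]
  sums <- vapply(tms, function(tm) .blockSums(tm$term[usable], b, nb)[, 1L],
                 numeric(nb))
  wts <- tabulate(b, nb)
  list(sums = sums, wts = wts, m = m, n = n)
}

.qpadmSolve <- function(xvec, Q, m, n, iters = 8L) {
  X <- matrix(xvec, nrow = m)            # m x (n-1), vec column-major
  w <- rep(1 / m, m)
  degenerate <- FALSE
  for (it in seq_len(iters)) {
    K <- kronecker(diag(n - 1L), t(w))   # (n-1) x m(n-1): rows give w'X
    V <- K %*% Q %*% t(K)
    V <- V + diag(1e-12 * mean(diag(V)) + 1e-30, nrow(V))
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) { degenerate <- TRUE; break }
    M <- X %*% Vi %*% t(X)
    if (rcond(M) < 1e-12) { degenerate <- TRUE; break }
    wn <- solve(M, rep(1, m))
    wn <- wn / sum(wn)
    if (max(abs(wn - w)) < 1e-12) { w <- wn; break }
    w <- wn
  }
  K <- kronecker(diag(n - 1L), t(w))
  V <- K %*% Q %*% t(K)
  Vi <- tryCatch(solve(V + diag(1e-12 * mean(diag(V)), nrow(V))),
                 error = function(e) diag(1 / pmax(diag(V), 1e-30)))
  e <- as.numeric(t(X) %*% w)
  chi2 <- as.numeric(t(e) %*% Vi %*% e)
  list(w = w, chi2 = chi2, degenerate = degenerate)
}

#' qpAdm-style admixture model fit
#'
#' Estimates mixing weights of \code{sources} for \code{target} relative to
#' the reference ("right") populations, with a chi-squared model-fit
#' (rank-test) P-value and block-jackknife weight standard errors. Weights
#' are not constrained to [0,1]; values outside it are reported with a
#' warning as a model-failure diagnostic.
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param target target population.
#' @param sources m >= 1 source populations.
#' @param references n >= m+1 reference populations; the first is the f4 base.
#' @param blocks a \linkS4class{BlockPartition}
#' @return a \linkS4class{QpAdmResult}
#' @export
qpadmFit <- function(ft, target, sources, references, blocks) {
  m <- length(sources); n <- length(references)
  if (m < 1L) stop("need at least one source")
  if (n < m + 1L) stop("need at least m + 1 references")
  pops <- c(target, sources, references)
  if (anyDuplicated(pops)) stop("target, sources and references must be distinct")
  bs <- .qpadmBlockSums(ft, target, sources, references, blocks)
  jk <- jackknifeRatio(bs$sums, bs$wts)
  Q <- jk$cov + diag(1e-4 * mean(diag(jk$cov)), ncol(bs$sums))
  sol <- .qpadmSolve(jk$estimate, Q, m, n)
  dof <- as.integer(n - m)
  p <- pchisq(sol$chi2, df = dof, lower.tail = FALSE)
  # leave-one-block-out weights for the jackknife SE (V held at full fit)
  used <- bs$wts > 0
  loo <- jk$loo                      # B x K leave-one-out f4 vectors
  B <- nrow(loo)
  K <- kronecker(diag(n - 1L), t(sol$w))
  V <- K %*% Q %*% t(K)
  Vi <- solve(V + diag(1e-12 * mean(diag(V)), nrow(V)))
  wloo <- matrix(NA_real_, B, m)
  for (b in seq_len(B)) {
    Xb <- matrix(loo[b, ], nrow = m)
    Mb <- Xb %*% Vi %*% t(Xb)
    wb <- tryCatch(solve(Mb, rep(1, m)), error = function(e) rep(NA_real_, m))
    wloo[b, ] <- wb / sum(wb)
  }
  wts <- bs$wts[used]
  se <- rep(NA_real_, m)
  ok <- stats::complete.cases(wloo)
  if (sum(ok) >= 2L) {
    W <- sum(wts[ok]); h <- W / wts[ok]
    ps <- outer(h, sol$w) - (h - 1) * wloo[ok, , drop = FALSE]
    thetaJ <- sum(ok) * sol$w - colSums((1 - wts[ok] / W) * wloo[ok, , drop = FALSE])
    dev <- sweep(ps, 2L, thetaJ)
    se <- sqrt(pmax(colSums(dev^2 / (h - 1)) / sum(ok), 0))
  }
  if (!sol$degenerate && any(sol$w < -1e-6 | sol$w > 1 + 1e-6))
    warning("qpAdm weights outside [0,1]: likely model misfit")
  if (sol$degenerate) warning("degenerate qpAdm model (non-identifiable sources)")
  new("QpAdmResult", target = target, sources = sources,
      references = references,
      weights = setNames(sol$w, sources), weightSE = setNames(se, sources),
      pValue = if (sol$degenerate) NA_real_ else p, dof = dof,
      nSnps = as.integer(sum(bs$wts)), nBlocks = as.integer(sum(used)),
      details = list(chi2 = sol$chi2, degenerate = sol$degenerate))
}

#' Ghost-lineage proportion via restricted references
#'
#' Estimates the contribution of an unsampled deep ("ghost") lineage to
#' \code{target} by running a 2-source qpAdm fit with
#' \code{sources = c(anchor_source, proxy_source)} against a reference set
#' deliberately restricted to populations that are cladal with the anchor
#' relative to the deep split being proxied. With such references the model
#' cannot distinguish any lineage branching below them, so the proxy's
#' weight estimates the ghost contribution regardless of which deep
#' population stands in as proxy. The caller is responsible for the
#' cladality of the restricted references.
#'
#' @inheritParams qpadmFit
#' @param anchor_source the sampled majority source (e.g. Iran_BronzeAge-like).
#' @param proxy_source any population branching deeper than all references
#'   (e.g. the outgroup).
#' @param restricted_references the restricted reference set (>= 3).
#' @return a \linkS4class{QpAdmResult}; the proxy's weight
#'   (\code{weights[proxy_source]}) is the ghost-lineage estimate.
#' @export
ghostProportion <- function(ft, target, anchor_source, proxy_source,
                            restricted_references, blocks) {
  qpadmFit(ft, target, sources = c(anchor_source, proxy_source),
           references = restricted_references, blocks = blocks)
}

#' Batch qpAdm modeling over targets and model specifications
#'
#' Runs each (target, model) combination; per-row errors are recorded and
#' the batch continues. A model is flagged as failing when its fit P-value
#' is below \code{alpha} (the adequacy rule).
#'
#' @inheritParams qpadmFit
#' @param targets character vector of target populations.
#' @param model_specs named list; each element a list with \code{sources}
#'   (2 populations) and \code{references}.
#' @param alpha adequacy threshold on the fit P-value (default 0.05).
#' @return data.frame: target, model, one weight/SE column pair per source
#'   position, p_value, pass, error.
#' @export
modelBattery <- function(ft, targets, model_specs, blocks, alpha = 0.05) {
  rows <- list()
  for (tg in targets) for (mn in names(model_specs)) {
    spec <- model_specs[[mn]]
    res <- tryCatch(qpadmFit(ft, tg, spec$sources, spec$references, blocks),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, model = mn, source1 = spec$sources[1L],
        source2 = spec$sources[2L], w1 = NA_real_, w2 = NA_real_,
        se1 = NA_real_, se2 = NA_real_, p_value = NA_real_, pass = NA,
        error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, model = mn, source1 = spec$sources[1L],
        source2 = spec$sources[2L], w1 = res@weights[1L], w2 = res@weights[2L],
        se1 = res@weightSE[1L], se2 = res@weightSE[2L], p_value = res@pValue,
        pass = !is.na(res@pValue) && res@pValue >= alpha, error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(target = character(), model = character(),
                      source1 = character(), source2 = character(),
                      w1 = numeric(), w2 = numeric(), se1 = numeric(),
                      se2 = numeric(), p_value = numeric(), pass = logical(),
                      error = character())
  rownames(out) <- NULL
  out
}
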