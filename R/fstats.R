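# Unbiased f2/f3/f4 estimators with weighted block-jackknife errors.
#
# Per-SNP terms (sample frequencies a, b, c, d with called-chromosome counts
# n_a, n_b, ...):
#   f2(A,B)   : (a-b)^2 - a(1-a)/(n_a-1) - b(1-b)/(n_b-1)
#   f3(C;A,B) : (c-a)(c-b) - c(1-c)/(n_c-1)
#   f4(A,B;C,D): (a-b)(c-d)
# Terms are averaged over usable SNPs; the SE comes from the weighted
# delete-one-block jackknife with block SNP counts as weights.

.heterCorr <- function(p, n) {
  # h/(n-1) finite-sample correction; its algebraic limit at n=1 is 0
  # (a single sampled chromosome has p in {0,1}, so p(1-p) = 0)
  ifelse(n >= 2L, p * (1 - p) / pmax(n - 1L, 1L), 0)
}

.fstatTerms <- function(ft, kind, pops, min_n, bias_correction = TRUE) {
  p <- freq(ft)[, pops, drop = FALSE]
  n <- calledTotals(ft)[, pops, drop = FALSE]
  if (kind == "f2") {
    usable <- n[, 1L] >= min_n & n[, 2L] >= min_n
    term <- (p[, 1L] - p[, 2L])^2
    if (bias_correction)
      term <- term - .heterCorr(p[, 1L], n[, 1L]) - .heterCorr(p[, 2L], n[, 2L])
  } else if (kind == "f3") {
    usable <- n[, 1L] >= min_n & n[, 2L] >= 1L & n[, 3L] >= 1L
    term <- (p[, 1L] - p[, 2L]) * (p[, 1L] - p[, 3L])
    if (bias_correction) term <- term - .heterCorr(p[, 1L], n[, 1L])
  } else {
    usable <- n[, 1L] >= 1L & n[, 2L] >= 1L & n[, 3L] >= 1L & n[, 4L] >= 1L
    term <- (p[, 1L] - p[, 2L]) * (p[, 3L] - p[, 4L])
  }
  term[!usable] <- NA_real_
  list(term = term, usable = usable)
}

.fstatJack <- function(term, usable, blocks, kind, pops) {
  if (!any(usable)) stop("no usable SNPs for ", kind, "(",
                         paste(pops, collapse = ","), ")")
  b <- blockId(blocks)[usable]
  t <- term[usable]
  nb <- nBlocks(blocks)
  sums <- .blockSums(t, b, nb)[, 1L]
  wts <- tabulate(b, nb)
  jk <- jackknifeRatio(matrix(sums, ncol = 1L), wts)
  new("FStatResult", kind = kind, pops = pops,
      estimate = jk$estimate, se = jk$se,
      z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
      nSnps = length(t), nBlocks = jk$nBlocks, loo = jk$loo[, 1L])
}

#' f2 statistic between two populations
#'
#' Average squared allele-frequency difference with the finite-sample
#' heterozygosity correction, jackknifed over genetic-map blocks. By default
#' SNPs where either population has fewer than 2 called chromosomes are
#' skipped (\code{min_n = 2}); with \code{min_n = 1} single pseudo-haploid
#' chromosomes are used and their correction term is 0, which inflates each
#' terminal branch by its heterozygosity (absorbed by graph terminal edges
#' and cancelling in all f4 contrasts).
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param A,B population names.
#' @param blocks a \linkS4class{BlockPartition}
#' @param min_n minimum called chromosomes per population (default 2).
#' @param bias_correction apply the h/(n-1) correction (default TRUE).
#' @return an \linkS4class{FStatResult}
#' @export
f2Stat <- function(ft, A, B, blocks, min_n = 2L, bias_correction = TRUE) {
  tm <- .fstatTerms(ft, "f2", c(A, B), min_n, bias_correction)
  .fstatJack(tm$term, tm$usable, blocks, "f2", c(A, B))
}

#' f3 statistic f3(C; A, B)
#'
#' Positive outgroup-f3 values measure drift shared by A and B relative to
#' C; significantly negative admixture-f3 values indicate C is admixed
#' between A- and B-related sources. The heterozygosity correction applies
#' to C only.
#'
#' @inheritParams f2Stat
#' @param C the focal (first) population.
#' @return an \linkS4class{FStatResult}
#' @export
f3Stat <- function(ft, C, A, B, blocks, min_n = 2L, bias_correction = TRUE) {
  tm <- .fstatTerms(ft, "f3", c(C, A, B), min_n, bias_correction)
  .fstatJack(tm$term, tm$usable, blocks, "f3", c(C, A, B))
}

#' f4 statistic f4(A, B; C, D)
#'
#' No bias correction is needed; every SNP where all four populations have at
#' least one called chromosome is used.
#'
#' @inheritParams f2Stat
#' @param C,D second population pair.
#' @return an \linkS4class{FStatResult}
#' @export
f4Stat <- function(ft, A, B, C, D, blocks) {
  tm <- .fstatTerms(ft, "f4", c(A, B, C, D), 1L)
  .fstatJack(tm$term, tm$usable, blocks, "f4", c(A, B, C, D))
}

#' Joint jackknife covariance of a set of f-statistics
#'
#' Statistics are evaluated on the intersection of their usable SNP sets so
#' the block-jackknife covariance is coherent; \code{allsnps = TRUE} instead
#' uses each statistic's own maximal SNP set (covariance then mixes slightly
#' different supports, as in the laxer convention of some tools).
#'
#' @param specs list of character vectors, each \code{c(kind, pops...)},
#'   e.g. \code{c("f4","A","B","C","D")}.
#' @inheritParams f2Stat
#' @param allsnps use per-statistic SNP sets (default FALSE).
#' @return an \linkS4class{FStatCovariance}
#' @export
fstatCovariance <- function(specs, ft, blocks, min_n = 2L, allsnps = FALSE) {
  tms <- lapply(specs, function(s)
    .fstatTerms(ft, s[1L], s[-1L], if (s[1L] == "f4") 1L else min_n))
  usable <- Reduce(`&`, lapply(tms, `[[`, "usable"))
  nb <- nBlocks(blocks)
  labels <- vapply(specs, function(s)
    paste0(s[1L], "(", paste(s[-1L], collapse = ","), ")"), character(1))
  if (allsnps) {
    sums <- vapply(tms, function(tm) {
      t <- tm$term; t[!tm$usable] <- 0
      .blockSums(t, blockId(blocks), nb)[, 1L]
    }, numeric(nb))
    wts <- blockWeights(blocks)
  } else {
    if (!any(usable)) stop("no SNPs usable for all statistics")
    b <- blockId(blocks)[usable]
    sums <- vapply(tms, function(tm) .blockSums(tm$term[usable], b, nb)[, 1L],
                   numeric(nb))
    wts <- tabulate(b, nb)
  }
  if (sum(wts > 0) < 2L) stop("need at least 2 non-empty blocks")
  jk <- jackknifeRatio(sums, wts)
  new("FStatCovariance", labels = labels, estimates = jk$estimate,
      covmat = jk$cov, nBlocks = jk$nBlocks, nSnps = as.integer(sum(wts)))
}

#' Indicine-admixture screen for a taurine target
#'
#' Computes f4(outgroup, indicine_ref; target, taurine_ref) against each
#' taurine reference. A significantly negative Z indicates the target shares
#' more drift with the indicine reference than the taurine reference does,
#' i.e. indicine admixture; the target is called unadmixed when every
#' Z exceeds \code{z_floor} (default -3).
#'
#' @inheritParams f2Stat
#' @param outgroup outgroup population (e.g. African buffalo).
#' @param indicine_ref indicine reference (e.g. Sahiwal).
#' @param target candidate taurine population.
#' @param taurine_refs one or more taurine reference populations.
#' @param z_floor screen threshold on Z (default -3).
#' @return list with \code{table} (per-reference data.frame: taurine_ref,
#'   estimate, se, z, verdict) and \code{unadmixed} (logical).
#' @export
indicineScreen <- function(ft, outgroup, indicine_ref, target, taurine_refs,
                           blocks, z_floor = -3) {
  if (!length(taurine_refs)) stop("need at least one taurine reference")
  rows <- lapply(taurine_refs, function(r) {
    fs <- f4Stat(ft, outgroup, indicine_ref, target, r, blocks)
    data.frame(taurine_ref = r, estimate = fs@estimate, se = fs@se, z = fs@z)
  })
  tab <- do.call(rbind, rows)
  tab$verdict <- ifelse(tab$z > z_floor, "no-admixture-signal", "admixed")
  list(table = tab, unadmixed = all(tab$z > z_floor))
}
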