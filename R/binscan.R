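# Localization scan: per-bin f2 divergence of a target from a composite
# 2-source mixture model, top-quantile bin selection, and outgroup-f4
# enrichment contrasts between the selected bins and the whole genome.

#' Composite model allele frequency
#'
#' Expected target frequency under a 2-source mixture:
#' \code{alpha * p_A + (1 - alpha) * p_B}. Undefined (NA) where either
#' source has no called chromosomes. Weights must sum to exactly 1; no
#' silent renormalization is performed.
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param sources two source populations.
#' @param weights their mixing weights, summing to 1.
#' @return numeric vector of model frequencies per SNP.
#' @export
modelExpectedFreq <- function(ft, sources, weights) {
  if (length(sources) != 2L || length(weights) != 2L)
    stop("exactly two sources and two weights are required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1 (no renormalization)")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0,1]")
  p <- freq(ft)[, sources, drop = FALSE]
  n <- calledTotals(ft)[, sources, drop = FALSE]
  out <- weights[1L] * p[, 1L] + weights[2L] * p[, 2L]
  out[n[, 1L] < 1L | n[, 2L] < 1L] <- NA_real_
  out
}

#' Windowed f2 divergence scan against a composite model
#'
#' Splits the genome into fixed nonoverlapping physical bins anchored at
#' coordinate 0 of each chromosome (half-open intervals) and scores each bin
#' by the mean, over its usable SNPs, of
#' \code{(p_target - p_model)^2 - p_t (1 - p_t) / (n_t - 1)}: the
#' bias-corrected f2 of the target against the model frequency, which is
#' treated as fixed. Bins without usable SNPs are unscored. The top
#' \code{top_fraction} of scored bins (ties broken toward the lower genomic
#' coordinate) are selected for enrichment testing.
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param target target population (must have >= 2 called chromosomes at
#'   scored SNPs).
#' @param model_freq per-SNP composite frequency from
#'   \code{\link{modelExpectedFreq}}.
#' @param bin_sizes bin widths in bp (default 1 kb, 10 kb, 50 kb).
#' @param top_fraction selected quantile (default 0.01).
#' @return named list of \linkS4class{ScanResult}, one per bin size.
#' @export
binF2Scan <- function(ft, target, model_freq,
                      bin_sizes = c(1000, 10000, 50000), top_fraction = 0.01) {
  pt <- freq(ft)[, target]
  nt <- calledTotals(ft)[, target]
  usable <- nt >= 2L & !is.na(model_freq)
  if (!any(usable)) stop("no scorable SNPs")
  term <- (pt - model_freq)^2 - pt * (1 - pt) / pmax(nt - 1L, 1L)
  chrom <- as.character(seqnames(ft@sites))
  pos0 <- start(ft@sites) - 1L  # 0-based coordinate for binning
  chromLevels <- unique(chrom)
  out <- list()
  for (bs in bin_sizes) {
    bin <- floor(pos0 / bs)
    key <- paste0(chrom, ":", bin)
    u <- which(usable)
    agg <- rowsum(cbind(term[u], 1), key[u])
    score <- agg[, 1L] / agg[, 2L]
    parts <- strsplit(rownames(agg), ":", fixed = TRUE)
    bchrom <- vapply(parts, `[`, "", 1L)
    bstart <- as.numeric(vapply(parts, `[`, "", 2L)) * bs
    ord <- order(match(bchrom, chromLevels), bstart)
    bins <- data.frame(chrom = bchrom, start = bstart, end = bstart + bs,
                       score = score, n_snps = agg[, 2L])[ord, ]
    nsel <- ceiling(top_fraction * nrow(bins))
    sel_ord <- order(-bins$score, match(bins$chrom, chromLevels), bins$start)
    bins$selected <- FALSE
    bins$selected[sel_ord[seq_len(nsel)]] <- TRUE
    selkey <- paste0(bins$chrom, ":", bins$start / bs)[bins$selected]
    rownames(bins) <- NULL
    out[[as.character(bs)]] <- new("ScanResult", binSize = as.numeric(bs),
      bins = bins, topFraction = top_fraction,
      snpSelected = key %in% selkey & usable,
      details = list(target = target))
  }
  out
}

# f4(out, X; composite-mix, target) block sums restricted to a SNP subset
.compositeF4 <- function(ft, outgroup, X, model_freq, target, blocks, subset) {
  p <- freq(ft)
  n <- calledTotals(ft)
  usable <- n[, outgroup] >= 1L & n[, X] >= 1L & n[, target] >= 1L &
    !is.na(model_freq) & subset
  if (!any(usable)) stop("no usable SNPs for composite f4")
  term <- (p[, outgroup] - p[, X]) * (model_freq - p[, target])
  b <- blockId(blocks)[usable]
  nb <- nBlocks(blocks)
  sums <- .blockSums(term[usable], b, nb)[, 1L]
  wts <- tabulate(b, nb)
  if (sum(wts > 0) < 2L) stop("SNP subset spans fewer than 2 blocks")
  jk <- jackknifeRatio(matrix(sums, ncol = 1L), wts)
  c(est = jk$estimate, se = jk$se, n = sum(wts))
}

#' Outgroup-f4 enrichment of the selected bins
#'
#' For each panel population X computes
#' f4(outgroup, X; composite-mix, target) on (a) SNPs inside the selected
#' top bins and (b) all SNPs, with block-jackknife SEs restricted to the
#' respective SNP sets, and reports the enrichment delta (top minus
#' genome-wide). A positive delta for X indicates the model-divergent bins
#' are enriched for drift shared between the target and X. Display
#' convention: +/- 3 SE bars.
#'
#' @param ft a \linkS4class{FrequencyTable}
#' @param scan a \linkS4class{ScanResult} from \code{\link{binF2Scan}}.
#' @param outgroup outgroup population.
#' @param panel populations X to contrast.
#' @param sources,weights the composite model (as in
#'   \code{\link{modelExpectedFreq}}).
#' @param target target population.
#' @param blocks a \linkS4class{BlockPartition}
#' @return data.frame: X, f4_top, se_top, f4_genomewide, se_genomewide,
#'   delta, n_snps_top, n_snps_genomewide.
#' @export
enrichmentF4 <- function(ft, scan, outgroup, panel, sources, weights, target,
                         blocks) {
  if (!length(panel)) stop("panel must be non-empty")
  mf <- modelExpectedFreq(ft, sources, weights)
  sel <- scan@snpSelected
  rows <- lapply(panel, function(X) {
    top <- .compositeF4(ft, outgroup, X, mf, target, blocks, sel)
    gw <- .compositeF4(ft, outgroup, X, mf, target, blocks,
                       rep(TRUE, length(sel)))
    data.frame(X = X, f4_top = top["est"], se_top = top["se"],
               f4_genomewide = gw["est"], se_genomewide = gw["se"],
               delta = top["est"] - gw["est"],
               n_snps_top = top["n"], n_snps_genomewide = gw["n"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
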