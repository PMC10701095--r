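# Allele-frequency summarisation, ascertainment-style site filtering and
# genetic-map block partitioning.

#' Per-population derived-allele counts
#'
#' A diploid call k contributes k derived out of 2 called chromosomes; a
#' pseudo-haploid call k in {0,2} contributes k/2 derived out of 1 called
#' chromosome; missing calls contribute nothing.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param populations populations to tabulate (default: all present).
#' @return a \linkS4class{FrequencyTable}
#' @export
alleleFrequencies <- function(gt, populations = NULL) {
  pop <- indPop(gt)
  if (is.null(populations)) populations <- unique(pop)
  unknown <- setdiff(populations, pop)
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  g <- calls(gt)
  ph <- isPseudohaploid(gt)
  counts <- totals <- matrix(0L, nrow(g), length(populations),
                             dimnames = list(rownames(g), populations))
  for (p in populations) {
    dip <- g[, pop == p & !ph, drop = FALSE]
    hap <- g[, pop == p & ph, drop = FALSE]
    cnt <- numeric(nrow(g))
    tot <- integer(nrow(g))
    if (ncol(dip)) {
      cnt <- cnt + rowSums(dip, na.rm = TRUE)
      tot <- tot + 2L * as.integer(rowSums(!is.na(dip)))
    }
    if (ncol(hap)) {
      cnt <- cnt + rowSums(hap, na.rm = TRUE) / 2
      tot <- tot + as.integer(rowSums(!is.na(hap)))
    }
    counts[, p] <- as.integer(round(cnt))
    totals[, p] <- tot
  }
  new("FrequencyTable", counts = counts, totals = totals, sites = rowRanges(gt))
}

#' Ascertainment-style site filtering
#'
#' Applies, in order: the transversions-only rule, minor-allele-frequency
#' thresholds computed separately in the cattle and outgroup groups (a SNP is
#' dropped when its MAF falls below the threshold in either group),
#' missingness thresholds per group (fraction of individuals without a call),
#' and finally the close-spacing rule: scanning left to right within each
#' chromosome over the SNPs that survived the other filters, a SNP is dropped
#' when the next SNP to its right is closer than \code{min_spacing_bp}.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param cattle_pops,outgroup_pops disjoint, non-empty population sets.
#' @param maf_cattle,maf_outgroup MAF floors (defaults 0.05 / 0.15).
#' @param miss_cattle,miss_outgroup missingness ceilings (defaults 0.2 / 0.6).
#' @param min_spacing_bp minimum distance to the next retained SNP (52 bp).
#' @param transversions_only drop A<->G and C<->T SNPs (default TRUE).
#' @return the filtered \linkS4class{GenotypeTable} (possibly 0 rows).
#' @export
filterSites <- function(gt, cattle_pops, outgroup_pops,
                        maf_cattle = 0.05, maf_outgroup = 0.15,
                        miss_cattle = 0.2, miss_outgroup = 0.6,
                        min_spacing_bp = 52, transversions_only = TRUE) {
  if (!length(cattle_pops) || !length(outgroup_pops))
    stop("both population sets must be non-empty")
  if (length(intersect(cattle_pops, outgroup_pops)))
    stop("cattle and outgroup population sets must be disjoint")
  keep <- rep(TRUE, nrow(gt))
  if (transversions_only) {
    pair <- paste0(pmin(rowRanges(gt)$ref, rowRanges(gt)$alt),
                   pmax(rowRanges(gt)$ref, rowRanges(gt)$alt))
    keep <- keep & !(pair %in% c("AG", "CT"))
  }
  grpStats <- function(pops) {
    ft <- alleleFrequencies(gt, pops)
    cnt <- rowSums(derivedCounts(ft))
    tot <- rowSums(calledTotals(ft))
    f <- ifelse(tot > 0, cnt / tot, NA_real_)
    maf <- pmin(f, 1 - f)
    idx <- indPop(gt) %in% pops
    miss <- rowMeans(is.na(calls(gt)[, idx, drop = FALSE]))
    list(maf = maf, miss = miss)
  }
  ca <- grpStats(cattle_pops)
  og <- grpStats(outgroup_pops)
  keep <- keep &
    !is.na(ca$maf) & ca$maf >= maf_cattle &
    !is.na(og$maf) & og$maf >= maf_outgroup &
    ca$miss <= miss_cattle & og$miss <= miss_outgroup
  # spacing rule, left to right within chromosome over survivors
  if (min_spacing_bp > 0 && any(keep)) {
    idx <- which(keep)
    chrom <- snpChrom(gt)[idx]
    pos <- snpPos(gt)[idx]
    n <- length(idx)
    if (n > 1L) {
      same <- chrom[-n] == chrom[-1L]
      close <- same & (pos[-1L] - pos[-n] < min_spacing_bp)
      keep[idx[c(close, FALSE)]] <- FALSE
    }
  }
  gt[keep, ]
}

#' Partition SNPs into contiguous genetic-map blocks
#'
#' Blocks are maximal runs of consecutive SNPs spanning at most
#' \code{block_size_cM} centimorgans of genetic distance; they never cross a
#' chromosome boundary. Where no genetic map is stored, positions are
#' converted at \code{fallback_cM_per_Mb}.
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param block_size_cM block span in cM (default 5).
#' @param fallback_cM_per_Mb map rate used when the map column is absent.
#' @return a \linkS4class{BlockPartition}
#' @export
makeBlocks <- function(gt, block_size_cM = 5, fallback_cM_per_Mb = 1.0) {
  if (block_size_cM <= 0) stop("block size must be positive")
  gpos <- gposCM(gt, fallback_cM_per_Mb)
  chrom <- snpChrom(gt)
  block <- integer(length(gpos))
  bid <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    g <- gpos[i]
    if (g[length(g)] - g[1L] < block_size_cM) {  # whole chromosome fits
      bid <- bid + 1L
      block[i] <- bid
      next
    }
    anchor <- -Inf
    for (k in seq_along(i)) {
      if (g[k] - anchor >= block_size_cM) { bid <- bid + 1L; anchor <- g[k] }
      block[i[k]] <- bid
    }
  }
  new("BlockPartition", block = block,
      weights = as.integer(tabulate(block, bid)),
      blockSizeCM = as.numeric(block_size_cM))
}
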