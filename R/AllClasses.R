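#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom stats pchisq optim rnorm rbinom runif rexp sd var setNames
#' @importFrom utils head read.table write.table combn
NULL

# ---------------------------------------------------------------------------
# GenotypeTable
# ---------------------------------------------------------------------------

#' GenotypeTable: per-SNP, per-individual genotype codes
#'
#' Container for diploid / pseudo-haploid genotype calls, built on
#' \linkS4class{RangedSummarizedExperiment}. Rows are SNPs (with chromosome,
#' physical position, alleles and optional genetic position in cM), columns
#' are individuals (with population label and a pseudo-haploid flag). Calls
#' count derived/alt alleles: 0/1/2 for diploids, 0/2 for pseudo-haploid
#' individuals (one sampled chromosome), NA for missing.
#'
#' @export
setClass("GenotypeTable", contains = "RangedSummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  cd <- colData(object)
  if (!all(c("pop", "pseudohaploid") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'pop' and 'pseudohaploid'")
  if (length(msg)) return(msg)
  g <- assay(object, "calls")
  bad <- !(is.na(g) | g == 0L | g == 1L | g == 2L)
  if (any(bad)) msg <- c(msg, "calls must be in {0,1,2,NA}")
  ph <- cd$pseudohaploid
  if (any(ph) && any(g[, ph, drop = FALSE] == 1L, na.rm = TRUE))
    msg <- c(msg, "pseudo-haploid individuals must not carry genotype code 1")
  chrom <- as.character(seqnames(rowRanges(object)))
  pos <- start(rowRanges(object))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      msg <- c(msg, sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param calls integer matrix, SNPs x individuals, codes in {0,1,2,NA}
#'   (NA = missing; code 9 is accepted and mapped to NA).
#' @param chrom chromosome label per SNP.
#' @param pos_bp 1-based physical position per SNP.
#' @param ind_id individual identifiers.
#' @param pop population label per individual.
#' @param pseudohaploid logical per individual; pseudo-haploid calls are
#'   restricted to {0,2,NA} and represent a single sampled chromosome.
#' @param snp_id SNP identifiers (default "snp1"...).
#' @param ref,alt reference / alternative allele per SNP.
#' @param gcM genetic position in centimorgans per SNP (NA if no map).
#' @return a \linkS4class{GenotypeTable}.
#' @export
GenotypeTable <- function(calls, chrom, pos_bp, ind_id, pop, pseudohaploid,
                          snp_id = NULL, ref = NULL, alt = NULL, gcM = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  calls[calls == 9L] <- NA_integer_
  n <- nrow(calls)
  if (is.null(snp_id))
    snp_id <- if (n) paste0("snp", seq_len(n)) else character(0)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("C", n)
  if (is.null(gcM)) gcM <- rep(NA_real_, n)
  rr <- GRanges(seqnames = as.character(chrom), ranges = IRanges(pos_bp, width = 1L))
  S4Vectors::mcols(rr) <- DataFrame(snp_id = as.character(snp_id),
                                    ref = as.character(ref),
                                    alt = as.character(alt),
                                    gcM = as.numeric(gcM))
  names(rr) <- snp_id
  cd <- DataFrame(pop = as.character(pop),
                  pseudohaploid = as.logical(pseudohaploid),
                  row.names = as.character(ind_id))
  dimnames(calls) <- list(snp_id, as.character(ind_id))
  se <- SummarizedExperiment(assays = list(calls = calls), rowRanges = rr, colData = cd)
  new("GenotypeTable", se)
}

#' @describeIn GenotypeTable genotype call matrix (SNPs x individuals)
#' @param x,object a GenotypeTable
#' @export
calls <- function(x) assay(x, "calls")

#' @describeIn GenotypeTable population label per individual
#' @export
indPop <- function(x) setNames(colData(x)$pop, colnames(x))

#' @describeIn GenotypeTable pseudo-haploid flag per individual
#' @export
isPseudohaploid <- function(x) setNames(colData(x)$pseudohaploid, colnames(x))

#' @describeIn GenotypeTable chromosome label per SNP
#' @export
snpChrom <- function(x) as.character(seqnames(rowRanges(x)))

#' @describeIn GenotypeTable physical position (bp) per SNP
#' @export
snpPos <- function(x) start(rowRanges(x))

#' Genetic positions in centimorgans
#'
#' Returns the per-SNP genetic position, applying the constant-rate fallback
#' \code{pos_bp * fallback_cM_per_Mb / 1e6} where the map column is absent or
#' degenerate (all zero / all missing).
#'
#' @param x a GenotypeTable
#' @param fallback_cM_per_Mb map rate used when no genetic map is stored
#'   (default 1 cM/Mb).
#' @export
gposCM <- function(x, fallback_cM_per_Mb = 1.0) {
  g <- rowRanges(x)$gcM
  if (all(is.na(g)) || all(g[!is.na(g)] == 0))
    return(snpPos(x) * fallback_cM_per_Mb / 1e6)
  g
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object), "SNPs x", ncol(object), "individuals\n")
  pops <- table(colData(object)$pop)
  cat("  populations:", paste0(names(pops), "(", pops, ")", collapse = ", "), "\n")
  nph <- sum(colData(object)$pseudohaploid)
  if (nph) cat("  pseudo-haploid individuals:", nph, "\n")
  has_map <- !(all(is.na(rowRanges(object)$gcM)))
  cat("  genetic map:", if (has_map) "present" else "absent (1 cM/Mb fallback)", "\n")
})

# ---------------------------------------------------------------------------
# FrequencyTable
# ---------------------------------------------------------------------------

#' FrequencyTable: per-population derived-allele counts
#'
#' Per population and SNP, the number of chromosomes carrying the derived
#' allele and the number of chromosomes genotyped (a diploid individual
#' contributes 2, a pseudo-haploid individual 1). The sample frequency is
#' defined only where \code{totals >= 1}.
#'
#' @slot counts integer matrix SNPs x populations, derived-allele chromosomes.
#' @slot totals integer matrix SNPs x populations, called chromosomes.
#' @slot sites GRanges of the SNPs (chromosome, position, alleles, gcM).
#' @export
setClass("FrequencyTable",
         representation(counts = "matrix", totals = "matrix", sites = "GRanges"))

setValidity("FrequencyTable", function(object) {
  if (!identical(dim(object@counts), dim(object@totals)))
    return("counts and totals must have identical dimensions")
  if (any(object@counts < 0 | object@counts > object@totals, na.rm = TRUE))
    return("need 0 <= derived_count <= total_called")
  if (nrow(object@counts) != length(object@sites))
    return("sites length must match row count")
  TRUE
})

#' @describeIn FrequencyTable sample allele frequencies (NaN where no data)
#' @param x a FrequencyTable
#' @export
freq <- function(x) x@counts / x@totals

#' @describeIn FrequencyTable population names
#' @export
popNames <- function(x) colnames(x@counts)

#' @describeIn FrequencyTable derived-allele counts matrix
#' @export
derivedCounts <- function(x) x@counts

#' @describeIn FrequencyTable called-chromosome totals matrix
#' @export
calledTotals <- function(x) x@totals

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable:", nrow(object@counts), "SNPs x",
      ncol(object@counts), "populations\n")
  cat("  populations:", paste(colnames(object@counts), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# BlockPartition
# ---------------------------------------------------------------------------

#' BlockPartition: contiguous jackknife blocks
#'
#' Assigns every SNP to a contiguous block spanning at most
#' \code{blockSizeCM} centimorgans; blocks never cross chromosomes. Block
#' SNP counts serve as jackknife weights.
#'
#' @slot block integer block id per SNP (1..nBlocks).
#' @slot weights integer SNPs per block.
#' @slot blockSizeCM block span in centimorgans.
#' @export
setClass("BlockPartition",
         representation(block = "integer", weights = "integer",
                        blockSizeCM = "numeric"))

setValidity("BlockPartition", function(object) {
  b <- object@block
  if (length(b) && (min(b) < 1L || max(b) > length(object@weights)))
    return("block ids out of range")
  if (length(b) > 1L && any(diff(b) < 0L))
    return("blocks must be contiguous runs over the SNP order")
  if (!identical(as.integer(tabulate(b, length(object@weights))), object@weights))
    return("weights must equal per-block SNP counts")
  TRUE
})

#' @describeIn BlockPartition number of blocks
#' @param x a BlockPartition
#' @export
nBlocks <- function(x) length(x@weights)

#' @describeIn BlockPartition block id per SNP
#' @export
blockId <- function(x) x@block

#' @describeIn BlockPartition SNP count per block
#' @export
blockWeights <- function(x) x@weights

setMethod("show", "BlockPartition", function(object) {
  cat("BlockPartition:", length(object@block), "SNPs in",
      length(object@weights), "blocks (<=", object@blockSizeCM, "cM)\n")
})

# ---------------------------------------------------------------------------
# FStatResult / FStatCovariance
# ---------------------------------------------------------------------------

#' FStatResult: one f-statistic with block-jackknife uncertainty
#'
#' @slot kind "f2", "f3" or "f4".
#' @slot pops population arguments in order.
#' @slot estimate point estimate (drift units).
#' @slot se weighted delete-one-block jackknife standard error.
#' @slot z estimate / se.
#' @slot nSnps SNPs used.
#' @slot nBlocks blocks containing at least one used SNP.
#' @slot loo leave-one-block-out estimates (one per used block).
#' @export
setClass("FStatResult",
         representation(kind = "character", pops = "character",
                        estimate = "numeric", se = "numeric", z = "numeric",
                        nSnps = "integer", nBlocks = "integer", loo = "numeric"))

setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s(%s) = %.6g  se %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              object@kind, paste(object@pops, collapse = ", "),
              object@estimate, object@se, object@z,
              object@nSnps, object@nBlocks))
})

#' FStatCovariance: a vector of f-statistics with jackknife covariance
#'
#' @slot labels statistic labels.
#' @slot estimates point estimates.
#' @slot covmat jackknife covariance matrix over blocks.
#' @slot nBlocks blocks used.
#' @slot nSnps shared SNPs used.
#' @export
setClass("FStatCovariance",
         representation(labels = "character", estimates = "numeric",
                        covmat = "matrix", nBlocks = "integer", nSnps = "integer"))

setMethod("show", "FStatCovariance", function(object) {
  cat("FStatCovariance:", length(object@estimates), "statistics,",
      object@nBlocks, "blocks,", object@nSnps, "shared SNPs\n")
})

# ---------------------------------------------------------------------------
# AdmixtureGraph / GraphFit / ModelComparison
# ---------------------------------------------------------------------------

#' AdmixtureGraph: rooted admixture graph with drift lengths
#'
#' A rooted directed acyclic graph whose leaves are populations. Ordinary
#' nodes have one parent; admixture nodes have exactly two parents and a
#' mixing proportion alpha (the weight of the first parent). Edges into
#' admixture nodes ("mix" edges) carry no drift; every other edge carries a
#' drift length in f2 units (NA while unset).
#'
#' @slot edges data.frame with columns from, to, type ("drift"/"mix"),
#'   length (numeric, NA = free).
#' @slot admix data.frame with columns node, parent1, parent2, alpha.
#' @slot root root node name.
#' @slot leaves leaf population names.
#' @export
setClass("AdmixtureGraph",
         representation(edges = "data.frame", admix = "data.frame",
                        root = "character", leaves = "character"))

setValidity("AdmixtureGraph", function(object) {
  e <- object@edges
  msg <- character()
  nodes <- union(e$from, e$to)
  indeg <- table(factor(e$to, levels = nodes))
  adm <- object@admix$node
  if (any(indeg[adm] != 2L)) msg <- c(msg, "admixture nodes need exactly 2 parents")
  if (any(indeg[setdiff(nodes, adm)] > 1L))
    msg <- c(msg, "non-admixture nodes may have at most one parent")
  if (sum(indeg == 0L) != 1L) msg <- c(msg, "graph must have a single root")
  if (nrow(object@admix) &&
      any(!is.na(object@admix$alpha) &
          (object@admix$alpha < 0 | object@admix$alpha > 1)))
    msg <- c(msg, "alpha must lie in [0,1]")
  if (any(!is.na(e$length) & e$length < 0)) msg <- c(msg, "drift lengths must be >= 0")
  # acyclicity via topological sort
  if (is.na(topoSortNodes(e)[1])) msg <- c(msg, "graph must be acyclic")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdmixtureGraph", function(object) {
  cat("AdmixtureGraph:", length(object@leaves), "leaves,",
      nrow(object@edges), "edges,", nrow(object@admix), "admixture nodes\n")
  cat("  leaves:", paste(object@leaves, collapse = ", "), "\n")
  if (nrow(object@admix))
    for (i in seq_len(nrow(object@admix)))
      cat(sprintf("  %s = %s %s + %s %s\n", object@admix$node[i],
                  format(object@admix$alpha[i]), object@admix$parent1[i],
                  format(1 - object@admix$alpha[i]), object@admix$parent2[i]))
})

#' GraphFit: a fitted admixture graph
#'
#' @slot graph the graph with fitted lengths and alphas filled in.
#' @slot score generalized least-squares objective at the optimum (>= 0;
#'   the "likelihood score" convention is -score, higher is better).
#' @slot worstZ largest |observed - fitted| / SE over all leaf f4 quadruples.
#' @slot converged optimizer convergence flag.
#' @slot alphas fitted mixing proportions (named by admixture node).
#' @slot lengths fitted drift lengths (named "from->to").
#' @slot details list: fitted/observed f2 vectors, per-quadruple f4 z table.
#' @export
setClass("GraphFit",
         representation(graph = "AdmixtureGraph", score = "numeric",
                        worstZ = "numeric", converged = "logical",
                        alphas = "numeric", lengths = "numeric",
                        details = "list"))

setMethod("show", "GraphFit", function(object) {
  cat(sprintf("GraphFit: score %.4g (likelihood score %.4g), worst |Z| %.2f%s\n",
              object@score, -object@score, object@worstZ,
              if (object@converged) "" else " [not converged]"))
  if (length(object@alphas))
    cat("  alphas:", paste(sprintf("%s=%.3f", names(object@alphas), object@alphas),
                           collapse = ", "), "\n")
})

#' ModelComparison: bootstrap out-of-bag comparison of two graphs
#'
#' Empirical P is the fraction of block-bootstrap replicates in which the
#' simpler graph A scores at least as well as graph B on held-out blocks
#' (ties count in favour of A).
#'
#' @slot labelA,labelB graph labels.
#' @slot scoresA,scoresB per-replicate out-of-bag objectives (lower = better).
#' @slot empiricalP fraction of replicates with objective(A) <= objective(B).
#' @slot nReplicates bootstrap replicates performed.
#' @export
setClass("ModelComparison",
         representation(labelA = "character", labelB = "character",
                        scoresA = "numeric", scoresB = "numeric",
                        empiricalP = "numeric", nReplicates = "integer"))

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison %s vs %s: empirical P = %.4g (%d replicates)\n",
              object@labelA, object@labelB, object@empiricalP, object@nReplicates))
})

# ---------------------------------------------------------------------------
# QpAdmResult
# ---------------------------------------------------------------------------

#' QpAdmResult: qpAdm-style admixture-weight estimate
#'
#' @slot target target population.
#' @slot sources source populations.
#' @slot references reference ("right") populations; the first is the base.
#' @slot weights mixing proportions (sum to 1; may leave [0,1]).
#' @slot weightSE block-jackknife standard error per source.
#' @slot pValue chi-squared tail probability of the rank (model-fit) test.
#' @slot dof degrees of freedom, (#references - 1) - (#sources - 1).
#' @slot nSnps,nBlocks data used.
#' @slot details list (chi-squared statistic, degeneracy flag, ...).
#' @export
setClass("QpAdmResult",
         representation(target = "character", sources = "character",
                        references = "character", weights = "numeric",
                        weightSE = "numeric", pValue = "numeric",
                        dof = "integer", nSnps = "integer", nBlocks = "integer",
                        details = "list"))

setMethod("show", "QpAdmResult", function(object) {
  cat(sprintf("QpAdmResult: %s = %s\n", object@target,
              paste(sprintf("%.3f (+/-%.3f) %s", object@weights,
                            object@weightSE, object@sources), collapse = " + ")))
  cat(sprintf("  model-fit P = %.4g (dof %d, %d SNPs, %d blocks)\n",
              object@pValue, object@dof, object@nSnps, object@nBlocks))
  if (isTRUE(object@details$degenerate))
    cat("  WARNING: degenerate model (non-identifiable sources)\n")
})

# ---------------------------------------------------------------------------
# DemographyModel
# ---------------------------------------------------------------------------

#' DemographyModel: explicit demography for coalescent simulation
#'
#' Population splits and pulse admixtures on a fixed effective size, with
#' times in years before present converted to generations by integer-rounded
#' division by the generation time.
#'
#' @slot populations data.frame name, Ne.
#' @slot splits data.frame time_gen, ancestral, derived (comma-separated pair).
#' @slot pulses data.frame time_gen, dest, source, proportion (forward-time
#'   semantics: dest receives proportion from source at time_gen).
#' @slot samples data.frame pop, n, pseudohaploid (pseudo-haploid samples are
#'   single chromosomes emitted as 0/2 genotype individuals); an optional
#'   time_gen column sets per-population sampling ages in generations
#'   (default 0).
#' @slot mutationRate,recombinationRate per bp per generation.
#' @slot generationTime years per generation.
#' @export
setClass("DemographyModel",
         representation(populations = "data.frame", splits = "data.frame",
                        pulses = "data.frame", samples = "data.frame",
                        mutationRate = "numeric", recombinationRate = "numeric",
                        generationTime = "numeric"))

setValidity("DemographyModel", function(object) {
  msg <- character()
  if (nrow(object@pulses) &&
      any(object@pulses$proportion <= 0 | object@pulses$proportion >= 1))
    msg <- c(msg, "pulse proportions must lie in (0,1)")
  if (nrow(object@splits) && any(object@splits$time_gen <= 0))
    msg <- c(msg, "split times must be positive")
  # each pulse's dest and source demes must exist (not yet merged) at pulse time
  if (nrow(object@pulses)) {
    born <- function(p) { # time above which deme p no longer exists
      hit <- vapply(seq_len(nrow(object@splits)), function(i)
        p %in% strsplit(object@splits$derived[i], ",")[[1]], logical(1))
      if (any(hit)) min(object@splits$time_gen[hit]) else Inf
    }
    for (i in seq_len(nrow(object@pulses))) {
      if (object@pulses$time_gen[i] >= born(object@pulses$dest[i]) ||
          object@pulses$time_gen[i] >= born(object@pulses$source[i]))
        msg <- c(msg, sprintf("pulse %d outside the lifetime of its demes", i))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DemographyModel", function(object) {
  cat("DemographyModel:", nrow(object@populations), "demes,",
      nrow(object@splits), "splits,", nrow(object@pulses), "pulses\n")
  cat(sprintf("  mu %.3g, r %.3g /bp/gen, generation %g yr\n",
              object@mutationRate, object@recombinationRate, object@generationTime))
})

# ---------------------------------------------------------------------------
# ScanResult
# ---------------------------------------------------------------------------

#' ScanResult: windowed f2 divergence scan
#'
#' Per-bin f2 divergence of a target population from a composite
#' (mixture-model) allele frequency, with the top-quantile bin selection
#' used for outgroup-f4 enrichment contrasts.
#'
#' @slot binSize bin width in bp.
#' @slot bins data.frame chrom, start (0-based), end, score, n_snps, selected.
#' @slot topFraction quantile selected (default 0.01).
#' @slot snpSelected logical per scored SNP: lies in a selected bin.
#' @slot details list (target, sources, weights).
#' @export
setClass("ScanResult",
         representation(binSize = "numeric", bins = "data.frame",
                        topFraction = "numeric", snpSelected = "logical",
                        details = "list"))

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d scored bins of %g bp; top %g%% selected (%d bins)\n",
              nrow(object@bins), object@binSize, 100 * object@topFraction,
              sum(object@bins$selected)))
})
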