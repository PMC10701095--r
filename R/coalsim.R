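# Explicit demographies for the Muturu introgression robustness experiment
# and the simulation harness around them. Simulation itself is carried out
# by msprime through the bundled worker script (inst/python); this module
# owns the demography encoding, the EIGENSTRAT round trip and the
# false-positive / false-negative experiment.

#' Build one of the B-1/B-2/B-3 demographies
#'
#' Encodes the cattle/aurochs demography behind the three competing Muturu
#' topologies: constant Ne 10,000 for every deme, 6-year generations, splits
#' (years BP): African buffalo 300,000 (or 3,000,000), indicine-taurine
#' 180,000, deep taurine 60,000, British aurochs 36,000, Armenian 24,000,
#' Moroccan 15,000, Sahiwal's taurine donor 9,000, Muturu 6,000, plus the
#' Muturu-donor split at 3,600 (from the Moroccan lineage, B-2) or 30,000
#' (from the deep-taurine lineage, B-3); pulses: taurine into Sahiwal 20%
#' at 6,000, deep taurine into the Moroccan aurochs 40% at 12,000, and into
#' Muturu 40% at 3,000 from the Moroccan lineage (B-2) or 20% at 3,000 from
#' the deep-taurine lineage (B-3). Years convert to generations by rounded
#' division by 6.
#'
#' @param topology "B-1" (no gene flow into Muturu), "B-2" or "B-3".
#' @param buffalo_split "300kya" or "3Mya".
#' @param extra_taurine_refs also emit two clean taurine reference demes
#'   ("BalkanLike" split 12,000 yBP, 4 pseudo-haploid samples; "ShimaoLike"
#'   split 7,000 yBP, 2 pseudo-haploid samples), cladal with IranBronzeAge
#'   relative to the deep-taurine split; used by the restricted-reference
#'   ghost-proportion benchmark.
#' @param Ne effective size for every deme (default 10,000).
#' @param generation_time years per generation (default 6).
#' @param mutation_rate,recombination_rate per bp per generation (defaults
#'   1.25e-8 and 1.6e-8).
#' @return a \linkS4class{DemographyModel} with the printed sample sizes:
#'   AfricanBuffalo 2 diploid, Sahiwal 2 diploid, Armenian/British/Moroccan
#'   aurochs 1 pseudo-haploid each, IranBronzeAge 2 pseudo-haploid,
#'   Muturu 9 diploid. All samples are drawn at time 0 (no archaeological
#'   ages are specified for the simulated ancients); an optional
#'   \code{time_gen} column in the samples slot overrides this per
#'   population.
#' @export
buildDemography <- function(topology = c("B-1", "B-2", "B-3"),
                            buffalo_split = c("300kya", "3Mya"),
                            extra_taurine_refs = FALSE, Ne = 10000,
                            generation_time = 6, mutation_rate = 1.25e-8,
                            recombination_rate = 1.6e-8) {
  topology <- match.arg(topology)
  buffalo_split <- match.arg(buffalo_split)
  g <- function(yBP) as.integer(round(yBP / generation_time))
  buf_y <- if (buffalo_split == "300kya") 3e5 else 3e6
  sp <- function(time_gen, ancestral, derived)
    data.frame(time_gen = time_gen, ancestral = ancestral,
               derived = paste(derived, collapse = ","))
  # In B-2 the Moroccan lineage needs an explicit ancestor deme (it both
  # receives the deep pulse and later sheds the Muturu donor); in B-3 the
  # deep-taurine lineage needs an explicit Moroccan-bound branch deme.
  # Splits must not leave a pulse pointing at a deme that is already the
  # ancestral side of an earlier (more recent) split.
  mor_deme <- if (topology == "B-2") "MoroccanAncestor" else "MoroccanAurochs"
  deep_donor <- if (topology == "B-3") "DeepTaurineMor" else "DeepTaurine"
  splits <- rbind(
    if (extra_taurine_refs) rbind(
      sp(g(6000), "MAIN7", c("Muturu", "IranBronzeAge")),
      sp(g(7000), "MAIN9", c("ShimaoLike", "MAIN7")),
      sp(g(9000), "MAIN12", c("SahiwalDonor", "MAIN9")),
      sp(g(12000), "MAIN15", c("BalkanLike", "MAIN12")))
    else rbind(
      sp(g(6000), "MAIN9", c("Muturu", "IranBronzeAge")),
      sp(g(9000), "MAIN15", c("SahiwalDonor", "MAIN9"))),
    sp(g(15000), "MAIN24", c(mor_deme, "MAIN15")),
    sp(g(24000), "MAIN36", c("ArmenianAurochs", "MAIN24")),
    sp(g(36000), "MAIN60", c("BritishAurochs", "MAIN36")),
    sp(g(60000), "TAUR", c("DeepTaurine", "MAIN60")),
    sp(g(180000), "CATTLE", c("Sahiwal", "TAUR")),
    sp(g(buf_y), "ROOT", c("AfricanBuffalo", "CATTLE")))
  pulses <- rbind(
    data.frame(time_gen = g(6000), dest = "Sahiwal", source = "SahiwalDonor",
               proportion = 0.20),
    data.frame(time_gen = g(12000), dest = mor_deme,
               source = deep_donor, proportion = 0.40))
  if (topology == "B-2") {
    splits <- rbind(sp(g(3600), "MoroccanAncestor",
                       c("MoroccanAurochs", "MuturuDonor")), splits)
    pulses <- rbind(pulses, data.frame(time_gen = g(3000), dest = "Muturu",
                                       source = "MuturuDonor", proportion = 0.40))
  } else if (topology == "B-3") {
    splits <- rbind(sp(g(30000), "DeepTaurine",
                       c("DeepTaurineMor", "MuturuDonor")), splits)
    pulses <- rbind(pulses, data.frame(time_gen = g(3000), dest = "Muturu",
                                       source = "MuturuDonor", proportion = 0.20))
  }
  splits <- splits[order(splits$time_gen), ]
  demes <- unique(c(unlist(strsplit(splits$derived, ",")), splits$ancestral))
  samples <- data.frame(
    pop = c("AfricanBuffalo", "Sahiwal", "ArmenianAurochs", "BritishAurochs",
            "MoroccanAurochs", "IranBronzeAge", "Muturu"),
    n = c(2L, 2L, 1L, 1L, 1L, 2L, 9L),
    pseudohaploid = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  if (extra_taurine_refs)
    samples <- rbind(samples,
                     data.frame(pop = c("BalkanLike", "ShimaoLike"),
                                n = c(4L, 2L), pseudohaploid = TRUE))
  new("DemographyModel",
      populations = data.frame(name = demes, Ne = Ne),
      splits = splits, pulses = pulses, samples = samples,
      mutationRate = mutation_rate, recombinationRate = recombination_rate,
      generationTime = generation_time)
}

#' Simulate a genotype dataset under a demography
#'
#' Runs the coalescent with recombination (msprime) over \code{n_regions}
#' unlinked regions, retains biallelic segregating sites, emits
#' pseudo-haploid populations as single-chromosome individuals with 0/2
#' calls, and assigns each region its own chromosome label so that one
#' region forms one jackknife block (50 kb spans 0.05 cM at the 1 cM/Mb
#' fallback map, far below the 5-cM block span).
#'
#' @param demography a \linkS4class{DemographyModel}.
#' @param n_regions independent regions (default 800).
#' @param region_length region length in bp (default 50,000).
#' @param seed simulation seed; the same seed reproduces the dataset exactly.
#' @param python python interpreter (default "python").
#' @return a \linkS4class{GenotypeTable}.
#' @export
simulateDataset <- function(demography, n_regions = 800, region_length = 50000,
                            seed = 1, python = "python") {
  if (n_regions < 1L || region_length < 1L)
    stop("n_regions and region_length must be >= 1")
  validObject(demography)
  script <- system.file("python", "coalsim_msprime.py", package = "admixscan")
  if (!nzchar(script)) stop("bundled simulation worker not found")
  tmp <- tempfile("coalsim")
  spec <- list(
    populations = lapply(seq_len(nrow(demography@populations)), function(i)
      list(name = demography@populations$name[i],
           Ne = demography@populations$Ne[i])),
    splits = lapply(seq_len(nrow(demography@splits)), function(i)
      list(time = demography@splits$time_gen[i],
           ancestral = demography@splits$ancestral[i],
           derived = as.list(strsplit(demography@splits$derived[i], ",")[[1]]))),
    pulses = lapply(seq_len(nrow(demography@pulses)), function(i)
      as.list(demography@pulses[i, ])),
    samples = lapply(seq_len(nrow(demography@samples)), function(i)
      as.list(demography@samples[i, ])),  # optional time_gen passes through
    n_regions = n_regions, region_length = region_length,
    mutation_rate = demography@mutationRate,
    recombination_rate = demography@recombinationRate,
    seed = seed, out_prefix = tmp)
  specfile <- paste0(tmp, ".json")
  jsonlite::write_json(spec, specfile, auto_unbox = TRUE, digits = NA)
  on.exit(unlink(paste0(tmp, c(".json", ".geno", ".snp", ".ind"))), add = TRUE)
  out <- system2(python, c(script, specfile), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("simulation worker failed:\n", paste(out, collapse = "\n"))
  nsites <- suppressWarnings(as.integer(out[length(out)]))
  if (!is.na(nsites) && nsites == 0L) {
    ind <- read.table(paste0(tmp, ".ind"), stringsAsFactors = FALSE)
    return(GenotypeTable(matrix(integer(0), 0L, nrow(ind)),
                         chrom = character(0), pos_bp = integer(0),
                         ind_id = ind[[1]], pop = ind[[3]],
                         pseudohaploid = ind[[4]] == "PH"))
  }
  readEigenstrat(tmp)
}

#' False-positive / false-negative experiment for the introgression signal
#'
#' Simulates \code{n_datasets} genotype datasets under the true topology,
#' fits the relevant graphs to each, runs the block-bootstrap out-of-bag
#' model comparison of B-1 against each gene-flow topology, and tabulates
#' error rates at level \code{alpha}. Under truth B-1 a false positive is a
#' dataset where a gene-flow graph fits significantly better (empirical
#' P < alpha); under truth B-2/B-3 a false negative is a dataset where B-1
#' survives (empirical P >= alpha).
#'
#' @param true_topology "B-1", "B-2" or "B-3".
#' @param buffalo_split "300kya" or "3Mya".
#' @param n_datasets simulated datasets (the full-scale experiment uses 100).
#' @param n_boot bootstrap replicates per comparison (full scale 1000).
#' @param alpha significance level (default 0.05).
#' @param seed master seed; per-dataset seeds derive from it and are logged.
#' @param n_regions,region_length per-dataset simulation size.
#' @param n_starts multi-starts for the full-data graph fits.
#' @param boot_maxit optimizer iterations per bootstrap replicate fit
#'   (replicates are warm-started at the full-data fit, so a small budget
#'   suffices; default 40).
#' @param verbose print per-dataset progress.
#' @return list with \code{rates} (data.frame: comparison, errors, n, rate)
#'   and \code{details} (per-dataset seeds, empirical P-values, and the
#'   fitted mixing proportions of the true graph, for parameter-recovery
#'   summaries).
#' @export
fpfnExperiment <- function(true_topology = c("B-1", "B-2", "B-3"),
                           buffalo_split = c("300kya", "3Mya"),
                           n_datasets = 100, n_boot = 1000, alpha = 0.05,
                           seed = 1, n_regions = 800, region_length = 50000,
                           n_starts = 6, boot_maxit = 40, verbose = FALSE) {
  true_topology <- match.arg(true_topology)
  buffalo_split <- match.arg(buffalo_split)
  dem <- buildDemography(true_topology, buffalo_split)
  alts <- if (true_topology == "B-1") c("B-2", "B-3") else true_topology
  set.seed(seed)
  dseeds <- sample.int(2^31 - 2, n_datasets)
  details <- vector("list", n_datasets)
  emp <- matrix(NA_real_, n_datasets, length(alts),
                dimnames = list(NULL, alts))
  for (d in seq_len(n_datasets)) {
    gt <- simulateDataset(dem, n_regions, region_length, seed = dseeds[d])
    ft <- alleleFrequencies(gt)
    blocks <- makeBlocks(gt)
    basis <- f2Basis(ft, blocks, min_n = 1L)
    ob <- f2Observed(basis)
    graphs <- setNames(lapply(unique(c("B-1", alts)), function(tp)
      muturuGraph(tp, with_truth = TRUE, buffalo_split = buffalo_split)),
      unique(c("B-1", alts)))
    fits <- lapply(graphs, fitGraph, f2_obs = ob, n_starts = n_starts,
                   seed = dseeds[d] %% 1000L + 1L)
    sc <- bootstrapScores(graphs, basis, n_boot,
                          seed = dseeds[d] %% 100000L + 1L, fits = fits,
                          maxit_replicate = boot_maxit)
    for (a in alts) emp[d, a] <- mean(sc[, "B-1"] <= sc[, a])
    details[[d]] <- list(seed = dseeds[d], empiricalP = emp[d, ],
                         alphas = lapply(fits, slot, "alphas"),
                         scores = vapply(fits, slot, numeric(1), "score"))
    if (verbose)
      message(sprintf("dataset %d/%d: %s", d, n_datasets,
                      paste(sprintf("P[%s]=%.3f", alts, emp[d, ]),
                            collapse = " ")))
  }
  if (true_topology == "B-1") {
    rates <- data.frame(
      comparison = paste0("FP vs ", alts),
      errors = colSums(emp < alpha), n = n_datasets,
      rate = colMeans(emp < alpha))
  } else {
    rates <- data.frame(
      comparison = paste0("FN (", true_topology, ")"),
      errors = sum(emp[, 1L] >= alpha), n = n_datasets,
      rate = mean(emp[, 1L] >= alpha))
  }
  rownames(rates) <- NULL
  list(rates = rates, details = details, alpha = alpha,
       true_topology = true_topology, buffalo_split = buffalo_split)
}
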