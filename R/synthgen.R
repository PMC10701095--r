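# Fast synthetic-data generators with the statistical structure the
# analyses assume: allele frequencies drifting along an admixture graph
# (SNPs independent by design) and segment-mosaic genomes with a minor
# third ancestry in short tracts. Pure functions of (spec, seed).

#' Simulate genotypes by drift along an admixture graph
#'
#' Root frequencies are drawn per SNP from Uniform(0.05, 0.95); along each
#' drift edge the child frequency is a normal perturbation with variance
#' c_e (the edge's drift length in f2 units), clamped to [0,1]; an admixture
#' node's frequency is the alpha-weighted average of its parents. Because
#' frequency increments are additive with per-edge variance c_e, the
#' expected f2 between any two leaves equals \code{\link{expectedF2Matrix}}
#' of the generating graph exactly (the generator and the expectation are
#' mutual oracles); clamping at the [0,1] boundary is the only source of
#' bias and is negligible for c_e <= 0.2 with the default root-frequency
#' law. The p(1-p) scaling of Wright-Fisher drift is intentionally dropped
#' for this exactness; use the coalescent harness when realistic drift
#' scaling matters. Genotypes are binomial draws given the final leaf
#' frequencies, with optional missingness; pseudo-haploid samples draw one
#' chromosome (calls 0/2).
#'
#' @param graph an \linkS4class{AdmixtureGraph} with all parameters set.
#' @param n_snps number of independent SNPs.
#' @param samples data.frame pop, n, pseudohaploid (defaults: 10 diploids
#'   per leaf).
#' @param missingness per-call missing probability in [0,1).
#' @param seed RNG seed.
#' @param root_freq_range range of the root-frequency uniform law.
#' @param snp_spacing_bp physical spacing of consecutive SNPs on the single
#'   synthetic chromosome (default 10,000 bp, i.e. 0.01 cM at the fallback
#'   map rate, so 5-cM jackknife blocks hold 500 SNPs).
#' @return a \linkS4class{GenotypeTable}.
#' @export
driftSim <- function(graph, n_snps, samples = NULL, missingness = 0,
                     seed = 1, root_freq_range = c(0.05, 0.95),
                     snp_spacing_bp = 10000) {
  if (anyNA(graph@edges$length) ||
      (nrow(graph@admix) && anyNA(graph@admix$alpha)))
    stop("graph parameters must be fully set")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0,1)")
  set.seed(seed)
  leaves <- graph@leaves
  if (is.null(samples))
    samples <- data.frame(pop = leaves, n = 10L, pseudohaploid = FALSE)
  ord <- topoSortNodes(graph@edges)
  fr <- matrix(NA_real_, n_snps, length(ord), dimnames = list(NULL, ord))
  fr[, graph@root] <- runif(n_snps, root_freq_range[1L], root_freq_range[2L])
  e <- graph@edges
  a <- setNames(graph@admix$alpha, graph@admix$node)
  for (v in ord[-1L]) {
    idx <- which(e$to == v)
    if (length(idx) == 2L) {
      arow <- match(v, graph@admix$node)
      f1 <- fr[, graph@admix$parent1[arow]]
      f2 <- fr[, graph@admix$parent2[arow]]
      fr[, v] <- a[v] * f1 + (1 - a[v]) * f2
    } else {
      p <- fr[, e$from[idx]]
      ce <- e$length[idx]
      fr[, v] <- pmin(pmax(p + rnorm(n_snps, 0, sqrt(ce)), 0), 1)
    }
  }
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(samples))) {
    pop <- samples$pop[i]
    if (!pop %in% leaves) stop("sample population is not a leaf: ", pop)
    for (k in seq_len(samples$n[i])) {
      g <- if (samples$pseudohaploid[i]) 2L * rbinom(n_snps, 1L, fr[, pop])
           else rbinom(n_snps, 2L, fr[, pop])
      if (missingness > 0)
        g[runif(n_snps) < missingness] <- NA_integer_
      cols[[length(cols) + 1L]] <- g
      meta[[length(meta) + 1L]] <- data.frame(
        ind_id = paste0(pop, k), pop = pop,
        pseudohaploid = samples$pseudohaploid[i])
    }
  }
  meta <- do.call(rbind, meta)
  GenotypeTable(do.call(cbind, cols), chrom = rep("1", n_snps),
                pos_bp = seq_len(n_snps) * snp_spacing_bp,
                ind_id = meta$ind_id, pop = meta$pop,
                pseudohaploid = meta$pseudohaploid)
}

#' Simulate segment-mosaic target genomes
#'
#' Generates allele frequencies for four panels (major sources A and B, a
#' minor donor X and a distant outgroup) on a fixed star-like topology, then
#' builds each target haplotype as a positional mosaic: minor-donor tracts
#' with exponentially distributed lengths (mean \code{tract_mean_bp})
#' covering an expected genome fraction \code{phi}, and the remainder split
#' between A and B ancestry in long blocks (mean \code{major_block_bp}) with
#' probabilities alpha and 1-alpha. Alleles are drawn from the local
#' ancestry's panel frequency; two haplotypes form one diploid target.
#'
#' @param chrom_length_bp chromosome length (default 5 Mb).
#' @param snp_spacing_bp SNP spacing (default 500 bp).
#' @param alpha major-mixture weight of source A.
#' @param phi expected minor-donor genome fraction in [0,1).
#' @param tract_mean_bp mean minor tract length (default 5,000 bp).
#' @param major_block_bp mean major-ancestry block length (default 100 kb).
#' @param n_targets diploid target individuals (default 10).
#' @param n_panel diploid individuals per source/outgroup panel (default 10).
#' @param drift list of diffusion-scaled drift parameters (variance of a
#'   frequency step is p(1-p) times the parameter): out, split, x, a, b.
#'   Defaults give closely related major sources and a deeply diverged
#'   minor donor, the regime the scan targets.
#' @param seed RNG seed.
#' @return a \linkS4class{GenotypeTable} with populations Target, SourceA,
#'   SourceB, DonorX and Outgroup; \code{metadata()$realized_phi} records
#'   the realized minor fraction.
#' @export
mosaicSim <- function(chrom_length_bp = 5e6, snp_spacing_bp = 500,
                      alpha = 0.6, phi = 0.05, tract_mean_bp = 5000,
                      major_block_bp = 1e5, n_targets = 10, n_panel = 10,
                      drift = list(out = 0.3, split = 0.05, x = 1.0,
                                   a = 0.01, b = 0.01),
                      seed = 1) {
  if (phi < 0 || phi >= 1) stop("phi must be in [0,1)")
  if (tract_mean_bp <= 0) stop("tract mean must be positive")
  if (tract_mean_bp >= chrom_length_bp)
    warning("degenerate spec: mean tract length >= chromosome length")
  set.seed(seed)
  pos <- seq(snp_spacing_bp, chrom_length_bp, by = snp_spacing_bp)
  n <- length(pos)
  # panel frequencies: ((A,B),X) vs Outgroup star
  p0 <- runif(n, 0.05, 0.95)
  drift1 <- function(p, c) pmin(pmax(p + rnorm(n, 0, sqrt(p * (1 - p) * c)), 0), 1)
  pOut <- drift1(p0, drift$out)
  pC1 <- drift1(p0, drift$split)
  pX <- drift1(pC1, drift$x)
  pA <- drift1(pC1, drift$a)
  pB <- drift1(pC1, drift$b)
  freqs <- cbind(A = pA, B = pB, X = pX, O = pOut)
  # ancestry painting of one haplotype: 1=A, 2=B, 3=X.
  # Minor tracts follow an alternating renewal process: tract lengths are
  # exponential with mean tract_mean_bp, inter-tract gaps exponential with
  # mean tract_mean_bp*(1-phi)/phi, so minor coverage has expectation phi.
  # Major (A/B) ancestry switches in blocks of mean major_block_bp inside
  # the gaps. Segments are generated as a breakpoint stream and mapped to
  # SNPs in one findInterval pass.
  paintHap <- function() {
    lens <- numeric(0); states <- integer(0)
    cur <- 0
    gap_mean <- if (phi > 0) tract_mean_bp * (1 - phi) / phi else Inf
    repeat {
      glen <- if (is.finite(gap_mean)) rexp(1, 1 / gap_mean)
              else chrom_length_bp - cur
      gend <- min(cur + glen, chrom_length_bp)
      while (cur < gend) {
        blen <- min(rexp(1, 1 / major_block_bp), gend - cur)
        lens <- c(lens, blen)
        states <- c(states, if (runif(1) < alpha) 1L else 2L)
        cur <- cur + blen
      }
      if (cur >= chrom_length_bp) break
      tlen <- min(rexp(1, 1 / tract_mean_bp), chrom_length_bp - cur)
      lens <- c(lens, tlen)
      states <- c(states, 3L)
      cur <- cur + tlen
      if (cur >= chrom_length_bp) break
    }
    cuts <- cumsum(lens)
    states[findInterval(pos - 0.5, cuts) + 1L]
  }
  cols <- list(); meta <- list(); minor_snps <- 0; total_snps <- 0
  for (k in seq_len(n_targets)) {
    h1 <- paintHap(); h2 <- paintHap()
    a1 <- rbinom(n, 1L, freqs[cbind(seq_len(n), pmin(h1, 3L))])
    a2 <- rbinom(n, 1L, freqs[cbind(seq_len(n), pmin(h2, 3L))])
    minor_snps <- minor_snps + sum(h1 == 3L) + sum(h2 == 3L)
    total_snps <- total_snps + 2L * n
    cols[[length(cols) + 1L]] <- a1 + a2
    meta[[length(meta) + 1L]] <- data.frame(ind_id = paste0("Target", k),
                                            pop = "Target",
                                            pseudohaploid = FALSE)
  }
  panels <- c(SourceA = "A", SourceB = "B", DonorX = "X", Outgroup = "O")
  for (pi in seq_along(panels)) {
    pname <- names(panels)[pi]
    for (k in seq_len(n_panel)) {
      cols[[length(cols) + 1L]] <- rbinom(n, 2L, freqs[, panels[[pi]]])
      meta[[length(meta) + 1L]] <- data.frame(
        ind_id = paste0(pname, k), pop = pname, pseudohaploid = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  gt <- GenotypeTable(do.call(cbind, cols), chrom = rep("1", n), pos_bp = pos,
                      ind_id = meta$ind_id, pop = meta$pop,
                      pseudohaploid = meta$pseudohaploid)
  metadata(gt)$realized_phi <- minor_snps / total_snps
  metadata(gt)$alpha <- alpha
  gt
}
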