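# Shared fixtures, all built in code.

# small genotype table with diploid + pseudo-haploid individuals and
# missingness, deterministic in seed
toyGenotypes <- function(n_snps = 200, seed = 42) {
  set.seed(seed)
  pops <- c(A = 4L, B = 3L, C = 3L, D = 2L)
  ph <- c(A = FALSE, B = FALSE, C = TRUE, D = FALSE)
  cols <- list(); ids <- character(); popv <- character(); phv <- logical()
  p <- matrix(runif(n_snps * length(pops), 0.1, 0.9), n_snps)
  for (i in seq_along(pops)) {
    for (k in seq_len(pops[i])) {
      g <- if (ph[i]) 2L * rbinom(n_snps, 1L, p[, i])
           else rbinom(n_snps, 2L, p[, i])
      g[runif(n_snps) < 0.1] <- NA_integer_
      cols[[length(cols) + 1L]] <- g
      ids <- c(ids, paste0(names(pops)[i], k))
      popv <- c(popv, names(pops)[i])
      phv <- c(phv, ph[i])
    }
  }
  GenotypeTable(do.call(cbind, cols), chrom = rep("1", n_snps),
                pos_bp = seq_len(n_snps) * 1000L, ind_id = ids, pop = popv,
                pseudohaploid = phv)
}

# literal per-SNP loop oracle for f2/f3/f4 point estimates (no blocks)
bruteFStat <- function(ft, kind, pops, min_n = 2L, bias_correction = TRUE) {
  p <- freq(ft); n <- calledTotals(ft)
  terms <- c()
  for (s in seq_len(nrow(p))) {
    ns <- n[s, pops]
    ps <- p[s, pops]
    corr <- function(i) {
      if (ns[i] >= 2) ps[i] * (1 - ps[i]) / (ns[i] - 1) else 0
    }
    if (kind == "f2") {
      if (ns[1] < min_n || ns[2] < min_n) next
      t <- (ps[1] - ps[2])^2
      if (bias_correction) t <- t - corr(1) - corr(2)
    } else if (kind == "f3") {
      if (ns[1] < min_n || any(ns[2:3] < 1)) next
      t <- (ps[1] - ps[2]) * (ps[1] - ps[3])
      if (bias_correction) t <- t - corr(1)
    } else {
      if (any(ns < 1)) next
      t <- (ps[1] - ps[2]) * (ps[3] - ps[4])
    }
    terms <- c(terms, t)
  }
  mean(terms)
}

# 8-population graph in which Tgt is a true 30/70 admixture of SA- and
# SB-related ancestries, with a clean outgroup + 4 references
qpadmMixGraph <- function(alpha = 0.3, c0 = 0.01) {
  de <- data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2", "N3", "N3", "N4", "N4",
             "A1", "N5", "N5", "B1", "MIX"),
    to = c("Out", "N1", "R0", "N2", "R1", "N3", "R2", "N4", "A1", "N5",
           "SA", "B1", "R3", "SB", "Tgt"),
    length = c0)
  admixtureGraph(de, data.frame(node = "MIX", parent1 = "A1", parent2 = "B1",
                                alpha = alpha))
}

qpadmMixSamples <- function(n = 10L)
  data.frame(pop = c("Out", "R0", "R1", "R2", "R3", "SA", "SB", "Tgt"),
             n = n, pseudohaploid = FALSE)

# two-clade graph: taurine-like T with references, indicine clade holding a
# true source I1 (with sister reference RI) and a diverged wrong source I2;
# TgtAdm is (1-beta) T-side + beta I1-side, TgtPure is a pure T-side branch
batteryGraph <- function(beta = 0.5, c0 = 0.01) {
  de <- data.frame(
    from = c("root", "root", "N0", "N0", "NT", "NT", "NTa", "NTa", "NTb",
             "NTb", "NI", "NI", "NI1", "NI1", "I1a", "MIX"),
    to = c("Out", "N0", "NT", "NI", "RT1", "NTa", "RT2", "NTb", "T",
           "TgtPure", "I2", "NI1", "RI1", "I1a", "I1", "Tgt"),
    length = c0)
  de$length[de$to == "I2"] <- 0.08  # deeply diverged wrong source
  admixtureGraph(de, data.frame(node = "MIX", parent1 = "NTb", parent2 = "I1a",
                                alpha = 1 - beta))
}

muturuPops <- c("AfricanBuffalo", "Sahiwal", "ArmenianAurochs",
                "BritishAurochs", "MoroccanAurochs", "IranBronzeAge", "Muturu")

# combined-SE z for an enrichment delta row
deltaZ <- function(e) e$delta / sqrt(e$se_top^2 + e$se_genomewide^2)
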