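test_that("f2/f3/f4 estimators equal the per-SNP brute-force loop", {
  gt <- toyGenotypes(200)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 0.02)  # 20-kb blocks over the 200-kb toy chromosome
  expect_equal(f2Stat(ft, "A", "B", bl)@estimate,
               bruteFStat(ft, "f2", c("A", "B")), tolerance = 1e-12)
  expect_equal(f3Stat(ft, "C", "A", "B", bl)@estimate,
               bruteFStat(ft, "f3", c("C", "A", "B")), tolerance = 1e-12)
  expect_equal(f4Stat(ft, "A", "B", "C", "D", bl)@estimate,
               bruteFStat(ft, "f4", c("A", "B", "C", "D")), tolerance = 1e-12)
  expect_equal(f2Stat(ft, "A", "B", bl, min_n = 1L, bias_correction = FALSE)@estimate,
               bruteFStat(ft, "f2", c("A", "B"), 1L, FALSE), tolerance = 1e-12)
})

test_that("fixed difference gives f2 = 1 and self-f2 carries only the correction", {
  mk <- function(countsA, countsB, totA, totB) {
    counts <- cbind(A = countsA, B = countsB)
    totals <- cbind(A = totA, B = totB)
    new("FrequencyTable", counts = counts, totals = totals,
        sites = GenomicRanges::GRanges(rep("1", length(countsA)),
                                       IRanges::IRanges(seq_along(countsA) * 1e6, width = 1)))
  }
  bl2 <- new("BlockPartition", block = c(1L, 2L), weights = c(1L, 1L),
             blockSizeCM = 0.5)
  fixed <- mk(c(10L, 10L), c(0L, 0L), c(10L, 10L), c(10L, 10L))
  expect_equal(f2Stat(fixed, "A", "B", bl2)@estimate, 1.0)
  same <- mk(c(5L, 5L), c(5L, 5L), c(10L, 10L), c(10L, 10L))
  expect_equal(f2Stat(same, "A", "B", bl2)@estimate, -2 * 0.25 / 9,
               tolerance = 1e-12)
})

test_that("f4 is zero on duplicated pairs, antisymmetric, and an f2 combination", {
  gt <- toyGenotypes(300, seed = 9)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 0.05)
  expect_equal(f4Stat(ft, "A", "B", "C", "C", bl)@estimate, 0)
  expect_equal(f4Stat(ft, "A", "B", "C", "D", bl)@estimate,
               -f4Stat(ft, "B", "A", "C", "D", bl)@estimate, tolerance = 1e-12)
  # f4(A,B;C,D) = [f2(A,D)+f2(B,C)-f2(A,C)-f2(B,D)]/2 with uncorrected f2
  # on the SNPs where all four populations are called
  n <- calledTotals(ft)
  shared <- rowSums(n[, c("A", "B", "C", "D")] >= 1L) == 4L
  ft2 <- new("FrequencyTable", counts = derivedCounts(ft)[shared, ],
             totals = calledTotals(ft)[shared, ], sites = ft@sites[shared])
  blk <- blockId(bl)[shared]
  bl2 <- new("BlockPartition", block = blk,
             weights = as.integer(tabulate(blk, nBlocks(bl))),
             blockSizeCM = bl@blockSizeCM)
  u <- function(x, y) f2Stat(ft2, x, y, bl2, min_n = 1L,
                             bias_correction = FALSE)@estimate
  lhs <- f4Stat(ft2, "A", "B", "C", "D", bl2)@estimate
  expect_equal(lhs, (u("A", "D") + u("B", "C") - u("A", "C") - u("B", "D")) / 2,
               tolerance = 1e-12)
})

test_that("f3 vanishes when the focal population equals both others", {
  counts <- cbind(C = rep(500L, 40), A = rep(500L, 40), B = rep(500L, 40))
  totals <- cbind(C = 1000L, A = 1000L, B = 1000L)[rep(1, 40), ]
  colnames(totals) <- c("C", "A", "B")
  ft <- new("FrequencyTable", counts = counts, totals = totals,
            sites = GenomicRanges::GRanges(rep("1", 40),
                                           IRanges::IRanges(1:40 * 1e6, width = 1)))
  bl <- new("BlockPartition", block = rep(1:4, each = 10L),
            weights = rep(10L, 4), blockSizeCM = 5)
  # only the -c(1-c)/(n-1) correction remains: -0.25/999
  expect_equal(f3Stat(ft, "C", "A", "B", bl)@estimate, -0.25 / 999,
               tolerance = 1e-12)
})

test_that("outgroup f3 recovers the focal branch drift on a star phylogeny", {
  g <- admixtureGraph(data.frame(from = c("root", "root", "root"),
                                 to = c("C", "A", "B"),
                                 length = c(0.01, 0.004, 0.005)))
  gt <- driftSim(g, 60000, samples = data.frame(pop = c("A", "B", "C"),
                                                n = 25L, pseudohaploid = FALSE),
                 seed = 11, root_freq_range = c(0.15, 0.85))
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt)
  fs <- f3Stat(ft, "C", "A", "B", bl)
  expect_lt(abs(fs@estimate - 0.01), 3.5 * fs@se)
})

test_that("block jackknife matches the classical SE for single-SNP blocks", {
  gt <- toyGenotypes(400, seed = 3)
  ft <- alleleFrequencies(gt)
  bl1 <- new("BlockPartition", block = seq_len(400L),
             weights = rep(1L, 400L), blockSizeCM = 0.001)
  fs <- f2Stat(ft, "A", "B", bl1)
  tm <- admixscan:::.fstatTerms(ft, "f2", c("A", "B"), 2L)
  t <- tm$term[tm$usable]
  classical <- sd(t) / sqrt(length(t))
  expect_equal(fs@se, classical, tolerance = 1e-6)
  expect_equal(fs@z, fs@estimate / fs@se)
  expect_equal(fs@nBlocks, length(t))
})

test_that("joint covariance matches a direct leave-one-block-out oracle", {
  gt <- toyGenotypes(300, seed = 5)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 0.05)
  specs <- list(c("f2", "A", "B"), c("f4", "A", "B", "C", "D"))
  fc <- fstatCovariance(specs, ft, bl)
  expect_true(isSymmetric(fc@covmat))
  # single statistic: 1x1 covariance equal to its jackknife variance on the
  # same (intersected) SNP set
  fc1 <- fstatCovariance(specs[1], ft, bl)
  expect_equal(dim(fc1@covmat), c(1L, 1L))
  # duplicated statistic: rank-1 2x2
  fc2 <- fstatCovariance(list(specs[[1]], specs[[1]]), ft, bl)
  expect_equal(fc2@covmat[1, 1], fc2@covmat[1, 2], tolerance = 1e-12)
  expect_lt(rcond(fc2@covmat), 1e-10)
  # direct oracle: recompute the weighted jackknife from per-block estimates
  tms <- lapply(specs, function(s)
    admixscan:::.fstatTerms(ft, s[1], s[-1], if (s[1] == "f4") 1L else 2L))
  usable <- tms[[1]]$usable & tms[[2]]$usable
  b <- blockId(bl)[usable]
  sums <- vapply(tms, function(tm)
    admixscan:::.blockSums(tm$term[usable], b, nBlocks(bl))[, 1], numeric(nBlocks(bl)))
  wts <- tabulate(b, nBlocks(bl))
  keep <- wts > 0
  est <- colSums(sums[keep, ]) / sum(wts[keep])
  loo <- sapply(1:2, function(k)
    sapply(which(keep), function(bb)
      (sum(sums[keep, k]) - sums[bb, k]) / (sum(wts[keep]) - wts[bb])))
  W <- sum(wts[keep]); h <- W / wts[keep]; B <- sum(keep)
  thetaJ <- B * est - colSums((1 - wts[keep] / W) * loo)
  ps <- outer(h, est) - (h - 1) * loo
  covO <- crossprod(sweep(ps, 2, thetaJ) / sqrt(h - 1)) / B
  expect_equal(unname(fc@covmat), unname(covO), tolerance = 1e-10)
})

test_that("indicine screen calls admixed targets and spares pure ones", {
  # taurine clade (T1 target-like, T2/T3 references), indicine I, outgroup O;
  # TgtAdm carries 30% indicine ancestry
  de <- data.frame(
    from = c("root", "root", "N0", "N0", "NI", "NT", "NT", "NTa", "NTa",
             "NTb", "NTb", "MIX"),
    to = c("O", "N0", "NI", "NT", "I", "T2", "NTa", "T3", "NTb", "T1",
           "MIXP", "TgtAdm"),
    length = 0.01)
  g <- admixtureGraph(de, data.frame(node = "MIX", parent1 = "MIXP",
                                     parent2 = "NI", alpha = 0.7))
  gt <- driftSim(g, 50000,
                 samples = data.frame(pop = c("O", "I", "T1", "T2", "T3", "TgtAdm"),
                                      n = 12L, pseudohaploid = FALSE), seed = 8)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt)
  pure <- indicineScreen(ft, "O", "I", "T1", c("T2", "T3"), bl)
  expect_true(pure$unadmixed)
  adm <- indicineScreen(ft, "O", "I", "TgtAdm", c("T2", "T3"), bl)
  expect_false(adm$unadmixed)
  expect_true(any(adm$table$z <= -3))
  # floor at -Inf declares anything unadmixed
  expect_true(indicineScreen(ft, "O", "I", "TgtAdm", c("T2", "T3"), bl,
                             z_floor = -Inf)$unadmixed)
})
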