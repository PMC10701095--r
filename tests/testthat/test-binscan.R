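test_that("composite model frequency is the weighted source average", {
  gt <- toyGenotypes(50)
  ft <- alleleFrequencies(gt)
  mfA <- modelExpectedFreq(ft, c("A", "B"), c(1, 0))
  expect_equal(mfA[!is.na(mfA)], freq(ft)[!is.na(mfA), "A"])
  counts <- cbind(A = 2L, B = 6L); totals <- cbind(A = 10L, B = 10L)
  ft2 <- new("FrequencyTable", counts = counts[rep(1, 2), ],
             totals = totals[rep(1, 2), ],
             sites = GenomicRanges::GRanges(c("1", "1"),
                                            IRanges::IRanges(c(1, 2), width = 1)))
  expect_equal(unname(modelExpectedFreq(ft2, c("A", "B"), c(0.5, 0.5))),
               c(0.4, 0.4))
  expect_error(modelExpectedFreq(ft, c("A", "B"), c(0.3, 0.6)), "sum to 1")
})

test_that("bins are fixed half-open windows anchored at zero", {
  # 100-kb chromosome, SNPs everywhere: exactly 2 bins of 50 kb
  gt <- GenotypeTable(matrix(rep(c(0L, 1L, 2L, 1L), 50), 50, 4),
                      chrom = rep("1", 50), pos_bp = seq(2000, 100000, 2000),
                      ind_id = paste0("i", 1:4),
                      pop = rep(c("T", "S"), each = 2),
                      pseudohaploid = FALSE)
  ft <- alleleFrequencies(gt)
  mf <- rep(0.5, 50)
  sc <- binF2Scan(ft, "T", mf, bin_sizes = 50000, top_fraction = 0.5)[[1]]
  expect_equal(nrow(sc@bins), 2L)
  expect_equal(sc@bins$start, c(0, 50000))
  expect_equal(sum(sc@bins$selected), 1L)  # ceil(0.5 * 2)
})

test_that("a target built as the exact mixture scores near zero", {
  set.seed(4)
  n <- 2000
  pA <- runif(n, 0.1, 0.9); pB <- pmin(pmax(pA + rnorm(n, 0, 0.2), 0), 1)
  mix <- 0.7 * pA + 0.3 * pB
  big <- 100000L  # effectively infinite sample: counts injected directly
  counts <- cbind(A = round(pA * big), B = round(pB * big),
                  T = round(mix * big))
  totals <- matrix(big, n, 3, dimnames = list(NULL, c("A", "B", "T")))
  ft <- new("FrequencyTable", counts = counts, totals = totals,
            sites = GenomicRanges::GRanges(rep("1", n),
                                           IRanges::IRanges(seq_len(n) * 500, width = 1)))
  mf <- modelExpectedFreq(ft, c("A", "B"), c(0.7, 0.3))
  sc <- binF2Scan(ft, "T", mf, bin_sizes = 10000)[[1]]
  # residual scale: frequency rounding plus the O(1/n) sampling correction
  expect_lt(max(abs(sc@bins$score)), 1e-5)
})

test_that("scan scores are right-skewed when short minor tracts are present", {
  gt <- mosaicSim(chrom_length_bp = 2e6, snp_spacing_bp = 100, phi = 0.05,
                  n_targets = 2, n_panel = 10, seed = 14)
  ft <- alleleFrequencies(gt)
  mf <- modelExpectedFreq(ft, c("SourceA", "SourceB"), c(0.6, 0.4))
  sc <- binF2Scan(ft, "Target", mf, bin_sizes = 1000)[[1]]
  s <- sc@bins$score
  skew <- mean((s - mean(s))^3) / sd(s)^3
  expect_gt(skew, 0.5)
})

test_that("top-bin selection is deterministic with coordinate tie-breaks", {
  counts <- cbind(T = c(10L, 2L, 10L, 5L), S = c(5L, 5L, 5L, 5L))
  totals <- matrix(10L, 4, 2, dimnames = list(NULL, c("T", "S")))
  ft <- new("FrequencyTable", counts = counts, totals = totals,
            sites = GenomicRanges::GRanges(rep("1", 4),
                                           IRanges::IRanges(c(500, 1500, 2500, 3500), width = 1)))
  mf <- rep(0.5, 4)
  sc <- binF2Scan(ft, "T", mf, bin_sizes = 1000, top_fraction = 0.25)[[1]]
  # bins 1 and 3 tie with the top score; the lower coordinate wins
  expect_equal(sc@bins$selected, c(TRUE, FALSE, FALSE, FALSE))
  sc2 <- binF2Scan(ft, "T", mf, bin_sizes = 1000, top_fraction = 0.5)[[1]]
  expect_equal(which(sc2@bins$selected), c(1L, 3L))
})

test_that("enrichment contrasts recover the minor donor and pass the null", {
  gt <- mosaicSim(chrom_length_bp = 6e6, snp_spacing_bp = 25, phi = 0.05,
                  n_targets = 2, n_panel = 15, seed = 3)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 0.025)
  mf <- modelExpectedFreq(ft, c("SourceA", "SourceB"), c(0.6, 0.4))
  scans <- binF2Scan(ft, "Target", mf, bin_sizes = c(1000, 10000))
  e1 <- enrichmentF4(ft, scans[["1000"]], "Outgroup", c("DonorX", "Target"),
                     c("SourceA", "SourceB"), c(0.6, 0.4), "Target", bl)
  donor <- e1[e1$X == "DonorX", ]
  expect_gt(donor$delta, 0)
  expect_gt(deltaZ(donor), 2)
  # X = target itself: strong positive f4 on both SNP sets (shared drift)
  self <- e1[e1$X == "Target", ]
  expect_gt(self$f4_genomewide / self$se_genomewide, 5)
  expect_gt(self$f4_top / self$se_top, 2)
  # genome-wide f4 does not depend on the bin size used for selection
  e2 <- enrichmentF4(ft, scans[["10000"]], "Outgroup", "DonorX",
                     c("SourceA", "SourceB"), c(0.6, 0.4), "Target", bl)
  expect_equal(e2$f4_genomewide, donor$f4_genomewide, tolerance = 1e-12)
})
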