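test_that("EIGENSTRAT write/read round-trip reproduces the table exactly", {
  g <- admixtureGraph(data.frame(from = c("root", "root"), to = c("A", "B"),
                                 length = 0.01))
  gt <- driftSim(g, 60, samples = data.frame(pop = c("A", "B"), n = c(3L, 2L),
                                             pseudohaploid = c(FALSE, TRUE)),
                 missingness = 0.15, seed = 7)
  pre <- file.path(tempdir(), "rt")
  writeEigenstrat(gt, pre)
  gt2 <- readEigenstrat(pre)
  expect_identical(unname(calls(gt2)), unname(calls(gt)))
  expect_identical(unname(indPop(gt2)), unname(indPop(gt)))
  expect_identical(unname(isPseudohaploid(gt2)), unname(isPseudohaploid(gt)))
  expect_equal(snpPos(gt2), snpPos(gt))
  expect_identical(snpChrom(gt2), snpChrom(gt))
})

test_that("malformed EIGENSTRAT input is rejected with informative errors", {
  pre <- file.path(tempdir(), "bad")
  writeLines(c("010", "019"), paste0(pre, ".geno"))
  writeLines(c("s1\t1\t0\t100\tA\tC", "s2\t1\t0\t200\tA\tC",
               "s3\t1\t0\t300\tA\tC"), paste0(pre, ".snp"))
  writeLines(c("i1\tU\tP1", "i2\tU\tP1", "i3\tU\tP2"), paste0(pre, ".ind"))
  expect_error(readEigenstrat(pre), "dimension mismatch")
  # packed binary magic
  writeBin(charToRaw("GENOxxxx"), paste0(pre, ".geno"))
  expect_error(readEigenstrat(pre), "packed")
  # unsorted positions
  writeLines(c("010", "019", "200"), paste0(pre, ".geno"))
  writeLines(c("s1\t1\t0\t300\tA\tC", "s2\t1\t0\t200\tA\tC",
               "s3\t1\t0\t100\tA\tC"), paste0(pre, ".snp"))
  expect_error(readEigenstrat(pre), "unsorted")
})

test_that("all-missing SNPs are retained and .ind populations drive grouping", {
  pre <- file.path(tempdir(), "miss")
  writeLines(c("9999", "0129"), paste0(pre, ".geno"))
  writeLines(c("s1\t1\t0\t100\tA\tC", "s2\t1\t0\t200\tA\tC"),
             paste0(pre, ".snp"))
  writeLines(c("i1\tU\tP1", "i2\tU\tP1", "i3\tU\tP2", "i4\tU\tP2"),
             paste0(pre, ".ind"))
  gt <- readEigenstrat(pre)
  expect_equal(nrow(gt), 2L)
  expect_true(all(is.na(calls(gt)[1L, ])))
  ft <- alleleFrequencies(gt)
  expect_identical(popNames(ft), c("P1", "P2"))
  expect_equal(unname(calledTotals(ft)[1L, ]), c(0L, 0L))
  expect_true(all(is.nan(freq(ft)[1L, ])))
})

test_that("allele counting follows diploid/pseudo-haploid chromosome rules", {
  gt <- GenotypeTable(
    calls = rbind(c(1L, 2L, 2L), c(0L, 9L, 0L)),
    chrom = c("1", "1"), pos_bp = c(10L, 20L),
    ind_id = c("d1", "d2", "h1"), pop = c("P", "P", "H"),
    pseudohaploid = c(FALSE, FALSE, TRUE))
  ft <- alleleFrequencies(gt)
  expect_equal(unname(derivedCounts(ft)[1L, ]), c(3L, 1L)) # {1,2} -> 3; hap 2 -> 1
  expect_equal(unname(calledTotals(ft)[1L, ]), c(4L, 1L))
  expect_equal(unname(calledTotals(ft)[2L, ]), c(2L, 1L))  # one diploid missing
  expect_error(alleleFrequencies(gt, "nope"), "unknown population")
})

test_that("frequency totals equal 2 x called diploids + called pseudo-haploids", {
  gt <- toyGenotypes()
  ft <- alleleFrequencies(gt)
  g <- calls(gt); pop <- indPop(gt); ph <- isPseudohaploid(gt)
  for (p in popNames(ft)) {
    dip <- g[, pop == p & !ph, drop = FALSE]
    hap <- g[, pop == p & ph, drop = FALSE]
    expect_equal(unname(calledTotals(ft)[, p]),
                 unname(2L * rowSums(!is.na(dip)) + rowSums(!is.na(hap))))
  }
})

test_that("site filter applies MAF, missingness and spacing rules as derived", {
  pre <- sub("\\.geno$", "",
             system.file("extdata", "toy_filter.geno", package = "admixscan"))
  gt <- readEigenstrat(pre)
  out <- filterSites(gt, cattle_pops = c("CattleA", "CattleB"),
                     outgroup_pops = "Out")
  # hand-derived: rs2/rs5/rs9 fail MAF, rs6/rs8 fail missingness, rs3 falls
  # to the 52-bp spacing rule against rs4
  expect_identical(SummarizedExperiment::rowRanges(out)$snp_id,
                   c("rs1", "rs4", "rs7", "rs10"))
  # idempotence
  out2 <- filterSites(out, c("CattleA", "CattleB"), "Out")
  expect_identical(SummarizedExperiment::rowRanges(out2)$snp_id,
                   SummarizedExperiment::rowRanges(out)$snp_id)
})

test_that("identity thresholds keep everything; transversion rule drops A/G", {
  gt <- toyGenotypes(50)
  out <- filterSites(gt, c("A", "B"), c("C", "D"), maf_cattle = 0,
                     maf_outgroup = 0, miss_cattle = 1, miss_outgroup = 1,
                     min_spacing_bp = 0, transversions_only = FALSE)
  expect_equal(nrow(out), nrow(gt))
  rr <- SummarizedExperiment::rowRanges(gt)
  rr$ref[1:10] <- "A"; rr$alt[1:10] <- "G"   # make transitions
  SummarizedExperiment::rowRanges(gt) <- rr
  out2 <- filterSites(gt, c("A", "B"), c("C", "D"), maf_cattle = 0,
                      maf_outgroup = 0, miss_cattle = 1, miss_outgroup = 1,
                      min_spacing_bp = 0, transversions_only = TRUE)
  expect_equal(nrow(out2), nrow(gt) - 10L)
})

test_that("block partitioning spans <= block size and respects chromosomes", {
  gt <- GenotypeTable(matrix(0L, 13, 1), chrom = rep("1", 13),
                      pos_bp = (0:12) * 1e6 + 1, ind_id = "i", pop = "P",
                      pseudohaploid = FALSE, gcM = 0:12)
  bl <- makeBlocks(gt, 5)
  expect_equal(nBlocks(bl), 3L)           # [0,5), [5,10), [10,12]
  expect_error(makeBlocks(gt, -1), "positive")
  # two chromosomes never share a block
  gt2 <- GenotypeTable(matrix(0L, 8, 1), chrom = rep(c("1", "2"), each = 4),
                       pos_bp = rep(c(1e6, 2e6, 3e6, 4e6), 2), ind_id = "i",
                       pop = "P", pseudohaploid = FALSE)
  bl2 <- makeBlocks(gt2, 5)
  expect_equal(length(unique(blockId(bl2)[1:4])), 1L)
  expect_true(all(blockId(bl2)[1:4] != blockId(bl2)[5:8]))
  # no genetic map: 1 cM/Mb fallback reproduces the cM case
  gt3 <- GenotypeTable(matrix(0L, 13, 1), chrom = rep("1", 13),
                       pos_bp = (0:12) * 1e6 + 1, ind_id = "i", pop = "P",
                       pseudohaploid = FALSE)
  expect_equal(nBlocks(makeBlocks(gt3, 5)), 3L)
  expect_identical(as.integer(tabulate(blockId(bl))), blockWeights(bl))
})

test_that("pseudo-haploid individuals cannot carry heterozygous calls", {
  expect_error(
    GenotypeTable(matrix(1L, 2, 1), chrom = c("1", "1"), pos_bp = c(1L, 2L),
                  ind_id = "h", pop = "P", pseudohaploid = TRUE),
    "pseudo-haploid")
})
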