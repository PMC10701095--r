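test_that("a target that copies a source gets weight one and a large P", {
  g <- qpadmMixGraph()
  gt <- driftSim(g, 15000, samples = qpadmMixSamples(), seed = 2)
  # relabel half of SA's individuals as a new population "SAcopy"
  cd <- SummarizedExperiment::colData(gt)
  take <- which(cd$pop == "SA")[1:5]
  cd$pop[take] <- "SAcopy"
  SummarizedExperiment::colData(gt) <- cd
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  # weights may sit a hair outside [0,1] for an exact-copy target
  r <- suppressWarnings(
    qpadmFit(ft, "SAcopy", c("SA", "SB"), c("Out", "R0", "R1", "R2", "R3"), bl))
  expect_equal(unname(r@weights["SA"]), 1, tolerance = 0.05)
  expect_equal(unname(r@weights["SB"]), 0, tolerance = 0.05)
  expect_gt(r@pValue, 0.05)
  expect_equal(sum(r@weights), 1, tolerance = 1e-9)
  expect_equal(r@dof, 3L)  # (5-1) - (2-1)
})

test_that("mixture weights are recovered within error on a true 2-way model", {
  g <- qpadmMixGraph(alpha = 0.3)
  gt <- driftSim(g, 40000, samples = qpadmMixSamples(15L), seed = 5)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  r <- qpadmFit(ft, "Tgt", c("SA", "SB"), c("Out", "R0", "R1", "R2", "R3"), bl)
  expect_lt(abs(r@weights["SA"] - 0.3), 2 * r@weightSE["SA"] + 0.02)
  expect_gt(r@pValue, 0.01)
})

test_that("duplicated sources are flagged as degenerate", {
  g <- qpadmMixGraph()
  gt <- driftSim(g, 8000, samples = qpadmMixSamples(), seed = 3)
  cd <- SummarizedExperiment::colData(gt)
  take <- which(cd$pop == "SA")[1:5]
  cd$pop[take] <- "SA2"   # statistically identical second source
  SummarizedExperiment::colData(gt) <- cd
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  r <- suppressWarnings(
    qpadmFit(ft, "Tgt", c("SA", "SA2"), c("Out", "R0", "R1", "R2", "R3"), bl))
  # near-identical sources: either flagged degenerate outright or the
  # weights blow up far outside [0,1]
  expect_true(isTRUE(r@details$degenerate) ||
                any(abs(r@weights) > 3) || any(r@weightSE > 1))
})

test_that("the fit is invariant to permuting non-base references", {
  g <- qpadmMixGraph()
  gt <- driftSim(g, 15000, samples = qpadmMixSamples(), seed = 7)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  r1 <- qpadmFit(ft, "Tgt", c("SA", "SB"), c("Out", "R0", "R1", "R2", "R3"), bl)
  r2 <- qpadmFit(ft, "Tgt", c("SA", "SB"), c("Out", "R3", "R1", "R0", "R2"), bl)
  expect_equal(unname(r1@weights), unname(r2@weights), tolerance = 1e-6)
  expect_equal(r1@pValue, r2@pValue, tolerance = 1e-6)
})

test_that("full-fit weights agree with the mean of leave-one-block weights", {
  g <- qpadmMixGraph()
  gt <- driftSim(g, 30000, samples = qpadmMixSamples(), seed = 11)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  bs <- admixscan:::.qpadmBlockSums(ft, "Tgt", c("SA", "SB"),
                                    c("Out", "R0", "R1", "R2", "R3"), bl)
  jk <- admixscan:::jackknifeRatio(bs$sums, bs$wts)
  Q <- jk$cov + diag(1e-4 * mean(diag(jk$cov)), ncol(bs$sums))
  sol <- admixscan:::.qpadmSolve(jk$estimate, Q, 2L, 5L)
  K <- kronecker(diag(4L), t(sol$w))
  V <- K %*% Q %*% t(K)
  Vi <- solve(V)
  wl <- t(apply(jk$loo, 1, function(x) {
    Xb <- matrix(x, nrow = 2)
    wb <- solve(Xb %*% Vi %*% t(Xb), c(1, 1)); wb / sum(wb)
  }))
  expect_lt(max(abs(colMeans(wl) - sol$w)), 0.01)
})

test_that("the model battery passes the right source and rejects the wrong one", {
  g <- batteryGraph(beta = 0.5)
  gt <- driftSim(g, 50000,
                 samples = data.frame(pop = graphLeaves(g), n = 12L,
                                      pseudohaploid = FALSE), seed = 13)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt)
  refs <- c("Out", "RT1", "RT2", "RI1")
  specs <- list(ModelI = list(sources = c("T", "I1"), references = refs),
                ModelII = list(sources = c("T", "I2"), references = refs))
  tab <- modelBattery(ft, c("Tgt", "TgtPure"), specs, bl)
  expect_equal(nrow(tab), 4L)
  get <- function(tg, mdl) tab[tab$target == tg & tab$model == mdl, ]
  expect_true(get("Tgt", "ModelI")$pass)
  expect_false(get("Tgt", "ModelII")$pass)     # wrong, diverged indicine source
  expect_true(get("TgtPure", "ModelI")$pass)   # 0% indicine: both models fit
  expect_equal(get("TgtPure", "ModelI")$w1, 1, tolerance = 0.05)
  expect_lt(abs(get("Tgt", "ModelI")$w1 - 0.5), 3 * get("Tgt", "ModelI")$se1 + 0.02)
  # empty target list
  expect_equal(nrow(modelBattery(ft, character(0), specs, bl)), 0L)
})

test_that("errors in one battery row do not stop the batch", {
  g <- qpadmMixGraph()
  gt <- driftSim(g, 5000, samples = qpadmMixSamples(), seed = 17)
  ft <- alleleFrequencies(gt)
  bl <- makeBlocks(gt, 2)
  specs <- list(ok = list(sources = c("SA", "SB"),
                          references = c("Out", "R0", "R1", "R2", "R3")),
                bad = list(sources = c("SA", "NOPOP"),
                           references = c("Out", "R0", "R1", "R2", "R3")))
  tab <- suppressWarnings(modelBattery(ft, "Tgt", specs, bl))
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$p_value[tab$model == "bad"]))
  expect_false(is.na(tab$p_value[tab$model == "ok"]))
})
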