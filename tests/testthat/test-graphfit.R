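test_that("noise-free expected f2 is refit to itself with near-zero score", {
  g <- muturuGraph("B-2", with_truth = TRUE)
  M <- expectedF2Matrix(g)
  pairs <- t(combn(rownames(M), 2))
  f2v <- setNames(M[pairs], paste(pairs[, 1], pairs[, 2], sep = "|"))
  fit <- fitGraph(muturuGraph("B-2"), f2v, diag(1e-8, length(f2v)),
                  n_starts = 8, seed = 2)
  expect_lt(fit@score, 1e-2)
  expect_equal(unname(fit@alphas["SAHADM"]), 0.8, tolerance = 1e-2)
  expect_equal(unname(fit@alphas["MORADM"]), 0.6, tolerance = 1e-2)
  expect_equal(unname(fit@alphas["MUTADM"]), 0.6, tolerance = 1e-2)
  expect_equal(unname(fit@details$fitted), unname(f2v), tolerance = 1e-4)
})

test_that("the inner non-negative solver matches an independent implementation", {
  set.seed(10)
  for (i in 1:40) {
    k <- sample(3:20, 1); m <- k + sample(0:15, 1)
    C <- matrix(rnorm(m * k), m, k)
    if (i %% 3 == 0) C[, 1] <- C[, 2]        # structural rank deficiency
    d <- rnorm(m)
    x1 <- admixscan:::nnlsSolve(C, d)
    lam <- sqrt(1e-8 * max(colSums(C * C)))
    x2 <- pracma::lsqnonneg(rbind(C, diag(lam, k)), c(d, numeric(k)))$x
    expect_true(all(x1 >= 0))
    o1 <- sum((d - C %*% x1)^2); o2 <- sum((d - C %*% x2)^2)
    expect_lt(o1, o2 + 1e-6 * (1 + o2))
  }
})

test_that("adding an admixture edge never worsens the fit (nested models)", {
  g <- muturuGraph("B-2", with_truth = TRUE)
  gt <- driftSim(g, 30000, seed = 13)
  ft <- alleleFrequencies(gt)
  basis <- f2Basis(ft, makeBlocks(gt), pops = muturuPops)
  ob <- f2Observed(basis)
  fit1 <- fitGraph(muturuGraph("B-1", with_truth = TRUE), ob, n_starts = 6, seed = 1)
  fit2 <- fitGraph(muturuGraph("B-2", with_truth = TRUE), ob, n_starts = 6, seed = 1)
  expect_lte(fit2@score, fit1@score * (1 + 1e-6))
})

test_that("a misspecified tree shows a large worst residual Z under gene flow", {
  g <- muturuGraph("B-2", with_truth = TRUE)
  gt <- driftSim(g, 50000, seed = 17)
  ft <- alleleFrequencies(gt)
  basis <- f2Basis(ft, makeBlocks(gt), pops = muturuPops)
  ob <- f2Observed(basis)
  fit1 <- fitGraph(muturuGraph("B-1", with_truth = TRUE), ob, basis = basis,
                   n_starts = 6, seed = 4)
  fit2 <- fitGraph(muturuGraph("B-2", with_truth = TRUE), ob, basis = basis,
                   n_starts = 6, seed = 4)
  expect_gt(fit1@worstZ, 3)
  expect_lt(fit2@worstZ, fit1@worstZ)
})

test_that("a relabeled copy of a leaf attaches to that leaf's terminal edge", {
  backbone <- admixtureGraph(data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2"),
    to = c("O", "N1", "A", "N2", "B", "C"), length = 0.01))
  gt <- driftSim(backbone, 20000, seed = 23)
  # new population "Bcopy": fresh binomial samples from B's frequencies --
  # i.e. B with no extra drift
  g2 <- admixtureGraph(data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2", "BB", "BB"),
    to = c("O", "N1", "A", "N2", "BB", "C", "B", "Bcopy"),
    length = c(rep(0.01, 4), 0.01, 0.01, 0, 0)))
  gt2 <- driftSim(g2, 20000, seed = 23)
  ft <- alleleFrequencies(gt2)
  basis <- f2Basis(ft, makeBlocks(gt2))
  res <- searchAttachments(backbone, "Bcopy", basis, max_admixture_edges = 0)
  best <- res[1, ]
  expect_equal(best$attach_edge, "N2->B")
  fits <- attr(res, "fits")
  att_len <- fits[[1]]@lengths[grep("->Bcopy$", names(fits[[1]]@lengths))]
  expect_lt(att_len, 0.003)
})

test_that("attachment search with one gene flow beats tree-only on admixed data", {
  backbone <- admixtureGraph(data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2"),
    to = c("O", "N1", "A", "N2", "B", "C"), length = 0.01))
  gfull <- admixtureGraph(data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2", "CC", "BB", "MIX"),
    to = c("O", "N1", "A", "N2", "BB", "CC", "C", "B", "NEW"),
    length = c(rep(0.01, 8), 0.005)),
    data.frame(node = "MIX", parent1 = "BB", parent2 = "CC", alpha = 0.6))
  gt <- driftSim(gfull, 40000, seed = 29)
  ft <- alleleFrequencies(gt)
  basis <- f2Basis(ft, makeBlocks(gt))
  res0 <- searchAttachments(backbone, "NEW", basis, max_admixture_edges = 0)
  res1 <- searchAttachments(backbone, "NEW", basis, max_admixture_edges = 1)
  expect_lt(res1$score[1], res0$score[1])
  expect_false(is.na(res1$flow_edge[1]))
})

test_that("bootstrap self-comparison of a graph centres near one half", {
  g <- muturuGraph("B-2", with_truth = TRUE)
  gt <- driftSim(g, 20000, seed = 31)
  ft <- alleleFrequencies(gt)
  basis <- f2Basis(ft, makeBlocks(gt, 1), pops = muturuPops)
  cmp <- bootstrapCompare(g, g, basis, n_replicates = 60, seed = 6)
  expect_gte(cmp@empiricalP, 0.2)
  expect_lte(cmp@empiricalP, 0.8)
  expect_equal(cmp@nReplicates, 60L)
})

test_that("alpha jackknife errors cover the generating proportion", {
  g <- admixtureGraph(data.frame(
    from = c("root", "root", "N1", "N1", "N2", "N2", "CC", "BB", "MIX"),
    to = c("O", "N1", "A", "N2", "BB", "CC", "C", "B", "NEW"),
    length = c(rep(0.01, 8), 0.005)),
    data.frame(node = "MIX", parent1 = "BB", parent2 = "CC", alpha = 0.6))
  gt <- driftSim(g, 40000, seed = 37)
  ft <- alleleFrequencies(gt)
  basis <- f2Basis(ft, makeBlocks(gt, 1))
  fit <- fitGraph(g, f2Observed(basis), n_starts = 6, seed = 3)
  se <- graphAlphaSE(fit, basis, n_groups = 40)
  expect_true(all(se > 0))
  expect_lt(abs(fit@alphas["MIX"] - 0.6), 4 * se["MIX"])
})
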