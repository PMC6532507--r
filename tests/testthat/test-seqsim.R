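test_that("HKY transition probabilities match closed forms and expm", {
  expect_equal(hkyProbs(0, 5, rep(0.25, 4)), diag(4), ignore_attr = TRUE)
  # kappa = 1, equal frequencies: Jukes-Cantor closed form
  for (t in c(0.05, 0.3, 1.2)) {
    P <- hkyProbs(t, 1, rep(0.25, 4))
    pSame <- 1/4 + 3/4 * exp(-4 * t / 3)
    expect_equal(unname(diag(P)), rep(pSame, 4), tolerance = 1e-12)
  }
  # ergodic limit: rows approach the stationary frequencies
  f <- c(0.3, 0.2, 0.35, 0.15)
  P <- hkyProbs(100, 5, f)
  expect_equal(unname(P[2, ]), f, tolerance = 1e-8)
  # general case versus a numerical matrix exponential
  skip_if_not_installed("Matrix")
  kappa <- 5
  pur <- c(TRUE, FALSE, TRUE, FALSE)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- ifelse(pur[i] == pur[j], kappa, 1) * f[j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(f * diag(Q))
  for (t in c(0.1, 0.7)) {
    expect_equal(unname(hkyProbs(t, kappa, f)),
                 unname(as.matrix(Matrix::expm(Q * t))), tolerance = 1e-10)
    # rows sum to one, detailed balance holds
    P <- hkyProbs(t, kappa, f)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_equal(f * P, t(f * P), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("discrete-gamma rates have mean one and match independent oracles", {
  r <- discreteGammaRates(0.25, 5)
  expect_equal(mean(r), 1, tolerance = 1e-14)
  expect_equal(length(r), 5L)
  expect_true(all(diff(r) > 0))
  # numerical quantile / mean-of-bin oracle by direct integration
  alpha <- 0.25; k <- 5
  q <- qgamma(seq_len(k - 1) / k, alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  oracle <- vapply(seq_len(k), function(i) {
    k * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                  bounds[i], bounds[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(r, oracle / mean(oracle), tolerance = 1e-6)
  skip_if_not_installed("phangorn")
  expect_equal(r, unname(phangorn::discrete.gamma(0.25, 5)),
               tolerance = 1e-9)
  # alpha -> infinity: all categories approach rate 1
  expect_equal(discreteGammaRates(1e5, 5), rep(1, 5), tolerance = 1e-2)
})

test_that("the relaxed clock has the configured mean and degenerates at sd 0", {
  tr <- threeSpeciesComplete()
  ck <- simClock(tr, meanRate = 0.04, logSd = 0)
  expect_equal(ck$branchRates, rep(0.04, 5))
  set.seed(71)
  rates <- replicate(3000, simClock(tr, meanRate = 0.04,
                                    logSd = 0.1)$branchRates[1])
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.04), 3 * se)
  # mean rate drawn per tree: gamma(2, scale 2)/100 has mean 0.04
  set.seed(72)
  means <- replicate(3000, simClock(tr)$meanRate)
  expect_lt(abs(mean(means) - 0.04), 3 * sd(means) / sqrt(3000))
  # scale versus rate convention switch
  set.seed(73)
  meansRate <- replicate(2000, simClock(tr, betaIsScale = FALSE)$meanRate)
  expect_lt(abs(mean(meansRate) - 0.01), 3 * sd(meansRate) / sqrt(2000))
})

test_that("simulated alignments have the right shape and stationary composition", {
  set.seed(74)
  rep <- studyReplicate()
  et <- extantTree(rep$sampled)$tree
  ck <- simClock(et, meanRate = 0.04, logSd = 0.1)
  aln <- simAlignment(et, ck, hkyModel(), 2000)
  expect_equal(dim(aln), c(2000L, 25L))
  expect_setequal(colnames(aln), et$label[tipIndices(et)])
  expect_true(all(aln %in% 1:4))
  freqs <- tabulate(aln, 4) / length(aln)
  # base composition stays at the stationary 1/4 (correlated sites: allow a
  # generous multiple of the iid standard error)
  expect_true(all(abs(freqs - 0.25) < 0.05))
  # effectively zero rate: all sequences identical to the root draw
  aln0 <- simAlignment(et, simClock(et, meanRate = 1e-12, logSd = 0),
                       hkyModel(), 100)
  expect_true(all(aln0 == aln0[, 1]))
})

test_that("pairwise divergence increases with path duration", {
  set.seed(75)
  rep <- studyReplicate()
  et <- extantTree(rep$sampled)$tree
  ck <- simClock(et, meanRate = 0.02, logSd = 0)
  aln <- simAlignment(et, ck, hkyModel(), 2000)
  tips <- tipIndices(et)
  prs <- combn(length(tips), 2)[, sample(300, 40)]
  ham <- path <- numeric(ncol(prs))
  for (j in seq_len(ncol(prs))) {
    i1 <- tips[prs[1, j]]; i2 <- tips[prs[2, j]]
    ham[j] <- mean(aln[, et$label[i1]] != aln[, et$label[i2]])
    path[j] <- 2 * et$age[mrcaNode(et, et$label[c(i1, i2)])]
  }
  expect_gt(cor(ham, path, method = "spearman"), 0.5)
})

test_that("alignments round-trip through FASTA and NEXUS", {
  set.seed(76)
  rep <- studyReplicate()
  et <- extantTree(rep$sampled)$tree
  aln <- simAlignment(et, simClock(et, meanRate = 0.04, logSd = 0),
                      hkyModel(), 120)
  f <- tempfile(fileext = ".fasta")
  writeAlignmentFasta(aln, f)
  back <- readAlignmentFasta(f)
  expect_setequal(colnames(back), colnames(aln))
  expect_equal(back[, colnames(aln)], aln, ignore_attr = TRUE)
  fn <- tempfile(fileext = ".nex")
  writeAlignmentNexus(aln, fn)
  expect_true(any(grepl("NEXUS", readLines(fn, n = 2), ignore.case = TRUE)))
})
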