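# cherry time tree with tips A, B at ages 0 and root at h Ma
cherry <- function(h, origin = h + 1) {
  timeTree(parent = c(0L, 1L, 1L), age = c(h, 0, 0),
           label = c("", "A", "B"),
           status = c("internal", "extant", "extant"), origin = origin)
}

alnFrom <- function(states, labels) {
  m <- matrix(as.integer(states), nrow = 1)
  colnames(m) <- labels
  class(m) <- c("fbdAlignment", class(m))
  m
}

test_that("two-taxon one-site likelihood equals direct enumeration", {
  model <- hkyModel(kappa = 5, baseFreqs = c(0.3, 0.2, 0.35, 0.15),
                    gammaShape = 0.25, nCat = 5)
  rates <- discreteGammaRates(0.25, 5)
  h <- 7; rate <- 0.02
  for (states in list(c(1L, 1L), c(1L, 3L), c(2L, 4L))) {
    aln <- alnFrom(states, c("A", "B"))
    ll <- phyloLogLik(aln, cherry(h), model, rate)
    direct <- mean(vapply(rates, function(r) {
      P <- hkyProbs(h * rate * r, model$kappa, model$baseFreqs)
      sum(model$baseFreqs * P[, states[1]] * P[, states[2]])
    }, numeric(1)))
    expect_equal(ll, log(direct), tolerance = 1e-12)
  }
})

test_that("three-taxon likelihood equals enumeration over internal states", {
  set.seed(91)
  model <- hkyModel(kappa = 5, baseFreqs = c(0.3, 0.2, 0.35, 0.15),
                    gammaShape = 0.5, nCat = 4)
  rates <- discreteGammaRates(0.5, 4)
  tr <- timeTree(parent = c(0L, 1L, 2L, 2L, 1L), age = c(9, 4, 0, 0, 0),
                 label = c("", "", "A", "B", "C"),
                 status = c("internal", "internal", "extant", "extant",
                            "extant"), origin = 10)
  rate <- 0.03
  for (i in 1:5) {
    states <- sample.int(4, 3, replace = TRUE)
    aln <- alnFrom(states, c("A", "B", "C"))
    ll <- phyloLogLik(aln, tr, model, rate)
    direct <- mean(vapply(rates, function(r) {
      P1 <- hkyProbs(5 * rate * r, model$kappa, model$baseFreqs)  # root->AB
      P2 <- hkyProbs(4 * rate * r, model$kappa, model$baseFreqs)  # AB->tip
      P3 <- hkyProbs(9 * rate * r, model$kappa, model$baseFreqs)  # root->C
      tot <- 0
      for (x in 1:4) for (y in 1:4)
        tot <- tot + model$baseFreqs[x] * P3[x, states[3]] *
          P1[x, y] * P2[y, states[1]] * P2[y, states[2]]
      tot
    }, numeric(1)))
    expect_equal(ll, log(direct), tolerance = 1e-12)
  }
})

test_that("an all-missing taxon contributes a factor of one", {
  model <- hkyModel()
  set.seed(92)
  # ((A,B):, C) where C is entirely missing data
  tr3 <- timeTree(parent = c(0L, 1L, 2L, 2L, 1L), age = c(9, 4, 0, 0, 0),
                  label = c("", "", "A", "B", "C"),
                  status = c("internal", "internal", "extant", "extant",
                             "extant"), origin = 10)
  nsites <- 40
  s <- matrix(sample.int(4, 2 * nsites, replace = TRUE), ncol = 2)
  aln3 <- cbind(s, rep(5L, nsites))
  colnames(aln3) <- c("A", "B", "C")
  class(aln3) <- c("fbdAlignment", class(aln3))
  aln2 <- s; colnames(aln2) <- c("A", "B")
  class(aln2) <- c("fbdAlignment", class(aln2))
  ll3 <- phyloLogLik(aln3, tr3, model, 0.02)
  ll2 <- phyloLogLik(aln2, cherry(4, origin = 10), model, 0.02)
  expect_equal(ll3, ll2, tolerance = 1e-10)
})

test_that("pruning likelihood matches phangorn on a simulated dataset", {
  skip_if_not_installed("phangorn")
  set.seed(93)
  rep <- simReplicate(simConfig(nExtant = 6, originMin = 10,
                                originMax = 200, fossilMin = 1))
  et <- extantTree(rep$sampled)$tree
  model <- hkyModel()
  aln <- simAlignment(et, simClock(et, meanRate = 0.04, logSd = 0),
                      model, 400)
  ll <- phyloLogLik(aln, et, model, 0.04)
  pd <- phangorn::phyDat(t(alignmentToChar(aln)))
  phy <- asPhylo(et)
  phy$edge.length <- phy$edge.length * 0.04
  fit <- phangorn::pml(phy, pd, bf = rep(0.25, 4), Q = c(1, 5, 1, 1, 5, 1),
                       shape = 0.25, k = 5)
  expect_equal(ll, fit$logLik, tolerance = 1e-8)
})

test_that("taxon mismatch raises and the engine cache updates consistently", {
  model <- hkyModel()
  aln <- alnFrom(c(1L, 2L), c("A", "X"))
  expect_error(phyloLogLik(aln, cherry(5), model, 0.02), "match")
  # cached partial updates agree with full recomputation
  set.seed(94)
  rep <- studyReplicate()
  et <- extantTree(rep$sampled)$tree
  aln <- simAlignment(et, simClock(et, meanRate = 0.04, logSd = 0),
                      model, 200)
  eng <- likEngine(aln, et, model)
  len <- fbdage:::engineBranchLengths(eng, et$age, 0.04)
  full <- fbdage:::.engine_set_all(eng$ptr, len)
  for (i in 1:20) {
    b <- sample(which(eng$eparent != 0L), 1)
    new <- len; new[b] <- len[b] * runif(1, 0.5, 1.5)
    dirty <- eng$anc[[b]]
    prop <- fbdage:::.engine_propose(eng$ptr, dirty, b, new[b])
    e2 <- likEngine(aln, et, model)
    ref <- fbdage:::.engine_set_all(e2$ptr, new)
    expect_equal(prop, ref, tolerance = 1e-9)
    fbdage:::.engine_reject(eng$ptr)
    expect_equal(fbdage:::.engine_loglik(eng$ptr), full, tolerance = 1e-12)
  }
})
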