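test_that("HPD intervals match the exhaustive window-search oracle", {
  bruteHPD <- function(x, level = 0.95) {
    x <- sort(x); n <- length(x); k <- ceiling(level * n)
    if (k >= n) return(c(x[1], x[n]))
    best <- c(Inf, NA, NA)
    for (i in 1:(n - k)) {
      w <- x[i + k] - x[i]
      if (w < best[1]) best <- c(w, x[i], x[i + k])
    }
    best[2:3]
  }
  expect_equal(hpdInterval(rep(3.2, 10)), c(3.2, 3.2))
  expect_equal(hpdInterval(1:100, 0.95), bruteHPD(1:100, 0.95))
  expect_equal(diff(hpdInterval(1:100, 0.95)), 95)
  set.seed(111)
  for (i in 1:40) {
    n <- sample(2:200, 1)
    x <- switch(1 + i %% 3, rnorm(n), rexp(n), rlnorm(n))
    lv <- sample(c(0.5, 0.8, 0.95), 1)
    expect_equal(hpdInterval(x, lv), bruteHPD(x, lv))
  }
  x <- rnorm(1e5)
  h <- hpdInterval(x, 0.95)
  expect_lt(max(abs(h - c(-1.96, 1.96))), 0.05)
  expect_error(hpdInterval(numeric(0)), "empty")
})

test_that("effective sample size matches iid and AR(1) closed forms", {
  set.seed(112)
  x <- rnorm(10000)
  expect_true(mcmcESS(x) / 10000 > 0.9 && mcmcESS(x) / 10000 <= 1.1)
  phi <- 0.5
  y <- as.numeric(arima.sim(list(ar = phi), 10000))
  expect_lt(abs(mcmcESS(y) - 10000 * (1 - phi) / (1 + phi)) /
              (10000 * (1 - phi) / (1 + phi)), 0.15)
  expect_equal(mcmcESS(rep(2, 100)), 1)
})

test_that("relative error is |median - truth| / truth", {
  expect_equal(relativeError(5, 5), 0)
  expect_equal(relativeError(1.5, 1.0), 0.5)
  expect_equal(relativeError(0.5, 1.0), 0.5)
  expect_error(relativeError(1, 0), "truth")
  # mean over nodes equals the hand-computed average on a 3-node toy
  est <- c(10, 22, 28); truth <- c(10, 20, 35)
  expect_equal(mean(relativeError(est, truth)), mean(c(0, 0.1, 0.2)))
})

# build a synthetic trace whose marginals are fully controlled
syntheticTrace <- function(n = 400, nodes = c(`7` = 10, `9` = 20)) {
  cn <- c("Sample", "posterior", "likelihood", "prior", "d", "nu", "s",
          "lambda", "mu", "psi", "clockRate", "origin", "rootAge",
          paste0("age_", names(nodes)))
  m <- matrix(rnorm(n * length(cn)), n, length(cn),
              dimnames = list(NULL, cn))
  m[, "Sample"] <- seq_len(n)
  m[, "posterior"] <- rnorm(n)
  m[, "rootAge"] <- rnorm(n, 30)
  for (i in seq_along(nodes))
    m[, paste0("age_", names(nodes)[i])] <- rnorm(n, nodes[i], 0.5)
  m[, "d"] <- rnorm(n, 0.05, 0.005)
  m[, "nu"] <- runif(n, 0.4, 0.6)
  m[, "s"] <- runif(n, 0.5, 0.8)
  structure(m, class = c("fbdTrace", "matrix"), burnin = 0.1,
            cpuTime = 2.5, handling = "correct", mode = "posterior")
}

test_that("replicate summaries compute coverage, error and widths per node", {
  set.seed(113)
  tr <- syntheticTrace()
  truth <- list(nodeAges = c(`7` = 10, `9` = 20), d = 0.05, nu = 0.5,
                s = 0.65)
  s <- summarizeReplicate(tr, truth, essGate = 10)
  expect_equal(unname(s$divtime["coverage"]), 1)     # truth at the centre
  expect_lt(s$divtime["relError"], 0.05)
  expect_equal(nrow(s$nodes), 2L)
  expect_true(all(s$nodes$lo <= s$nodes$median &
                    s$nodes$median <= s$nodes$hi))
  expect_equal(s$timePerESS, 2.5 / min(s$ess))
  # truth far outside every HPD: coverage 0
  truthOff <- list(nodeAges = c(`7` = 50, `9` = 80))
  s0 <- summarizeReplicate(tr, truthOff, essGate = 10)
  expect_equal(unname(s0$divtime["coverage"]), 0)
  # relative HPD width formula on a constructed (4, 8) interval
  trW <- syntheticTrace(n = 100)
  trW[, "age_7"] <- rep(c(4, 8), 50)
  sW <- summarizeReplicate(trW, list(nodeAges = c(`7` = 5, `9` = 20)),
                           essGate = 1)
  expect_equal(sW$nodes$relWidth[sW$nodes$node == "7"], 0.8)
  # convergence gate flags, never drops
  sG <- summarizeReplicate(tr, truth, essGate = 1e6)
  expect_false(sG$converged)
  expect_equal(sG$divtime, s$divtime)
})

test_that("aggregation reduces to the replicate for n = 1 and tallies
           coverage independently", {
  set.seed(114)
  truth <- list(nodeAges = c(`7` = 10, `9` = 20), d = 0.05, nu = 0.5,
                s = 0.65)
  s1 <- summarizeReplicate(syntheticTrace(), truth, essGate = 10)
  agg1 <- aggregateResults(list(s1))
  row <- agg1[agg1$parameter == "divtime", ]
  expect_equal(row$relError, unname(s1$divtime["relError"]))
  expect_equal(row$coverage, unname(s1$divtime["coverage"]))
  # several replicates: coverage equals an independent tally
  ss <- lapply(1:6, function(i) summarizeReplicate(syntheticTrace(),
                                                   truth, essGate = 10))
  agg <- aggregateResults(ss)
  tally <- mean(vapply(ss, function(s) s$divtime["coverage"], numeric(1)))
  expect_equal(agg[agg$parameter == "divtime", "coverage"], tally)
  pooledTally <- mean(unlist(lapply(ss, function(s) s$nodes$covered)))
  expect_equal(agg[agg$parameter == "divtime_pooled", "coverage"],
               pooledTally)
  # permutation invariance over replicates
  expect_equal(aggregateResults(rev(ss)), agg)
})
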