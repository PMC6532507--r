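# ---- operator-level checks ------------------------------------------------

# minimal static info for parameter-only operator tests
paramInfo <- function() {
  tr <- timeTree(parent = c(0L, 1L, 1L), age = c(5, 0, 0),
                 label = c("", "A", "B"),
                 status = c("internal", "extant", "extant"), origin = 10)
  fbdage:::initializeInference(tr, NULL, priorConfig())$info
}

# one-dimensional Metropolis harness driving a single operator against a
# known target; returns the sampled values of `get`
driveOperator <- function(op, st, logTarget, get, n = 30000) {
  out <- numeric(n)
  cur <- logTarget(st)
  for (i in seq_len(n)) {
    d <- op$propose(st)
    if (!is.null(d)) {
      new <- st
      if (!is.null(d$param))
        for (k in seq_along(d$param)) new[[d$param[k]]] <- d$value[k]
      if (!is.null(d$ageNodes)) new$age[d$ageNodes] <- d$ageVals
      if (!is.null(d$origin)) new$origin <- d$origin
      lt <- logTarget(new)
      if (is.finite(lt) && log(runif(1)) < lt - cur + d$logH) {
        st <- new; cur <- lt
      }
    }
    out[i] <- get(st)
  }
  out
}

test_that("scale and slide operators satisfy detailed balance on known targets", {
  set.seed(101)
  info <- paramInfo()
  ops <- fbdage:::makeOperators(info, mode = "posterior")
  st <- list(age = c(5, 0, 0), origin = 10, d = 1, nu = 0.5, s = 0.5,
             clockRate = 1)
  # multiplier move targeting Exp(1); subsample hard so the KS iid
  # assumption holds
  x <- driveOperator(ops$d, st, function(s) dexp(s$d, log = TRUE),
                     function(s) s$d, n = 80000)
  x <- x[seq(5000, length(x), by = 100)]
  expect_gt(ks.test(x, "pexp")$p.value, 0.01)
  # reflected slide targeting Beta(2, 3)
  y <- driveOperator(ops$nu, st,
                     function(s) dbeta(s$nu, 2, 3, log = TRUE),
                     function(s) s$nu, n = 80000)
  y <- y[seq(5000, length(y), by = 100)]
  expect_gt(ks.test(y, "pbeta", 2, 3)$p.value, 0.01)
})

test_that("rate-space multiplier moves carry the correct Jacobian", {
  # target a fully known product density on (d, nu, s); if the Jacobian of
  # the (lambda, mu, psi) reparameterization were wrong, the stationary
  # marginals would be biased
  set.seed(102)
  info <- paramInfo()
  ops <- fbdage:::makeOperators(info, mode = "posterior")
  logTarget <- function(s) {
    if (s$d <= 0 || s$nu <= 0 || s$nu >= 1 || s$s <= 0 || s$s >= 1)
      return(-Inf)
    dexp(s$d, 2, log = TRUE) + dbeta(s$nu, 2, 2, log = TRUE) +
      dbeta(s$s, 3, 2, log = TRUE)
  }
  st <- list(age = c(5, 0, 0), origin = 10, d = 0.5, nu = 0.5, s = 0.5,
             clockRate = 1)
  n <- 120000
  keepD <- numeric(n); keepNu <- numeric(n); keepS <- numeric(n)
  cur <- logTarget(st)
  pool <- ops[c("lambdaScale", "muScale", "psiScale", "d", "nu", "s")]
  for (i in seq_len(n)) {
    op <- pool[[sample.int(length(pool), 1)]]
    dd <- op$propose(st)
    if (!is.null(dd)) {
      new <- st
      for (k in seq_along(dd$param)) new[[dd$param[k]]] <- dd$value[k]
      lt <- logTarget(new)
      if (is.finite(lt) && log(runif(1)) < lt - cur + dd$logH) {
        st <- new; cur <- lt
      }
    }
    keepD[i] <- st$d; keepNu[i] <- st$nu; keepS[i] <- st$s
  }
  idx <- seq(10000, n, by = 150)
  expect_gt(ks.test(keepD[idx], "pexp", 2)$p.value, 0.005)
  expect_gt(ks.test(keepNu[idx], "pbeta", 2, 2)$p.value, 0.005)
  expect_gt(ks.test(keepS[idx], "pbeta", 3, 2)$p.value, 0.005)
})

test_that("operator suites reflect the age-handling method", {
  rep <- studyReplicate()
  prior <- priorConfig()
  med <- fbdage:::initializeInference(rep$sampled,
                                      applyAgeHandling(rep$fossils, "median"),
                                      prior)
  opsMed <- fbdage:::makeOperators(med$info)
  expect_false("fossilAge" %in% names(opsMed))
  int <- fbdage:::initializeInference(rep$sampled,
                                      applyAgeHandling(rep$fossils, "interval"),
                                      prior)
  opsInt <- fbdage:::makeOperators(int$info)
  expect_true("fossilAge" %in% names(opsInt))
  # fossil-age proposals always fall inside the stratigraphic bounds
  set.seed(103)
  st <- int$state
  st$d <- 0.05; st$nu <- 0.5; st$s <- 0.5; st$clockRate <- 0.04
  b <- int$info$bounds
  for (i in 1:2000) {
    d <- opsInt$fossilAge$propose(st)
    if (is.null(d)) next
    w <- d$ageNodes[length(d$ageNodes)]          # the fossil tip node
    j <- match(w, b$node)
    expect_true(d$ageVals[1] >= b$lower[j] - 1e-12)
    expect_true(d$ageVals[1] <= b$upper[j] + 1e-12)
  }
})

# ---- sampler-level calibration -------------------------------------------

test_that("effective-prior root ages match direct forward simulation
           (fixed origin, no fossils)", {
  set.seed(104)
  lambda <- 0.15; mu <- 0.1; T0 <- 25; n <- 3
  # forward oracle: run a birth-death process for exactly T0 and accept
  # realizations with exactly n surviving species; record the two ordered
  # divergence times of the reconstructed tree
  fwd <- function() {
    repeat {
      alive <- c(T0)       # remaining lifetimes to the present, per lineage
      splits <- numeric(0) # ages of splits with >= 1 survivor on each side?
      # simulate the full tree recursively instead
      nodes <- list(list(t = T0))  # stack of (lineage start age)
      tipsA <- c(); intA <- c()
      # explicit recursion
      simLin <- function(t0) {
        # returns vector of ages of surviving-to-present "leaf times"
        # and records split ages with survivors both sides
        repeat {
          dt <- rexp(1, lambda + mu)
          t1 <- t0 - dt
          if (t1 <= 0) return(list(surv = TRUE, splits = numeric(0)))
          if (runif(1) < lambda / (lambda + mu)) {
            a <- simLin(t1); b <- simLin(t1)
            sp <- c(a$splits, b$splits)
            if (a$surv && b$surv) sp <- c(sp, t1)
            return(list(surv = a$surv || b$surv, splits = sp))
          } else return(list(surv = FALSE, splits = numeric(0)))
        }
      }
      r <- simLin(T0)
      if (r$surv && length(r$splits) == n - 1) return(sort(r$splits))
    }
  }
  oracle <- t(replicate(500, fwd()))
  # effective-prior MCMC on a fixed 3-tip topology with origin fixed at T0
  tr <- timeTree(parent = c(0L, 1L, 2L, 2L, 1L), age = c(20, 10, 0, 0, 0),
                 label = c("", "", "A", "B", "C"),
                 status = c("internal", "internal", "extant", "extant",
                            "extant"), origin = T0)
  trace <- runMCMC(tr, NULL, mode = "effective_prior",
                   config = mcmcConfig(chainLength = 150000, thin = 100,
                                       burnin = 0.2),
                   prior = priorConfig(originMax = T0 + 1),
                   init = list(d = lambda - mu, nu = mu / lambda, s = 0,
                               clockRate = 0.04, rho = 1),
                   fixParams = c("d", "nu", "s", "origin", "clockRate"))
  post <- trace[-(1:300), ]
  ages <- post[, grep("^age_", colnames(post))]
  expect_gt(ks.test(apply(ages, 1, max), oracle[, 2])$p.value, 0.01)
  expect_gt(ks.test(apply(ages, 1, min), oracle[, 1])$p.value, 0.01)
})

test_that("effective prior with a stem sampled ancestor matches numeric
           integration and keeps the fossil age in bounds", {
  set.seed(105)
  lambda <- 0.2; mu <- 0.1; psi <- 0.15; x0 <- 18
  # 2 extant tips, one sampled ancestor on the stem above the root
  tr <- timeTree(parent = c(0L, 1L, 1L, 3L, 3L),
                 age = c(10, 10, 6, 0, 0),
                 label = c("", "f", "", "A", "B"),
                 status = c("internal", "fossil", "internal", "extant",
                            "extant"),
                 origin = x0, sa = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  fs <- data.frame(id = 1L, lineage = NA_integer_, true_age = 10,
                   min_age = 0, max_age = x0, sym_min_age = 0,
                   sym_max_age = x0, node = 2L, sa = TRUE)
  class(fs) <- c("fossilTable", "data.frame")
  fs <- applyAgeHandling(fs, "interval")
  trace <- runMCMC(tr, fs, mode = "effective_prior",
                   config = mcmcConfig(chainLength = 150000, thin = 75,
                                       burnin = 0.2),
                   prior = priorConfig(originMax = x0 + 1),
                   init = list(d = lambda - mu, nu = mu / lambda,
                               s = psi / (mu + psi), clockRate = 0.04,
                               rho = 1),
                   fixParams = c("d", "nu", "s", "origin", "clockRate"))
  post <- trace[-(1:600), ]
  x1 <- post[, "age_3"]                # the extant root (branching node)
  z <- post[, "fossilage_1"]
  expect_true(all(z >= 0 & z <= x0))
  expect_true(all(z >= x1 - 1e-9))               # SA above the root
  # marginal of the root age: proportional to q(x1) (x0 - x1)
  grid <- seq(0, x0, length.out = 4000)
  dens <- exp(fbdage:::fbdLogQ(grid, lambda, mu, psi, 1)) * (x0 - grid)
  cdf <- cumsum(dens) / sum(dens)
  pit <- approx(grid, cdf, xout = x1)$y
  expect_gt(ks.test(pit, "punif")$p.value, 0.01)
  # conditional of the SA age given the root age is uniform on (x1, x0)
  u <- (z - x1) / (x0 - x1)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("degenerate chains and bound containment behave as specified", {
  rep <- studyReplicate()
  fos <- applyAgeHandling(rep$fossils, "interval")
  tr0 <- runMCMC(rep$sampled, fos, mode = "effective_prior",
                 config = mcmcConfig(chainLength = 0, thin = 1))
  expect_equal(nrow(tr0), 1L)
  set.seed(106)
  tr1 <- runMCMC(rep$sampled, fos, mode = "effective_prior",
                 config = mcmcConfig(chainLength = 3000, thin = 10,
                                     burnin = 0.2))
  fcols <- grep("^fossilage_", colnames(tr1), value = TRUE)
  ids <- as.integer(sub("fossilage_", "", fcols))
  j <- match(ids, fos$id)
  for (k in seq_along(fcols)) {
    expect_true(all(tr1[, fcols[k]] >= fos$lower[j[k]] - 1e-9))
    expect_true(all(tr1[, fcols[k]] <= fos$upper[j[k]] + 1e-9))
  }
  # non-finite initial state raises informatively
  expect_error(runMCMC(rep$sampled, fos, mode = "posterior",
                       config = mcmcConfig(chainLength = 10, thin = 1)),
               "alignment")
})

test_that("effective-prior summaries quantify departure from uniformity", {
  set.seed(107)
  rep <- studyReplicate()
  fos <- applyAgeHandling(rep$fossils, "interval")
  tr <- runMCMC(rep$sampled, fos, mode = "effective_prior",
                config = mcmcConfig(chainLength = 20000, thin = 20,
                                    burnin = 0.2))
  i <- which.max(fos$upper - fos$lower)
  s <- effectivePriorSummary(tr, fos$id[i], fos$lower[i], fos$upper[i])
  expect_true(s$ksStat >= 0 && s$ksStat <= 1)
  expect_equal(sum(s$hist$counts), length(s$samples))
  # interval width -> 0 concentrates at the midpoint
  fosNarrow <- fos
  fosNarrow$lower <- fosNarrow$true_age - 1e-4
  fosNarrow$upper <- fosNarrow$true_age + 1e-4
  trN <- runMCMC(rep$sampled, fosNarrow, mode = "effective_prior",
                 config = mcmcConfig(chainLength = 2000, thin = 20,
                                     burnin = 0.2))
  fcols <- grep("^fossilage_", colnames(trN), value = TRUE)
  dev <- abs(trN[, fcols[1]] - fosNarrow$true_age[match(
    as.integer(sub("fossilage_", "", fcols[1])), fosNarrow$id)])
  expect_true(all(dev <= 2e-4))
  # fixed-age handling has no sampled fossil ages to summarize
  fosMed <- applyAgeHandling(rep$fossils, "median")
  trM <- runMCMC(rep$sampled, fosMed, mode = "effective_prior",
                 config = mcmcConfig(chainLength = 500, thin = 10))
  expect_error(effectivePriorSummary(trM, fosMed$id[1],
                                     fosMed$min_age[1], fosMed$max_age[1]),
               "not.*sampled|sampled")
})
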