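#' MCMC run settings
#'
#' Defaults follow the desk-scale convention used throughout the package:
#' 1e6 iterations thinned every 1e3, 10% burn-in, effective-sample-size gate
#' of 200.  Tests and the acceptance pipeline pass shorter chains.
#'
#' @param chainLength number of Metropolis-Hastings iterations.
#' @param thin record every \code{thin}-th iteration (the initial state is
#'   always recorded).
#' @param burnin fraction of the chain treated as burn-in (used for
#'   adaptation and by the evaluation step).
#' @param essGate minimum effective sample size considered satisfactory.
#' @param adapt tune proposal step sizes during burn-in towards an
#'   acceptance rate of 0.2--0.4.
#' @return a list of class \code{"mcmcConfig"}.
#' @export
mcmcConfig <- function(chainLength = 1e6, thin = 1e3, burnin = 0.1,
                       essGate = 200, adapt = TRUE) {
  stopifnot(chainLength >= 0, thin >= 1, burnin >= 0, burnin < 1)
  structure(list(chainLength = as.integer(chainLength),
                 thin = as.integer(thin), burnin = burnin,
                 essGate = essGate, adapt = adapt),
            class = "mcmcConfig")
}

# --- inference state construction -----------------------------------------

# Classify nodes, apply the age-handling method to the tree, demote sampled
# ancestors whose fixed age conflicts with fixed ages below them, and build
# a feasible initial state.  Returns the static `info` list and the mutable
# initial state.
initializeInference <- function(tree, fossils, prior, eps = 1e-6,
                                margin = 1e-3) {
  n <- length(tree$parent)
  parent <- tree$parent
  ch <- childrenList(tree)
  tips <- tipIndices(tree)
  isTip <- logical(n); isTip[tips] <- TRUE
  age <- tree$age
  origin <- tree$origin
  sa <- tree$sa

  nf <- if (is.null(fossils)) 0L else nrow(fossils)
  sampledAges <- nf > 0L && !is.null(fossils$method) &&
    fossils$method[1] %in% c("interval", "symmetric")
  fixedAges <- nf > 0L && !sampledAges

  if (nf > 0L && (is.null(fossils$node) || anyNA(fossils$node)))
    stop("fossil table must carry sampled-tree node indices (column 'node')")

  if (fixedAges) {
    if (anyNA(fossils$operational_age))
      stop("fixed-age handling requires operational ages; ",
           "run applyAgeHandling() first")
    # Fossil specimens on one lineage carry no data besides their age, so
    # their attachment order along the branch is exchangeable: assign the
    # operational ages along each chain in its original (true-age) order,
    # which removes within-branch order conflicts exactly as a
    # topology-sampling analysis would.
    if (!is.null(fossils$lineage) && !anyNA(fossils$lineage)) {
      for (L in unique(fossils$lineage[duplicated(fossils$lineage)])) {
        rows <- which(fossils$lineage == L)
        ord <- rows[order(-fossils$true_age[rows])]
        fossils$operational_age[ord] <-
          sort(fossils$operational_age[rows], decreasing = TRUE)
      }
    }
    # fixed floors come from fossil tip ages only
    age[fossils$node] <- fossils$operational_age
    # maximum fixed age strictly below each node
    below <- rep(-Inf, n)
    fixedTip <- rep(NA_real_, n)
    fixedTip[fossils$node] <- fossils$operational_age
    for (v in postorderNodes(tree)) {
      p <- parent[v]
      if (p == 0L) next
      val <- max(below[v], fixedTip[v], na.rm = TRUE)
      if (val > below[p]) below[p] <- val
    }
    # demote conflicted sampled ancestors: the attachment node keeps the
    # fossil below it but becomes a free branching node
    for (i in which(!is.na(fossils$sa) & fossils$sa)) {
      w <- fossils$node[i]; a <- parent[w]
      others <- setdiff(ch[[a]], w)
      mb <- max(c(-Inf, below[others], fixedTip[others]), na.rm = TRUE)
      if (fossils$operational_age[i] <= mb + margin) {
        sa[w] <- FALSE
        fossils$sa[i] <- FALSE
      }
    }
  }
  saTipIdx <- if (nf) fossils$node[fossils$sa] else integer(0)
  saAttachIdx <- parent[saTipIdx]
  fixedNode <- logical(n)                 # nodes whose age never moves
  if (nf) fixedNode[fossils$node] <- fixedAges
  if (fixedAges) fixedNode[saAttachIdx] <- TRUE

  if (fixedAges) {
    # fixed ceilings: nearest fixed sampled-ancestor attachment above
    for (i in seq_along(saTipIdx)) age[saAttachIdx[i]] <- age[saTipIdx[i]]
    ceil <- rep(Inf, n)
    for (v in rev(postorderNodes(tree))) {    # preorder
      p <- parent[v]
      if (p == 0L) next
      ceil[v] <- if (fixedNode[p] && !isTip[p]) min(ceil[p], age[p]) else ceil[p]
    }
    for (v in postorderNodes(tree)) {
      if (isTip[v] || fixedNode[v]) next
      mc <- max(age[ch[[v]]])
      a <- max(tree$age[v], mc + eps)
      if (is.finite(ceil[v]) && a >= ceil[v] - eps)
        a <- (mc + ceil[v]) / 2        # squeeze strictly between
      if (a <= mc)
        stop("could not build a feasible starting state for fixed fossil ages")
      age[v] <- a
    }
    origin <- min(max(origin, age[rootIndex(tree)] + 0.5), prior$originMax)
  }

  bounds <- NULL
  if (sampledAges) {
    if (anyNA(fossils$lower))
      stop("sampled-age handling requires bounds; run applyAgeHandling() first")
    bounds <- fossils[, c("id", "node", "sa", "lower", "upper")]
    # initialize fossil ages at interval midpoints where locally feasible
    ord <- rev(postorderNodes(tree))          # parents first
    pos <- match(seq_len(n), fossils$node)
    for (v in ord) {
      i <- pos[v]
      if (is.na(i)) next
      mid <- (fossils$lower[i] + fossils$upper[i]) / 2
      if (fossils$sa[i]) {
        a <- parent[v]
        others <- setdiff(ch[[a]], v)
        lo <- max(c(fossils$lower[i], age[others] + eps))
        hi <- min(fossils$upper[i],
                  (if (parent[a] == 0L) origin else age[parent[a]]) - eps)
        if (lo < hi) age[a] <- age[v] <- min(max(mid, lo), hi)
      } else {
        lo <- fossils$lower[i]
        hi <- min(fossils$upper[i], age[parent[v]] - eps)
        if (lo < hi) age[v] <- min(max(mid, lo), hi)
      }
    }
  }

  # node classification for the FBD density (post-demotion)
  fosTipIdx <- setdiff(if (nf) fossils$node else integer(0), saTipIdx)
  branchingIdx <- setdiff(which(!isTip), saAttachIdx)
  movable <- which(!isTip & !fixedNode &
                     !(seq_len(n) %in% (if (sampledAges) saAttachIdx else integer(0))))
  chIdx <- which(parent != 0L)
  # nodes whose age is subject to stratigraphic bounds (sampled-age arms)
  bndNode <- integer(0); bndLo <- bndHi <- numeric(0)
  if (sampledAges) {
    bndNode <- c(bounds$node, parent[bounds$node[bounds$sa]])
    bndLo <- c(bounds$lower, bounds$lower[bounds$sa])
    bndHi <- c(bounds$upper, bounds$upper[bounds$sa])
  }
  scaleNodes <- sort(unique(c(movable,
                              if (sampledAges) c(bounds$node,
                                                 parent[bounds$node[bounds$sa]]))))
  info <- list(parent = parent, children = ch, isTip = isTip,
               root = rootIndex(tree), nExtant = sum(tree$status == "extant"),
               saTipIdx = saTipIdx, saAttachIdx = saAttachIdx,
               fosTipIdx = fosTipIdx, branchingIdx = branchingIdx,
               movable = movable, fixedNode = fixedNode,
               chIdx = chIdx, paIdx = parent[chIdx],
               bndNode = bndNode, bndLo = bndLo, bndHi = bndHi,
               scaleNodes = scaleNodes,
               sampledAges = sampledAges, bounds = bounds,
               fossils = fossils)
  state <- list(age = age, origin = origin)
  list(info = info, state = state)
}

# FBD log density from the precomputed classification (fast path).
# Implements the interval-truncation rule: density is 0 (log -Inf) whenever
# ages are non-monotone or a sampled fossil age leaves its bounds.
fbdLogDensityFast <- function(info, age, origin, lambda, mu, psi, rho) {
  if (any(age[info$chIdx] > age[info$paIdx] + 1e-12)) return(-Inf)
  if (origin < age[info$root] - 1e-12) return(-Inf)
  if (length(info$bndNode) &&
      any(age[info$bndNode] < info$bndLo - 1e-9 |
            age[info$bndNode] > info$bndHi + 1e-9)) return(-Inf)
  nb <- length(info$branchingIdx)
  m <- length(info$fosTipIdx); k <- length(info$saTipIdx)
  ll <- 0
  if (m + k > 0) {
    if (psi <= 0) return(-Inf)
    ll <- (m + k) * log(psi)
  }
  if (rho < 1) ll <- ll + info$nExtant * log(rho)
  x <- c(origin, age[info$branchingIdx])
  ll <- ll + sum(fbdLogQ(x, lambda, mu, psi, rho)) + nb * log(lambda)
  if (m > 0) {
    y <- age[info$fosTipIdx]
    p0 <- fbdP0(y, lambda, mu, psi, rho)
    if (any(p0 <= 0)) return(-Inf)
    ll <- ll + sum(log(p0) - fbdLogQ(y, lambda, mu, psi, rho))
  }
  ll
}

# --- operators -------------------------------------------------------------

#' Build the proposal-operator suite for an inference state
#'
#' The suite contains scale moves on diversification, turnover, sampling
#' proportion and (in posterior mode) the clock rate; a uniform node-age
#' move respecting parent/child bounds; an origin slide reflected at the
#' root age; and -- only for the sampled-age handling methods -- a uniform
#' fossil-age move confined to the stratigraphic bounds.  Each operator is a
#' list with a \code{propose(state)} function returning the proposed change
#' and its log Hastings ratio (all moves here are symmetric).
#'
#' @param info static inference structure (internal; built by
#'   \code{\link{runMCMC}}).
#' @param mode \code{"posterior"} or \code{"effective_prior"}.
#' @param fixParams names among \code{c("d", "nu", "s", "clockRate",
#'   "origin")} to hold fixed (their operators, and any joint operator
#'   moving them, are omitted).
#' @return list of operators.
#' @keywords internal
makeOperators <- function(info, mode = "posterior",
                          fixParams = character(0)) {
  ops <- list()
  fbdFree <- !any(c("d", "nu", "s") %in% fixParams)
  clockFree <- !("clockRate" %in% fixParams)
  originFree <- !("origin" %in% fixParams)
  parent <- info$parent; ch <- info$children; root <- info$root

  if (length(info$movable)) {
    ops$nodeAge <- list(
      name = "nodeAge", weight = length(info$movable), tune = NULL,
      propose = function(st) {
        v <- info$movable[sample.int(length(info$movable), 1L)]
        lo <- max(st$age[ch[[v]]])
        hi <- if (parent[v] == 0L) st$origin else st$age[parent[v]]
        if (hi - lo < 1e-12) return(NULL)
        list(ageNodes = v, ageVals = stats::runif(1L, lo, hi), logH = 0)
      })
  }
  if (info$sampledAges && nrow(info$bounds)) {
    b <- info$bounds
    ops$fossilAge <- list(
      name = "fossilAge", weight = nrow(b), tune = NULL,
      propose = function(st) {
        i <- sample.int(nrow(b), 1L)
        w <- b$node[i]
        if (b$sa[i]) {
          a <- parent[w]
          others <- setdiff(ch[[a]], w)
          lo <- max(c(b$lower[i], st$age[others]))
          hi <- min(b$upper[i],
                    if (parent[a] == 0L) st$origin else st$age[parent[a]])
          if (hi - lo < 1e-12) return(NULL)
          x <- stats::runif(1L, lo, hi)
          list(ageNodes = c(a, w), ageVals = c(x, x), logH = 0)
        } else {
          lo <- b$lower[i]
          hi <- min(b$upper[i], st$age[parent[w]])
          if (hi - lo < 1e-12) return(NULL)
          list(ageNodes = w, ageVals = stats::runif(1L, lo, hi), logH = 0)
        }
      })
  }
  if (originFree) {
    originTune <- new.env(); originTune$step <- 5
    ops$origin <- list(
      name = "origin", weight = 3, tune = originTune,
      propose = function(st) {
        lo <- st$age[root]
        x <- st$origin + stats::runif(1L, -originTune$step, originTune$step)
        # reflect into (lo, Inf); the prior handles the upper bound
        if (x < lo) x <- 2 * lo - x
        list(origin = x, logH = 0)
      })
  }
  mkScale <- function(param, w) {
    tn <- new.env(); tn$step <- 0.5
    list(name = param, weight = w, tune = tn,
         propose = function(st) {
           f <- exp(tn$step * (stats::runif(1L) - 0.5))
           list(param = param, value = st[[param]] * f, logH = log(f))
         })
  }
  mkSlide01 <- function(param, w) {
    tn <- new.env(); tn$step <- 0.2
    list(name = param, weight = w, tune = tn,
         propose = function(st) {
           x <- st[[param]] + stats::runif(1L, -tn$step, tn$step)
           while (x < 0 || x > 1) x <- ifelse(x < 0, -x, 2 - x)
           list(param = param, value = x, logH = 0)
         })
  }
  # the FBD-parameter moves cost no likelihood evaluation, so they get a
  # large share of iterations to decorrelate the weakly identified
  # (d, nu, s) ridge
  if (fbdFree) {
    ops$d <- mkScale("d", 6)
    ops$nu <- mkSlide01("nu", 6)
    ops$s <- mkSlide01("s", 6)
  }
  # multiplier moves in (lambda, mu, psi) space cut across the strong
  # d-nu-s posterior correlations; the Jacobian of the reparameterization
  # |d(d,nu,s)/d(lambda,mu,psi)| = mu (lambda-mu) / ((mu+psi)^2 lambda^2)
  # enters the acceptance ratio
  logJrates <- function(lambda, mu, psi)
    log(mu) + log(lambda - mu) - 2 * log(mu + psi) - 2 * log(lambda)
  mkRateScale <- function(which, w) {
    tn <- new.env(); tn$step <- 0.4
    list(name = which, weight = w, tune = tn,
         propose = function(st) {
           lambda <- st$d / (1 - st$nu); mu <- st$nu * lambda
           psi <- st$s * mu / (1 - st$s)
           if (mu <= 0 || psi <= 0) return(NULL)
           f <- exp(tn$step * (stats::runif(1L) - 0.5))
           l2 <- lambda; m2 <- mu; p2 <- psi
           if (which == "lambdaScale") l2 <- lambda * f
           else if (which == "muScale") m2 <- mu * f
           else p2 <- psi * f
           if (l2 <= m2) return(NULL)
           list(param = c("d", "nu", "s"),
                value = c(l2 - m2, m2 / l2, p2 / (m2 + p2)),
                logH = log(f) + logJrates(l2, m2, p2) -
                  logJrates(lambda, mu, psi))
         })
  }
  if (fbdFree) {
    ops$lambdaScale <- mkRateScale("lambdaScale", 6)
    ops$muScale <- mkRateScale("muScale", 6)
    ops$psiScale <- mkRateScale("psiScale", 6)
  }
  if (mode == "posterior" && clockFree) ops$clock <- mkScale("clockRate", 6)
  # global scale of all free ages (+ origin): traverses tree-height moves
  # that single-node windows cannot make
  sn <- info$scaleNodes
  if (length(sn) && originFree) {
    saTune <- new.env(); saTune$step <- 0.1
    ops$scaleAges <- list(
      name = "scaleAges", weight = 3, tune = saTune,
      propose = function(st) {
        f <- exp(saTune$step * (stats::runif(1L) - 0.5))
        list(ageNodes = sn, ageVals = st$age[sn] * f,
             origin = st$origin * f,
             logH = (length(sn) + 1) * log(f))
      })
    if (mode == "posterior" && clockFree) {
      raTune <- new.env(); raTune$step <- 0.1
      ops$ratesAges <- list(
        name = "ratesAges", weight = 20, tune = raTune,
        propose = function(st) {
          # ridge move: ages * f, clock rate / f; every branch's expected
          # substitutions is exactly preserved, so the likelihood needs no
          # recomputation (likInvariant) and the move is as cheap as a
          # parameter move
          f <- exp(raTune$step * (stats::runif(1L) - 0.5))
          list(ageNodes = sn, ageVals = st$age[sn] * f,
               origin = st$origin * f,
               param = "clockRate", value = st$clockRate / f,
               likInvariant = TRUE,
               logH = length(sn) * log(f))
        })
      if (!identical(info$movable, sn)) {
        # variant leaving the bound-constrained fossil ages in place, so
        # the scale change is not vetoed by every stratigraphic bound
        rfTune <- new.env(); rfTune$step <- 0.1
        mv <- info$movable
        ops$ratesAgesFree <- list(
          name = "ratesAgesFree", weight = 20, tune = rfTune,
          propose = function(st) {
            f <- exp(rfTune$step * (stats::runif(1L) - 0.5))
            list(ageNodes = mv, ageVals = st$age[mv] * f,
                 origin = st$origin * f,
                 param = "clockRate", value = st$clockRate / f,
                 likInvariant = TRUE,
                 logH = length(mv) * log(f))
          })
      }
    }
  }
  ops
}

# --- main sampler ----------------------------------------------------------

#' Metropolis-Hastings sampler for the FBD model with fossil age handling
#'
#' Samples node ages, the origin, the FBD parameters (diversification,
#' turnover, sampling proportion) and the strict-clock rate on a fixed
#' sampled-tree topology with fossil attachments fixed to the lineages of
#' the input tree.  In \code{"posterior"} mode the target is
#' sequence-likelihood x FBD density x priors; in \code{"effective_prior"}
#' mode the sequence likelihood is switched off, yielding the marginal
#' distribution induced on fossil and node ages by the FBD prior and the
#' interval truncation alone.
#'
#' For the sampled-age handling methods (\code{interval}, \code{symmetric})
#' the proposed tree density is the FBD density when every fossil age lies
#' within its stratigraphic bounds and zero otherwise; the fossil-age
#' operator proposes only within bounds, and bound violation elsewhere is
#' rejected through the density.
#'
#' When fossil ages are fixed to wrong values (median/random handling), a
#' sampled ancestor whose fixed age conflicts with a fixed fossil age below
#' it admits no valid tree with the true attachments; such fossils are
#' demoted to ordinary fossil tips with a free attachment age, the minimal
#' relaxation a topology-sampling analysis would perform.
#'
#' @param tree the sampled \code{timeTree} (true ages; used as topology and
#'   starting state).
#' @param fossils \code{fossilTable} after \code{\link{applyAgeHandling}}
#'   (with sampled-tree columns \code{node}, \code{sa}); NULL for no
#'   fossils.
#' @param model an \code{\link{hkyModel}} (posterior mode).
#' @param alignment an \code{fbdAlignment} over the extant tips (posterior
#'   mode).
#' @param mode \code{"posterior"} or \code{"effective_prior"}.
#' @param config an \code{\link{mcmcConfig}}.
#' @param prior a \code{\link{priorConfig}}.
#' @param init named list of starting values \code{d}, \code{nu}, \code{s},
#'   \code{clockRate}, \code{rho} (rho is fixed, not sampled).
#' @param fixParams names among \code{c("d", "nu", "s", "clockRate",
#'   "origin")} to hold fixed at their initial values (used e.g. for
#'   effective-prior calibration runs).
#' @param traceFile optional path; the trace is appended there every
#'   recorded sample (Tracer-compatible TSV).
#' @return a numeric matrix of class \code{"fbdTrace"}: one row per recorded
#'   sample with log posterior/likelihood/prior, parameters, origin, root
#'   age, per-MRCA node ages (\code{age_<node>}) and per-fossil ages
#'   (\code{fossilage_<id>}).  Attributes: \code{cpuTime} (seconds),
#'   \code{config}, \code{mode}, \code{acceptance}, \code{ess}
#'   (posterior and root age), \code{burnin}.
#' @export
runMCMC <- function(tree, fossils = NULL, model = hkyModel(),
                    alignment = NULL,
                    mode = c("posterior", "effective_prior"),
                    config = mcmcConfig(), prior = priorConfig(),
                    init = list(d = 0.05, nu = 0.5, s = 0.5,
                                clockRate = 0.04, rho = 1),
                    fixParams = character(0), traceFile = NULL) {
  mode <- match.arg(mode)
  t0 <- proc.time()
  ini <- initializeInference(tree, fossils, prior)
  info <- ini$info
  st <- ini$state
  st$d <- init$d; st$nu <- init$nu; st$s <- init$s
  st$clockRate <- if (is.null(init$clockRate)) {
    if (mode == "posterior" && !is.null(alignment))
      estimateClockRate(alignment, tree) else 0.04
  } else init$clockRate
  rho <- if (is.null(init$rho)) 1 else init$rho

  useLik <- mode == "posterior"
  engine <- NULL
  engineInternalOf <- integer(length(st$age))
  if (useLik) {
    if (is.null(alignment)) stop("posterior mode requires an alignment")
    et <- extantTree(tree)
    engine <- likEngine(alignment, et$tree, model)
    # sampled-tree node -> engine internal node (0 when unmapped)
    emap <- integer(length(st$age))
    emap[et$nodeMap] <- seq_along(et$nodeMap)
    for (v in seq_along(emap))
      if (emap[v] > 0L && engine$engineOf[emap[v]] > engine$ntip)
        engineInternalOf[v] <- engine$engineOf[emap[v]]
    sampledOfEngine <- et$nodeMap[engine$treeOf]
    curBlen <- function(age, rate)
      (ifelse(engine$eparent == 0L, 0,
              age[sampledOfEngine[pmax(engine$eparent, 1L)]]) -
         age[sampledOfEngine]) * rate
  }

  rates <- function(st) {
    lambda <- st$d / (1 - st$nu)
    mu <- st$nu * lambda
    list(lambda = lambda, mu = mu,
         psi = if (st$s >= 1) Inf else st$s * mu / (1 - st$s))
  }
  fbdOf <- function(st) {
    r <- rates(st)
    fbdLogDensityFast(info, st$age, st$origin, r$lambda, r$mu, r$psi, rho)
  }
  priorOf <- function(st)
    logPriorScalars(st$d, st$nu, st$s, st$clockRate, st$origin,
                    st$age[info$root], prior, withClock = useLik)

  curFbd <- fbdOf(st)
  curPrior <- priorOf(st)
  if (!is.finite(curFbd + curPrior))
    stop("non-finite initial density (fbd = ", curFbd,
         ", prior = ", curPrior, ")")
  curLik <- 0
  blen <- NULL
  if (useLik) {
    blen <- curBlen(st$age, st$clockRate)
    curLik <- .engine_set_all(engine$ptr, blen)
    if (!is.finite(curLik)) stop("non-finite initial likelihood")
  }

  ops <- makeOperators(info, mode, fixParams)
  wts <- vapply(ops, function(o) o$weight, numeric(1))
  cumw <- cumsum(wts) / sum(wts)
  att <- acc <- numeric(length(ops))
  batchAtt <- batchAcc <- nAdapt <- numeric(length(ops))

  # trace layout
  mrca <- if (useLik) which(engineInternalOf > 0L) else
    info$branchingIdx
  fossilIds <- if (!is.null(fossils) && nrow(fossils)) fossils$id else integer(0)
  fossilNodes <- if (length(fossilIds)) info$fossils$node else integer(0)
  cn <- c("Sample", "posterior", "likelihood", "prior", "d", "nu", "s",
          "lambda", "mu", "psi", "clockRate", "origin", "rootAge",
          if (length(mrca)) paste0("age_", mrca),
          if (length(fossilIds)) paste0("fossilage_", fossilIds))
  nSamp <- config$chainLength %/% config$thin + 1L
  trace <- matrix(NA_real_, nSamp, length(cn), dimnames = list(NULL, cn))
  con <- if (!is.null(traceFile)) file(traceFile, "w") else NULL
  if (!is.null(con)) {
    writeLines(paste(cn, collapse = "\t"), con)
    on.exit(close(con), add = TRUE)
  }
  rec <- function(row, it, st) {
    r <- rates(st)
    vals <- c(it, curLik + curFbd + curPrior, curLik, curFbd + curPrior,
              st$d, st$nu, st$s, r$lambda, r$mu, r$psi, st$clockRate,
              st$origin, st$age[info$root],
              if (length(mrca)) st$age[mrca],
              if (length(fossilNodes)) st$age[fossilNodes])
    trace[row, ] <<- vals
    if (!is.null(con)) {
      cat(paste(format(vals, digits = 10, trim = TRUE), collapse = "\t"),
          "\n", sep = "", file = con)
      flush(con)
    }
  }
  rec(1L, 0L, st)

  nBurn <- floor(config$burnin * config$chainLength)
  row <- 1L
  if (config$chainLength > 0L) for (it in seq_len(config$chainLength)) {
    oi <- findInterval(stats::runif(1L), cumw) + 1L
    op <- ops[[oi]]
    att[oi] <- att[oi] + 1
    delta <- op$propose(st)
    ok <- FALSE
    if (!is.null(delta)) {
      newSt <- st
      if (!is.null(delta$ageNodes)) newSt$age[delta$ageNodes] <- delta$ageVals
      if (!is.null(delta$origin)) newSt$origin <- delta$origin
      if (!is.null(delta$param))
        for (k in seq_along(delta$param))
          newSt[[delta$param[k]]] <- delta$value[k]
      newPrior <- priorOf(newSt)
      engProposed <- FALSE
      if (is.finite(newPrior)) {
        newFbd <- fbdOf(newSt)
        if (is.finite(newFbd)) {
          newLik <- curLik
          if (useLik && !isTRUE(delta$likInvariant)) {
            dirty <- integer(0)
            if (!is.null(delta$param) && "clockRate" %in% delta$param) {
              dirty <- seq_len(engine$nnode - engine$ntip) + engine$ntip
              newBlen <- curBlen(newSt$age, newSt$clockRate)
            } else if (!is.null(delta$ageNodes)) {
              mapped <- engineInternalOf[delta$ageNodes]
              mapped <- mapped[mapped > 0L]
              if (length(mapped)) {
                dirty <- sort(unique(unlist(engine$anc[mapped])))
                newBlen <- curBlen(newSt$age, newSt$clockRate)
              }
            }
            if (length(dirty)) {
              chg <- which(newBlen != blen)
              newLik <- .engine_propose(engine$ptr, dirty, chg, newBlen[chg])
              engProposed <- TRUE
            }
          }
          logR <- (newFbd + newPrior + newLik) -
            (curFbd + curPrior + curLik) + delta$logH
          if (is.finite(logR) && log(stats::runif(1L)) < logR) {
            st <- newSt
            curFbd <- newFbd; curPrior <- newPrior; curLik <- newLik
            if (engProposed) {
              .engine_accept(engine$ptr)
              blen <- newBlen
              engProposed <- FALSE
            } else if (useLik && isTRUE(delta$likInvariant)) {
              blen <- curBlen(st$age, st$clockRate)
            }
            acc[oi] <- acc[oi] + 1
            ok <- TRUE
          }
        }
      }
      if (!ok && engProposed) .engine_reject(engine$ptr)
    }
    if (config$adapt && !is.null(op$tune)) {
      batchAtt[oi] <- batchAtt[oi] + 1
      if (ok) batchAcc[oi] <- batchAcc[oi] + 1
      if (batchAtt[oi] == 50) {
        # diminishing adaptation towards ~0.3 acceptance
        nAdapt[oi] <- nAdapt[oi] + 1
        g <- 2 / sqrt(nAdapt[oi])
        rate <- batchAcc[oi] / batchAtt[oi]
        op$tune$step <- min(max(op$tune$step * exp(g * (rate - 0.3)),
                                1e-4), 50)
        batchAtt[oi] <- batchAcc[oi] <- 0
      }
    }
    if (it %% config$thin == 0L) {
      row <- row + 1L
      rec(row, it, st)
    }
  }
  cpu <- sum(proc.time()[c("user.self", "sys.self")] -
               t0[c("user.self", "sys.self")])
  keep <- seq_len(row)
  trace <- trace[keep, , drop = FALSE]
  nb <- min(nrow(trace) - 1L, ceiling(config$burnin * nrow(trace)))
  post <- if (nb > 0L) trace[-seq_len(nb), , drop = FALSE] else trace
  ess <- c(posterior = mcmcESS(post[, "posterior"]),
           rootAge = mcmcESS(post[, "rootAge"]))
  structure(trace, class = c("fbdTrace", "matrix"),
            cpuTime = cpu, config = config, mode = mode,
            acceptance = stats::setNames(ifelse(att > 0, acc / att, NA), names(ops)),
            steps = vapply(ops, function(o)
              if (is.null(o$tune)) NA_real_ else o$tune$step, numeric(1)),
            ess = ess, burnin = config$burnin,
            handling = if (!is.null(fossils) && nrow(fossils))
              fossils$method[1] else "none",
            demoted = if (!is.null(info$fossils) &&
                            !is.null(fossils) && nrow(fossils))
              sum(fossils$sa & !info$fossils$sa, na.rm = TRUE) else 0L)
}

#' Summarize the effective prior on a fossil's age
#'
#' Given a trace from \code{mode = "effective_prior"}, extracts the marginal
#' of one fossil's age and quantifies how far it departs from uniformity
#' over its stratigraphic interval (Kolmogorov-Smirnov distance), supporting
#' the observation that effective priors range from near-uniform to strongly
#' concentrated.
#'
#' @param trace an \code{fbdTrace}.
#' @param fossilId fossil id (matching the \code{fossilage_} column).
#' @param lower,upper the fossil's stratigraphic bounds.
#' @param breaks histogram bin count.
#' @return list with \code{samples}, \code{hist} (counts + breaks),
#'   \code{ksStat}, \code{ksP}, \code{mean}.
#' @export
effectivePriorSummary <- function(trace, fossilId, lower, upper,
                                  breaks = 20) {
  col <- paste0("fossilage_", fossilId)
  if (!col %in% colnames(trace)) stop("fossil ", fossilId, " not in trace")
  nb <- ceiling(attr(trace, "burnin") * nrow(trace))
  x <- trace[-seq_len(min(nb, nrow(trace) - 1L)), col]
  if (stats::sd(x) == 0)
    stop("fossil ", fossilId, " age was not sampled (fixed-age handling)")
  ks <- suppressWarnings(stats::ks.test(x, "punif", lower, upper))
  h <- graphics::hist(x, breaks = seq(lower, upper, length.out = breaks + 1),
                      plot = FALSE)
  list(samples = x, hist = list(counts = h$counts, breaks = h$breaks),
       ksStat = unname(ks$statistic), ksP = ks$p.value, mean = mean(x))
}
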