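#' Simulation settings for the birth-death-fossilization generator
#'
#' Bundles the generative parameters of the study conditions: a birth-death
#' tree stopped once \code{nExtant} extant species exist, Poisson fossil
#' recovery at rate \code{psi}, rejection of replicates whose origin falls
#' outside \code{[originMin, originMax]} Ma or whose fossil count falls
#' outside \code{[fossilMin, fossilMax]}, and extant sampling probability
#' \code{rho}.
#'
#' Defaults are the mammal-like regime used throughout the package:
#' speciation 0.15/Myr, extinction 0.1/Myr, fossilization 0.2/Myr, 25 extant
#' species, complete extant sampling, origin between 40 and 100 Ma and 4 to
#' 125 fossils per replicate.
#'
#' @param lambda speciation rate per Myr (> mu).
#' @param mu extinction rate per Myr (>= 0).
#' @param psi fossil recovery rate per Myr (>= 0).
#' @param rho extant species sampling probability in (0, 1].
#' @param nExtant number of extant species to condition on (>= 2).
#' @param originMin,originMax accepted origin-age window in Ma.
#' @param fossilMin,fossilMax accepted fossil-count window (fossilMin >= 1).
#' @return a list of class \code{"simConfig"}.
#' @export
simConfig <- function(lambda = 0.15, mu = 0.1, psi = 0.2, rho = 1,
                      nExtant = 25, originMin = 40, originMax = 100,
                      fossilMin = 4, fossilMax = 125) {
  stopifnot(lambda > 0, lambda > mu, mu >= 0, psi >= 0,
            rho > 0, rho <= 1, nExtant >= 2, fossilMin >= 1,
            originMin >= 0, originMax > originMin, fossilMax >= fossilMin)
  structure(list(lambda = lambda, mu = mu, psi = psi, rho = rho,
                 nExtant = nExtant, originMin = originMin,
                 originMax = originMax, fossilMin = fossilMin,
                 fossilMax = fossilMax),
            class = "simConfig")
}

#' Simulate a complete birth-death tree conditioned on extant-tip count
#'
#' Forward (Gillespie) simulation from a single lineage at the origin:
#' lineages speciate at rate lambda and go extinct at rate mu.  The process
#' is stopped at the instant the \code{nExtant}-th extant lineage is born;
#' that instant is the present (age 0) and all ages are measured backwards
#' from it.  All extinct lineages are retained (the "complete" tree).
#' Replicates that die out before reaching \code{nExtant} lineages are
#' silently re-drawn, up to \code{maxTries} attempts.
#'
#' @param config a \code{\link{simConfig}}.
#' @param maxTries number of re-draws before giving up.
#' @return a \code{timeTree} with exactly \code{nExtant} extant tips; its
#'   \code{origin} is the total elapsed time of the process.
#' @export
simCompleteTree <- function(config, maxTries = 10000L) {
  lambda <- config$lambda; mu <- config$mu; n <- config$nExtant
  pSpec <- lambda / (lambda + mu)
  for (try in seq_len(maxTries)) {
    # flat node arrays, grown by doubling; each alive lineage remembers only
    # the node id of the speciation event that created it
    cap <- 8L * n
    parent <- integer(cap); etime <- numeric(cap); type <- integer(cap)
    nNode <- 0L
    aliveParent <- integer(n); aliveParent[1L] <- 0L
    nAlive <- 1L; t <- 0; died <- FALSE
    repeat {
      if (nNode + n + 1L > cap) {
        parent <- c(parent, integer(cap)); etime <- c(etime, numeric(cap))
        type <- c(type, integer(cap)); cap <- 2L * cap
      }
      t <- t + stats::rexp(1L, nAlive * (lambda + mu))
      i <- if (nAlive == 1L) 1L else sample.int(nAlive, 1L)
      nNode <- nNode + 1L
      parent[nNode] <- aliveParent[i]; etime[nNode] <- t
      if (stats::runif(1L) < pSpec) {
        type[nNode] <- 0L                        # internal (speciation)
        aliveParent[i] <- nNode
        nAlive <- nAlive + 1L
        aliveParent[nAlive] <- nNode
        if (nAlive == n) break
      } else {
        type[nNode] <- 1L                        # extinct tip
        aliveParent[i] <- aliveParent[nAlive]
        nAlive <- nAlive - 1L
        if (nAlive == 0L) { died <- TRUE; break }
      }
    }
    if (died) next                               # died out: re-draw
    # observe the tree at the end of the n-species holding interval (just
    # before the next event would fire); observing exactly at the n-th
    # birth would place a speciation node at age zero
    t <- t + stats::rexp(1L, nAlive * (lambda + mu))
    for (i in seq_len(nAlive)) {                 # alive lineages -> extant tips
      nNode <- nNode + 1L
      parent[nNode] <- aliveParent[i]; etime[nNode] <- t; type[nNode] <- 2L
    }
    parent <- parent[seq_len(nNode)]
    etime <- etime[seq_len(nNode)]
    type <- type[seq_len(nNode)]
    age <- t - etime
    age[type == 2L] <- 0                         # exact zero for extant tips
    status <- c("internal", "extinct", "extant")[type + 1L]
    label <- character(nNode)
    label[type == 2L] <- paste0("extant_", seq_len(sum(type == 2L)))
    label[type == 1L] <- paste0("extinct_", seq_len(sum(type == 1L)))
    return(timeTree(parent, age, label, status, origin = t))
  }
  stop("birth-death process died out in all ", maxTries, " attempts")
}

#' Sample fossil occurrences on a complete tree
#'
#' Fossils occur on every branch (the stem branch included) following a
#' Poisson process with constant rate \code{psi} per Myr; occurrence ages
#' are uniform within the branch's time span.  Any number of fossils can be
#' sampled for a given species.
#'
#' @param tree a complete \code{timeTree}.
#' @param psi fossil recovery rate per Myr.
#' @return a data.frame of class \code{"fossilTable"} with columns
#'   \code{id}, \code{lineage} (index of the branch's child node in
#'   \code{tree}), \code{true_age}, and placeholder stratigraphic columns
#'   \code{min_age}, \code{max_age}, \code{operational_age} (NA until age
#'   handling is applied).
#' @export
simFossils <- function(tree, psi) {
  stopifnot(psi >= 0)
  dur <- branchDurations(tree)
  counts <- stats::rpois(length(dur), psi * dur)
  lineage <- rep(seq_along(dur), counts)
  hi <- ifelse(tree$parent == 0L, tree$origin, tree$age[pmax(tree$parent, 1L)])
  ages <- stats::runif(length(lineage), tree$age[lineage], hi[lineage])
  out <- data.frame(id = seq_along(lineage), lineage = lineage,
                    true_age = ages,
                    min_age = rep(NA_real_, length(lineage)),
                    max_age = rep(NA_real_, length(lineage)),
                    operational_age = rep(NA_real_, length(lineage)))
  class(out) <- c("fossilTable", "data.frame")
  out
}

#' Accept or reject a simulated replicate
#'
#' A replicate is accepted iff the origin age lies within the configured
#' window (40--100 Ma by default) and the number of sampled fossils lies
#' within the configured range (4--125 by default), both inclusive.
#'
#' @param tree a complete \code{timeTree}.
#' @param fossils a \code{fossilTable} from \code{\link{simFossils}}.
#' @param config a \code{\link{simConfig}}.
#' @return logical flag.
#' @export
acceptReplicate <- function(tree, fossils, config) {
  nf <- nrow(fossils)
  tree$origin >= config$originMin && tree$origin <= config$originMax &&
    nf >= config$fossilMin && nf <= config$fossilMax
}

#' Prune a complete tree to the sampled (FBD) tree
#'
#' Keeps the extant samples (each extant tip independently with probability
#' \code{rho}; all of them when \code{rho = 1}) and the fossil occurrences,
#' and discards all unsampled lineages.  A fossil on a lineage with sampled
#' descendants becomes a sampled ancestor -- a binary node at the fossil's
#' age carrying a zero-length fossil tip; a fossil terminating an otherwise
#' unsampled subtree becomes a fossil tip attached at the divergence age of
#' its lineage from the sampled tree.  All node ages and the origin are
#' preserved.
#'
#' @param tree a complete \code{timeTree}.
#' @param fossils a \code{fossilTable} (rows may be zero).
#' @param rho extant sampling probability in (0, 1].
#' @return a list: \code{tree} (the sampled \code{timeTree}), \code{fossils}
#'   (the input table with columns \code{node} -- the fossil's tip index in
#'   the sampled tree -- and \code{sa} added).
#' @export
sampledTree <- function(tree, fossils, rho = 1) {
  stopifnot(rho > 0, rho <= 1)
  extant <- which(tree$status == "extant")
  keepExt <- if (rho >= 1) extant else extant[stats::runif(length(extant)) < rho]
  if (length(keepExt) + nrow(fossils) == 0L)
    stop("no extant samples and no fossils: nothing to build a sampled tree from")

  # Augment: insert, on each fossil-bearing branch, a chain of attachment
  # nodes (oldest first) each carrying the fossil as a same-age tip child.
  n0 <- length(tree$parent)
  nf <- nrow(fossils)
  parent <- c(tree$parent, integer(2L * nf))
  age <- c(tree$age, numeric(2L * nf))
  label <- c(tree$label, character(2L * nf))
  status <- c(tree$status, character(2L * nf))
  fossilNode <- integer(nf)
  nxt <- n0
  if (nf > 0L) {
    ord <- order(fossils$lineage, -fossils$true_age)
    for (k in ord) {
      L <- fossils$lineage[k]; a <- fossils$true_age[k]
      attach <- nxt + 1L; ftip <- nxt + 2L; nxt <- nxt + 2L
      parent[attach] <- parent[L]; age[attach] <- a
      label[attach] <- ""; status[attach] <- "internal"
      parent[ftip] <- attach; age[ftip] <- a
      label[ftip] <- paste0("fossil_", fossils$id[k]); status[ftip] <- "fossil"
      parent[L] <- attach
      fossilNode[k] <- ftip
    }
  }
  aug <- timeTree(parent[seq_len(nxt)], age[seq_len(nxt)],
                  label[seq_len(nxt)], status[seq_len(nxt)],
                  origin = tree$origin,
                  sa = c(tree$sa, rep(TRUE, nxt - n0))[seq_len(nxt)] &
                    status[seq_len(nxt)] == "fossil")
  samples <- c(keepExt, fossilNode)
  # a fossil tip is a sampled ancestor iff its attachment node survives the
  # pruning, i.e. the continuation below the attachment carries samples
  pr <- subtreeSpanned(aug, samples, saNodes = fossilNode)
  newTree <- pr$tree
  # recompute SA flags from the realized structure: fossil tip whose parent
  # in the pruned tree has the same age
  newTree$sa[] <- FALSE
  ftipNew <- match(fossilNode, pr$nodeMap)
  for (i in seq_along(ftipNew)) {
    v <- ftipNew[i]
    if (!is.na(v) && newTree$parent[v] != 0L &&
        abs(newTree$age[v] - newTree$age[newTree$parent[v]]) <= 1e-12)
      newTree$sa[v] <- TRUE
  }
  validateTimeTree(newTree)
  fs <- fossils
  fs$node <- ftipNew
  fs$sa <- newTree$sa[ftipNew]
  list(tree = newTree, fossils = fs)
}

#' Simulate one accepted replicate (tree + fossils + sampled tree)
#'
#' Runs \code{\link{simCompleteTree}}, \code{\link{simFossils}} and the
#' rejection step until a replicate satisfies the origin-age and
#' fossil-count conditions, then prunes to the sampled tree.
#'
#' @param config a \code{\link{simConfig}}.
#' @param maxTries bound on rejection re-draws.
#' @return a list: \code{complete} (complete \code{timeTree}),
#'   \code{fossils} (the \code{fossilTable} with sampled-tree columns),
#'   \code{sampled} (the sampled \code{timeTree}), \code{tries} (number of
#'   draws used).
#' @export
simReplicate <- function(config, maxTries = 10000L) {
  for (try in seq_len(maxTries)) {
    tr <- simCompleteTree(config)
    fs <- simFossils(tr, config$psi)
    if (!acceptReplicate(tr, fs, config)) next
    st <- sampledTree(tr, fs, config$rho)
    return(list(complete = tr, fossils = st$fossils, sampled = st$tree,
                tries = try))
  }
  stop("no replicate accepted in ", maxTries, " attempts")
}
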