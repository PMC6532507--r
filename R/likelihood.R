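#' Build a cached pruning-likelihood engine for a fixed topology
#'
#' Wraps the compiled Felsenstein pruning kernel.  The engine holds the
#' alignment, the HKY + discrete-gamma model and per-node conditional
#' likelihoods, so that proposals changing a few branch lengths only
#' recompute the affected nodes.  Branch lengths are in expected
#' substitutions per site and indexed by the engine's node numbering (tips
#' first, in alignment column order, then internal nodes in postorder; the
#' root is the last node and carries no branch).
#'
#' @param aln an \code{fbdAlignment} (sites x taxa integer matrix; 5 =
#'   missing).
#' @param tree a \code{timeTree} whose tips match the alignment columns
#'   (typically the extant reconstructed tree).
#' @param model an \code{\link{hkyModel}}.
#' @return a list of class \code{"likEngine"}: the external pointer plus the
#'   index maps between tree nodes and engine nodes.
#' @export
likEngine <- function(aln, tree, model) {
  tips <- tipIndices(tree)
  labs <- colnames(aln)
  if (!setequal(tree$label[tips], labs))
    stop("alignment taxa and tree tips do not match")
  n <- length(tree$parent)
  ntip <- length(tips)
  eid <- integer(n)
  eid[tips[match(labs, tree$label[tips])]] <- seq_len(ntip)
  post <- postorderNodes(tree)
  ipost <- post[!(post %in% tips)]
  eid[ipost] <- ntip + seq_along(ipost)
  treeOf <- integer(2L * ntip - 1L)
  treeOf[eid] <- seq_len(n)
  ch <- childrenList(tree)
  child1 <- child2 <- integer(length(ipost))
  for (i in seq_along(ipost)) {
    cc <- eid[ch[[ipost[i]]]]
    if (length(cc) != 2L) stop("likelihood tree must be strictly binary")
    child1[i] <- cc[1]; child2[i] <- cc[2]
  }
  rates <- discreteGammaRates(model$gammaShape, model$nCat)
  ptr <- .engine_create(aln, child1, child2,
                        ntip + seq_along(ipost), rates,
                        model$kappa, model$baseFreqs)
  eparent <- integer(2L * ntip - 1L)
  for (i in seq_along(ipost))
    eparent[c(child1[i], child2[i])] <- ntip + i
  # ancestor path of each node (itself first if internal, then up to root);
  # engine internal ids increase towards the root, so paths are sorted
  anc <- vector("list", 2L * ntip - 1L)
  for (v in seq_len(2L * ntip - 1L)) {
    p <- if (v > ntip) v else eparent[v]
    path <- integer(0)
    while (p != 0L) { path <- c(path, p); p <- eparent[p] }
    anc[[v]] <- path
  }
  echildren <- vector("list", 2L * ntip - 1L)
  for (i in seq_along(ipost)) echildren[[ntip + i]] <- c(child1[i], child2[i])
  structure(list(ptr = ptr, ntip = ntip, nnode = 2L * ntip - 1L,
                 engineOf = eid, treeOf = treeOf, eparent = eparent,
                 anc = anc, echildren = echildren, model = model),
            class = "likEngine")
}

# branch lengths (subst/site) for the current ages of the mapped tree nodes
engineBranchLengths <- function(engine, age, clockRate) {
  v <- seq_len(engine$nnode)
  tv <- engine$treeOf[v]
  pa <- engine$eparent[v]
  len <- numeric(engine$nnode)
  nz <- which(pa != 0L)
  len[nz] <- (age[engine$treeOf[pa[nz]]] - age[tv[nz]]) * clockRate
  len
}

#' Moment-matching starting value for the clock rate
#'
#' Crude likelihood-free estimate used to seed the MCMC: the median over
#' tip pairs of (Jukes-Cantor-corrected distance) / (2 x MRCA age).
#'
#' @param aln an \code{fbdAlignment}.
#' @param tree a \code{timeTree} with the alignment's taxa as extant tips.
#' @param maxPairs subsample size of tip pairs.
#' @return substitutions/site/Myr.
#' @export
estimateClockRate <- function(aln, tree, maxPairs = 60L) {
  tips <- tipIndices(tree)
  tips <- tips[match(colnames(aln), tree$label[tips])]
  nt <- length(tips)
  prs <- utils::combn(nt, 2L)
  if (ncol(prs) > maxPairs)
    prs <- prs[, sample.int(ncol(prs), maxPairs), drop = FALSE]
  est <- apply(prs, 2L, function(ij) {
    p <- mean(aln[, ij[1]] != aln[, ij[2]])
    p <- min(p, 0.74)
    d <- -0.75 * log(1 - 4 * p / 3)
    a <- mrcaNode(tree, tree$label[tips[ij]])
    d / (2 * tree$age[a])
  })
  max(stats::median(est), 1e-6)
}

#' Phylogenetic log-likelihood under HKY + discrete gamma
#'
#' One-shot pruning likelihood of an alignment on a time tree with a strict
#' clock rate: the expected number of substitutions on a branch is its
#' duration (Myr) times \code{clockRate}, integrated over the discrete-gamma
#' site-rate categories.  Taxa present in the tree but absent from the
#' alignment must not occur; fossils carry no characters, so the likelihood
#' is evaluated on the extant reconstructed tree.
#'
#' @param aln an \code{fbdAlignment} covering exactly the tree's tips.
#' @param tree a \code{timeTree} (extant tips only).
#' @param model an \code{\link{hkyModel}}.
#' @param clockRate substitutions/site/Myr.
#' @param branchRates optional per-tree-node relative rate multipliers
#'   (indexed like \code{tree$parent}), for relaxed-clock likelihoods.
#' @return log-likelihood.
#' @export
phyloLogLik <- function(aln, tree, model, clockRate, branchRates = NULL) {
  eng <- likEngine(aln, tree, model)
  len <- engineBranchLengths(eng, tree$age, clockRate)
  if (!is.null(branchRates))
    len <- len * branchRates[eng$treeOf[seq_len(eng$nnode)]]
  .engine_set_all(eng$ptr, len)
}
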