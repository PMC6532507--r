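#' Time-calibrated trees with fossil and sampled-ancestor annotations
#'
#' A \code{timeTree} is the central object of the package: a rooted binary
#' tree whose nodes carry absolute ages in Ma (million years before present,
#' present = 0).  It is stored as a flat node table: integer parent pointers
#' (0 for the root), node ages, tip labels and a per-node status.  The age of
#' the origin of the process (the start of the stem lineage, at or above the
#' root) is carried alongside.
#'
#' Statuses are \code{"extant"} (tip, age 0), \code{"extinct"} (tip of the
#' complete tree that left no sample), \code{"fossil"} (sampled fossil
#' specimen) and \code{"internal"}.  Sampled ancestors -- fossil specimens
#' that lie on a lineage with sampled descendants -- are represented by the
#' zero-length-branch convention: a \code{"fossil"} tip attached to a binary
#' node of exactly the same age, flagged in \code{sa}.
#'
#' @param parent integer vector of parent node indices, 0 for the root.
#' @param age numeric vector of node ages in Ma before present.
#' @param label character vector of node labels ("" allowed for internals).
#' @param status character vector, each element one of \code{"extant"},
#'   \code{"extinct"}, \code{"fossil"}, \code{"internal"}.
#' @param origin age of the origin of the process in Ma; must be >= root age.
#' @param sa logical vector flagging sampled-ancestor fossil tips.
#'
#' @return An object of class \code{"timeTree"}.
#' @export
timeTree <- function(parent, age, label, status, origin, sa = NULL) {
  n <- length(parent)
  if (is.null(sa)) sa <- rep(FALSE, n)
  tr <- structure(
    list(parent = as.integer(parent), age = as.numeric(age),
         label = as.character(label), status = as.character(status),
         origin = as.numeric(origin), sa = as.logical(sa)),
    class = "timeTree")
  validateTimeTree(tr)
  tr
}

#' Validate the structural invariants of a timeTree
#'
#' Checks: exactly one root; every child strictly younger than its parent
#' (sampled-ancestor attachments may share the parent's age); extant tips at
#' age 0; origin >= root age; statuses consistent with tip/internal roles.
#'
#' @param tree a \code{timeTree}.
#' @param tol numeric tolerance for age comparisons.
#' @return \code{tree}, invisibly; errors on violation.
#' @export
validateTimeTree <- function(tree, tol = 1e-9) {
  n <- length(tree$parent)
  stopifnot(length(tree$age) == n, length(tree$label) == n,
            length(tree$status) == n, length(tree$sa) == n)
  root <- which(tree$parent == 0L)
  if (length(root) != 1L)
    stop("timeTree must have exactly one root, found ", length(root))
  if (n > 1L) {
    ch <- which(tree$parent != 0L)
    bad <- tree$age[ch] > tree$age[tree$parent[ch]] + tol
    if (any(bad))
      stop("child older than its parent at node(s) ", paste(ch[bad], collapse = ", "))
    eq <- abs(tree$age[ch] - tree$age[tree$parent[ch]]) <= tol
    if (any(eq & !tree$sa[ch]))
      stop("zero-length branch at non-sampled-ancestor node(s) ",
           paste(ch[eq & !tree$sa[ch]], collapse = ", "))
  }
  tips <- tipIndices(tree)
  if (any(tree$status[tips] == "internal"))
    stop("tip node(s) with status 'internal'")
  if (any(tree$status[-tips] != "internal") && n > 1L)
    stop("internal node(s) with tip status")
  ext <- tips[tree$status[tips] == "extant"]
  if (any(abs(tree$age[ext]) > tol))
    stop("extant tip(s) with non-zero age")
  if (tree$origin < tree$age[root] - tol)
    stop("origin age (", tree$origin, ") below root age (", tree$age[root], ")")
  invisible(tree)
}

#' @export
print.timeTree <- function(x, ...) {
  tips <- tipIndices(x)
  st <- table(factor(x$status[tips], c("extant", "extinct", "fossil")))
  cat("timeTree:", length(x$parent), "nodes,", length(tips), "tips",
      sprintf("(%d extant, %d extinct, %d fossil; %d sampled ancestors)\n",
              st[["extant"]], st[["extinct"]], st[["fossil"]], sum(x$sa)))
  cat(sprintf("  origin %.3f Ma, root %.3f Ma\n", x$origin, rootAge(x)))
  invisible(x)
}

#' @rdname timeTree
#' @export
rootIndex <- function(tree) which(tree$parent == 0L)

#' @rdname timeTree
#' @export
rootAge <- function(tree) tree$age[rootIndex(tree)]

#' Indices of tip nodes (nodes that are no node's parent)
#' @param tree a \code{timeTree}.
#' @export
tipIndices <- function(tree) {
  n <- length(tree$parent)
  which(!(seq_len(n) %in% tree$parent))
}

#' Children of each node, as a list indexed by node
#' @param tree a \code{timeTree}.
#' @export
childrenList <- function(tree) {
  n <- length(tree$parent)
  ch <- vector("list", n)
  idx <- which(tree$parent != 0L)
  sp <- split(idx, tree$parent[idx])
  ch[as.integer(names(sp))] <- sp
  ch
}

#' Postorder traversal (children before parents)
#' @param tree a \code{timeTree}.
#' @return integer vector of node indices in postorder.
#' @export
postorderNodes <- function(tree) {
  # iterative DFS from the root
  ch <- childrenList(tree)
  root <- rootIndex(tree)
  n <- length(tree$parent)
  out <- integer(n); stack <- integer(n)
  stack[1] <- root; sp <- 1L; op <- n
  # reverse preorder = postorder for our purposes (parents before children
  # reversed gives children before parents)
  pre <- integer(n); pp <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    pp <- pp + 1L; pre[pp] <- v
    for (c in ch[[v]]) { sp <- sp + 1L; stack[sp] <- c }
  }
  rev(pre)
}

#' Branch durations in Myr (age of parent minus age of child)
#'
#' The root's branch is the stem: origin age minus root age.
#'
#' @param tree a \code{timeTree}.
#' @return numeric vector indexed by child node.
#' @export
branchDurations <- function(tree) {
  pa <- ifelse(tree$parent == 0L, tree$origin, tree$age[pmax(tree$parent, 1L)])
  pa - tree$age
}

#' Total tree length (sum of all branch durations, stem included)
#' @param tree a \code{timeTree}.
#' @export
treeLength <- function(tree) sum(branchDurations(tree))

#' Convert a timeTree to an ape "phylo" object
#'
#' Sampled ancestors appear as zero-length terminal branches (the on-disk
#' convention used throughout the package); the stem branch is stored in
#' \code{root.edge}.
#'
#' @param tree a \code{timeTree}.
#' @return an object of class \code{"phylo"}.
#' @export
asPhylo <- function(tree) {
  tips <- tipIndices(tree)
  n <- length(tree$parent)
  ntip <- length(tips)
  internal <- setdiff(seq_len(n), tips)
  # ape numbering: tips 1..ntip, root ntip+1, then other internals
  root <- rootIndex(tree)
  map <- integer(n)
  map[tips] <- seq_len(ntip)
  map[root] <- ntip + 1L
  rest <- setdiff(internal, root)
  map[rest] <- ntip + 1L + seq_along(rest)
  ch <- which(tree$parent != 0L)
  edge <- cbind(map[tree$parent[ch]], map[ch])
  len <- tree$age[tree$parent[ch]] - tree$age[ch]
  lab <- tree$label[tips]
  lab[lab == ""] <- paste0("t", tips[lab == ""])
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = lab, Nnode = length(internal)),
                   class = "phylo", order = "cladewise")
  phy$root.edge <- tree$origin - tree$age[root]
  ape::reorder.phylo(phy)
}

#' Convert an ape "phylo" object to a timeTree
#'
#' Node ages are recovered from branch lengths assuming the most distant tip
#' from the root sits at the present (age 0) unless \code{youngestTipAge}
#' says otherwise.  Tips at age > \code{saTol} above 0 are classified as
#' fossils; zero-length terminal branches are flagged as sampled ancestors.
#'
#' @param phy a \code{"phylo"} object with branch lengths in Myr.
#' @param origin origin age; defaults to root age plus \code{phy$root.edge}
#'   (or the root age when no root edge is present).
#' @param youngestTipAge age of the youngest tip, default 0.
#' @param saTol zero-branch tolerance for sampled-ancestor detection.
#' @return a \code{timeTree}.
#' @export
timeTreeFromPhylo <- function(phy, origin = NULL, youngestTipAge = 0,
                              saTol = 1e-6) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  depth <- numeric(nn)          # distance from root
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge)))
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + ord$edge.length[i]
  age <- max(depth[seq_len(ntip)]) - depth + youngestTipAge
  age[abs(age) <= saTol] <- 0          # snap rounded tip depths to present
  parent <- integer(nn)
  parent[ord$edge[, 2]] <- ord$edge[, 1]
  label <- c(phy$tip.label, rep("", phy$Nnode))
  status <- rep("internal", nn)
  isTip <- seq_len(nn) <= ntip
  status[isTip] <- ifelse(age[seq_len(ntip)] <= saTol, "extant", "fossil")
  sa <- rep(FALSE, nn)
  zl <- which(isTip & parent != 0L)
  zl <- zl[abs(age[zl] - age[parent[zl]]) <= saTol & status[zl] == "fossil"]
  sa[zl] <- TRUE
  age[zl] <- age[parent[zl]]           # snap sampled ancestors onto parents
  # rounding in the Newick text can leave a child marginally older than its
  # parent; nudge such nodes just below
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; v <- ord$edge[i, 2]
    if (!sa[v] && age[v] != 0 && age[v] > age[p] - 1e-9 &&
        age[v] - age[p] <= saTol)
      age[v] <- age[p] - 1e-7
  }
  rootA <- age[ntip + 1L]
  if (is.null(origin))
    origin <- rootA + if (!is.null(phy$root.edge)) phy$root.edge else 0
  timeTree(parent, age, label, status, origin, sa)
}

#' Reconstructed extant-species tree of a sampled tree
#'
#' Drops fossil tips and sampled ancestors and suppresses the resulting
#' degree-2 nodes, returning the tree spanned by the extant tips together
#' with the map from its nodes to the nodes of the input tree.  Those mapped
#' internal nodes are exactly the most recent common ancestors of extant
#' tip sets -- the node class over which divergence-time metrics are
#' averaged.
#'
#' @param tree a \code{timeTree} containing at least two extant tips.
#' @return a list with elements \code{tree} (the extant \code{timeTree}) and
#'   \code{nodeMap} (integer vector: for each node of the extant tree, the
#'   corresponding node index in \code{tree}).
#' @export
extantTree <- function(tree) {
  keep <- which(tree$status == "extant")
  if (length(keep) < 2L) stop("need at least two extant tips")
  subtreeSpanned(tree, keep)
}

# Tree spanned by a set of sample nodes: keep a node iff it is a sample or
# has >= 2 children whose subtrees contain samples; reconnect to the nearest
# kept ancestor.  Returns the new timeTree plus node maps.
subtreeSpanned <- function(tree, samples, saNodes = integer(0)) {
  n <- length(tree$parent)
  isSample <- logical(n); isSample[samples] <- TRUE
  post <- postorderNodes(tree)
  nbelow <- integer(n)       # number of samples at or below each node
  keptch <- integer(n)       # children with samples below
  for (v in post) {
    nbelow[v] <- nbelow[v] + isSample[v]
    p <- tree$parent[v]
    if (p != 0L) {
      nbelow[p] <- nbelow[p] + nbelow[v]
      if (nbelow[v] > 0L) keptch[p] <- keptch[p] + 1L
    }
  }
  kept <- isSample | keptch >= 2L
  korder <- which(kept)
  newId <- integer(n); newId[korder] <- seq_along(korder)
  np <- integer(length(korder))
  for (i in seq_along(korder)) {
    p <- tree$parent[korder[i]]
    while (p != 0L && !kept[p]) p <- tree$parent[p]
    np[i] <- if (p == 0L) 0L else newId[p]
  }
  if (sum(np == 0L) != 1L) stop("pruning produced no unique root")
  sa <- logical(length(korder))
  sa[newId[intersect(saNodes, korder)]] <- TRUE
  st <- tree$status[korder]
  st[!isSample[korder]] <- "internal"   # surviving branching nodes
  out <- timeTree(np, tree$age[korder], tree$label[korder], st,
                  tree$origin, sa)
  list(tree = out, nodeMap = korder)
}

#' Most recent common ancestor of a set of tip labels
#' @param tree a \code{timeTree}.
#' @param labels character vector of tip labels (length >= 2).
#' @return node index of the MRCA.
#' @export
mrcaNode <- function(tree, labels) {
  idx <- match(labels, tree$label)
  if (anyNA(idx)) stop("unknown tip label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  anc <- function(v) {
    path <- integer(0)
    while (v != 0L) { path <- c(path, v); v <- tree$parent[v] }
    path
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[which.min(tree$age[common])]
}
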