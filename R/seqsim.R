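#' HKY + Gamma substitution model settings
#'
#' Defaults follow the simulation conditions used throughout the package:
#' transition/transversion ratio 5, equal base frequencies, gamma shape 0.25
#' with 5 discrete rate categories.
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param baseFreqs length-4 vector of A, C, G, T frequencies summing to 1.
#' @param gammaShape shape of the gamma distribution of site rates (> 0).
#' @param nCat number of discrete rate categories (>= 1).
#' @return a list of class \code{"hkyModel"}.
#' @export
hkyModel <- function(kappa = 5, baseFreqs = rep(0.25, 4),
                     gammaShape = 0.25, nCat = 5L) {
  stopifnot(kappa > 0, length(baseFreqs) == 4, all(baseFreqs > 0),
            abs(sum(baseFreqs) - 1) < 1e-8, gammaShape > 0, nCat >= 1)
  structure(list(kappa = kappa, baseFreqs = baseFreqs,
                 gammaShape = gammaShape, nCat = as.integer(nCat)),
            class = "hkyModel")
}

#' HKY transition probability matrix
#'
#' Closed-form P(t) for the HKY85 model with the rate matrix normalized to
#' one expected substitution per unit of \code{t} at stationarity.  Rows are
#' the starting state, columns the ending state, order A, C, G, T.
#'
#' @param t branch length in expected substitutions per site (>= 0).
#' @param kappa transition/transversion ratio.
#' @param freqs stationary base frequencies (A, C, G, T).
#' @return a 4x4 row-stochastic matrix.
#' @export
hkyProbs <- function(t, kappa = 5, freqs = rep(0.25, 4)) {
  stopifnot(t >= 0, kappa > 0, length(freqs) == 4)
  piA <- freqs[1]; piC <- freqs[2]; piG <- freqs[3]; piT <- freqs[4]
  piR <- piA + piG; piY <- piC + piT
  beta <- 1 / (2 * piR * piY + 2 * kappa * (piA * piG + piC * piT))
  A <- c(piR, piY, piR, piY)            # group frequency of each target state
  e2 <- exp(-beta * t)
  e3 <- exp(-beta * t * (A * kappa + (1 - A)))
  P <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) {
      P[i, j] <- freqs[j] + freqs[j] * (1 / A[j] - 1) * e2 +
        (A[j] - freqs[j]) / A[j] * e3[j]
    } else if (purine[i] == purine[j]) {          # transition
      P[i, j] <- freqs[j] + freqs[j] * (1 / A[j] - 1) * e2 -
        freqs[j] / A[j] * e3[j]
    } else {                                      # transversion
      P[i, j] <- freqs[j] * (1 - e2)
    }
  }
  P
}

#' Discrete-gamma site rate categories
#'
#' Standard equal-probability discretization: category boundaries are the
#' quantiles of the mean-one gamma distribution with shape \code{alpha};
#' the representative rate of each category is the conditional mean within
#' its bin (computed through the incomplete-gamma identity), renormalized so
#' the rates average exactly 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories.
#' @return numeric vector of \code{k} positive rates with mean 1.
#' @export
discreteGammaRates <- function(alpha, k = 5L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  cdf1 <- stats::pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  rates <- k * diff(cdf1)
  rates / mean(rates)
}

#' Draw an uncorrelated lognormal relaxed clock for a tree
#'
#' The mean substitution rate is drawn once per tree from
#' Gamma(shape 2, scale 2)/100 (substitutions/site/Myr); each branch then
#' receives an independent lognormal rate with real-space mean equal to the
#' tree's mean rate and log-space standard deviation \code{logSd}.  The
#' Gamma's second parameter is interpreted as the scale by default (mean
#' rate 0.04); set \code{betaIsScale = FALSE} for the rate-parameter
#' convention (mean rate 0.01).
#'
#' @param tree a \code{timeTree}; rates are indexed by the child node of
#'   each branch (stem branch included at the root's index).
#' @param meanRate optional fixed mean rate; when NULL it is drawn.
#' @param logSd standard deviation of log branch rates.
#' @param shape,beta parameters of the gamma distribution of the mean rate.
#' @param betaIsScale interpret \code{beta} as the scale parameter.
#' @return a list of class \code{"relaxedClock"} with elements
#'   \code{meanRate}, \code{logSd}, \code{branchRates}.
#' @export
simClock <- function(tree, meanRate = NULL, logSd = 0.1,
                     shape = 2, beta = 2, betaIsScale = TRUE) {
  if (is.null(meanRate)) {
    meanRate <- if (betaIsScale)
      stats::rgamma(1L, shape = shape, scale = beta) / 100
    else stats::rgamma(1L, shape = shape, rate = beta) / 100
  }
  stopifnot(meanRate > 0, logSd >= 0)
  n <- length(tree$parent)
  br <- if (logSd == 0) rep(meanRate, n) else
    stats::rlnorm(n, meanlog = log(meanRate) - logSd^2 / 2, sdlog = logSd)
  structure(list(meanRate = meanRate, logSd = logSd, branchRates = br),
            class = "relaxedClock")
}

#' Simulate a nucleotide alignment on a time tree
#'
#' Sequences evolve root-to-tips under HKY + discrete-gamma with the given
#' relaxed clock: the expected number of substitutions on a branch at a site
#' is branch duration (Myr) x branch rate (subst/site/Myr) x the site's
#' category rate.  Site categories are i.i.d. across sites and fixed across
#' the tree.  Only extant tips receive sequences (fossil specimens carry no
#' character data).
#'
#' @param tree a \code{timeTree} (typically the extant reconstructed tree).
#' @param clock a \code{\link{simClock}} object for \code{tree}.
#' @param model an \code{\link{hkyModel}}.
#' @param nSites alignment length in nucleotides.
#' @return integer matrix (sites x extant tips, values 1--4 for A, C, G, T)
#'   of class \code{"fbdAlignment"}, with tip labels as column names and the
#'   site category assignment in \code{attr(, "siteCat")}.
#' @export
simAlignment <- function(tree, clock, model, nSites = 2000L) {
  stopifnot(inherits(model, "hkyModel"), nSites >= 1)
  rates <- discreteGammaRates(model$gammaShape, model$nCat)
  siteCat <- sample.int(model$nCat, nSites, replace = TRUE)
  n <- length(tree$parent)
  states <- matrix(0L, nSites, n)
  root <- rootIndex(tree)
  states[, root] <- sample.int(4L, nSites, replace = TRUE,
                               prob = model$baseFreqs)
  ord <- rev(postorderNodes(tree))              # parents before children
  dur <- branchDurations(tree)
  for (v in ord) {
    if (v == root) next
    t0 <- dur[v] * clock$branchRates[v]
    ps <- states[, tree$parent[v]]
    for (c in seq_len(model$nCat)) {
      s <- which(siteCat == c)
      if (!length(s)) next
      P <- hkyProbs(t0 * rates[c], model$kappa, model$baseFreqs)
      cp <- t(apply(P, 1L, cumsum))
      u <- stats::runif(length(s))
      pc <- ps[s]
      states[s, v] <- 1L + (u > cp[cbind(pc, 1L)]) +
        (u > cp[cbind(pc, 2L)]) + (u > cp[cbind(pc, 3L)])
    }
  }
  keep <- which(tree$status == "extant")
  aln <- states[, keep, drop = FALSE]
  colnames(aln) <- tree$label[keep]
  attr(aln, "siteCat") <- siteCat
  class(aln) <- c("fbdAlignment", class(aln))
  aln
}

#' Convert an integer alignment to character sequences
#' @param aln an \code{fbdAlignment} matrix.
#' @return character matrix of A/C/G/T.
#' @export
alignmentToChar <- function(aln) {
  m <- matrix(c("a", "c", "g", "t")[aln], nrow(aln), ncol(aln))
  colnames(m) <- colnames(aln)
  m
}

#' Write an alignment as FASTA
#' @param aln an \code{fbdAlignment}.
#' @param file output path.
#' @export
writeAlignmentFasta <- function(aln, file) {
  ch <- alignmentToChar(aln)
  bin <- ape::as.DNAbin(t(ch))
  ape::write.FASTA(bin, file)
}

#' Write an alignment as NEXUS
#' @param aln an \code{fbdAlignment}.
#' @param file output path.
#' @export
writeAlignmentNexus <- function(aln, file) {
  ch <- t(alignmentToChar(aln))
  lst <- split(ch, row(ch))
  names(lst) <- rownames(ch)
  ape::write.nexus.data(lst, file, interleaved = FALSE)
}

#' Read a FASTA alignment into the internal integer representation
#' @param file FASTA path.
#' @return an \code{fbdAlignment} integer matrix (sites x taxa).
#' @export
readAlignmentFasta <- function(file) {
  bin <- ape::read.FASTA(file)
  ch <- tolower(as.character(as.matrix(bin)))
  m <- matrix(match(ch, c("a", "c", "g", "t")), nrow(ch), ncol(ch))
  m[is.na(m)] <- 5L      # anything ambiguous -> missing
  aln <- t(m)
  colnames(aln) <- labels(bin)
  class(aln) <- c("fbdAlignment", class(aln))
  aln
}
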