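#' FBD parameters on the inference scale
#'
#' The sampler works with diversification \code{d = lambda - mu} (/Myr),
#' turnover \code{nu = mu / lambda} (in [0, 1)) and sampling proportion
#' \code{s = psi / (mu + psi)} (in [0, 1]), with the extant sampling
#' probability \code{rho} fixed.  The map to the canonical rates is
#' bijective: \code{lambda = d / (1 - nu)}, \code{mu = nu d / (1 - nu)},
#' \code{psi = s mu / (1 - s)}.
#'
#' @param d diversification rate (> 0).
#' @param nu turnover in [0, 1).
#' @param s sampling proportion in [0, 1].
#' @param rho extant sampling probability in (0, 1].
#' @return a list of class \code{"fbdParams"}.
#' @export
fbdParams <- function(d, nu, s, rho = 1) {
  if (!(d > 0)) stop("diversification d must be > 0")
  if (nu < 0 || nu >= 1) stop("turnover nu must lie in [0, 1)")
  if (s < 0 || s > 1) stop("sampling proportion s must lie in [0, 1]")
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  structure(list(d = d, nu = nu, s = s, rho = rho), class = "fbdParams")
}

#' @rdname fbdParams
#' @param params an \code{fbdParams} object.
#' @return \code{fbdRates}: list with \code{lambda}, \code{mu}, \code{psi},
#'   \code{rho}.
#' @export
fbdRates <- function(params) {
  lambda <- params$d / (1 - params$nu)
  mu <- params$nu * lambda
  psi <- if (params$s >= 1) Inf else params$s * mu / (1 - params$s)
  list(lambda = lambda, mu = mu, psi = psi, rho = params$rho)
}

#' @rdname fbdParams
#' @param lambda,mu,psi speciation, extinction and fossilization rates /Myr.
#' @export
fbdParamsFromRates <- function(lambda, mu, psi, rho = 1) {
  fbdParams(d = lambda - mu, nu = mu / lambda,
            s = if (mu + psi == 0) 0 else psi / (mu + psi), rho = rho)
}

# c1, c2 constants and the q / p0 functions of the FBD process.
fbdConstants <- function(lambda, mu, psi, rho) {
  c1 <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
  c2 <- -(lambda - mu - 2 * lambda * rho - psi) / c1
  list(c1 = c1, c2 = c2)
}

# probability that a lineage starting t Myr ago leaves no sample at all
fbdP0 <- function(t, lambda, mu, psi, rho) {
  k <- fbdConstants(lambda, mu, psi, rho)
  ex <- exp(-k$c1 * t)
  (lambda + mu + psi +
     k$c1 * (ex * (1 - k$c2) - (1 + k$c2)) / (ex * (1 - k$c2) + (1 + k$c2))) /
    (2 * lambda)
}

# log of the q(t) function (per-lineage density factor)
fbdLogQ <- function(t, lambda, mu, psi, rho) {
  k <- fbdConstants(lambda, mu, psi, rho)
  log(4) - k$c1 * t - 2 * log(exp(-k$c1 * t) * (1 - k$c2) + (1 + k$c2))
}

#' Log probability density of a sampled tree under the FBD process
#'
#' Specimen-level fossilized birth-death density of a sampled tree
#' (extant tips, fossil tips, sampled ancestors) conditioned on the origin
#' age.  Writing q(t) and p0(t) for the standard per-lineage factors with
#' constants c1 = sqrt((lambda-mu-psi)^2 + 4 lambda psi) and
#' c2 = -(lambda - mu - 2 lambda rho - psi)/c1, the density is
#' \deqn{\psi^{k+m}\,\rho^{n}\, q(x_0) \prod_i \lambda\,q(x_i)
#'       \prod_j p_0(y_j)/q(y_j)}
#' over the branching-node ages x_i, fossil-tip ages y_j, m fossil tips,
#' k sampled ancestors and n extant tips.  Sampled ancestors contribute only
#' the bare \eqn{\psi} factor.
#'
#' Returns \code{-Inf} (a rejected state, not an error) when node ages are
#' non-monotone, the origin is younger than the root, or any fossil age lies
#' outside its stratigraphic bounds -- the interval-truncation rule used for
#' the sampled-age handling methods.
#'
#' @param tree a sampled \code{timeTree} (fossil tips flagged, sampled
#'   ancestors via \code{sa}).
#' @param params an \code{\link{fbdParams}} object; invalid parameter values
#'   raise an error.
#' @param fossils optional \code{fossilTable} with columns \code{node},
#'   \code{lower}, \code{upper}; rows with non-NA bounds are enforced.
#' @param origin origin age; defaults to \code{tree$origin}.
#' @return log density (finite or \code{-Inf}).
#' @export
fbdLogDensity <- function(tree, params, fossils = NULL, origin = tree$origin) {
  if (!inherits(params, "fbdParams")) params <- do.call(fbdParams, params)
  r <- fbdRates(params)
  fbdLogDensityRaw(parent = tree$parent, age = tree$age,
                   status = tree$status, sa = tree$sa, origin = origin,
                   lambda = r$lambda, mu = r$mu, psi = r$psi, rho = r$rho,
                   fossilNode = if (!is.null(fossils)) fossils$node,
                   fossilLower = if (!is.null(fossils)) fossils$lower,
                   fossilUpper = if (!is.null(fossils)) fossils$upper)
}

# flat-argument version used inside the sampler (no object construction)
fbdLogDensityRaw <- function(parent, age, status, sa, origin,
                             lambda, mu, psi, rho,
                             fossilNode = NULL, fossilLower = NULL,
                             fossilUpper = NULL) {
  ch <- which(parent != 0L)
  pa <- age[parent[ch]]
  if (any(age[ch] > pa + 1e-12)) return(-Inf)
  root <- which(parent == 0L)
  if (origin < age[root] - 1e-12) return(-Inf)
  if (!is.null(fossilNode) && length(fossilNode)) {
    ok <- is.na(fossilLower) |
      (age[fossilNode] >= fossilLower - 1e-12 &
         age[fossilNode] <= fossilUpper + 1e-12)
    if (!all(ok)) return(-Inf)
  }
  isTip <- !(seq_along(parent) %in% parent)
  saTips <- which(isTip & sa)
  fosTips <- which(isTip & status == "fossil" & !sa)
  nExt <- sum(isTip & status == "extant")
  saAttach <- parent[saTips]
  branching <- which(!isTip & !(seq_along(parent) %in% saAttach))
  m <- length(fosTips); k <- length(saTips)
  ll <- 0
  if (m + k > 0) {
    if (psi <= 0) return(-Inf)
    ll <- ll + (m + k) * log(psi)
  }
  if (rho < 1) ll <- ll + nExt * log(rho)
  x <- c(origin, age[branching])
  ll <- ll + sum(fbdLogQ(x, lambda, mu, psi, rho)) +
    length(branching) * log(lambda)
  if (m > 0) {
    y <- age[fosTips]
    ll <- ll + sum(log(fbdP0(y, lambda, mu, psi, rho)) -
                     fbdLogQ(y, lambda, mu, psi, rho))
  }
  ll
}

#' Prior settings for the Bayesian sampler
#'
#' Weakly informative defaults: diversification d ~ Exponential(mean 0.1),
#' turnover nu ~ Uniform(0, 1), sampling proportion s ~ Uniform(0, 1), clock
#' mean rate ~ Lognormal(log 0.02, sd 1.5) (wide on the substitution-rate
#' scale), origin ~ Uniform(0, originMax) truncated to origin > root age.
#'
#' @param dMean mean of the exponential prior on diversification.
#' @param clockMeanLog,clockSdLog log-mean and log-sd of the lognormal prior
#'   on the clock mean rate.
#' @param originMax upper bound of the uniform origin prior, Ma.
#' @return a list of class \code{"priorConfig"}.
#' @export
priorConfig <- function(dMean = 0.1, clockMeanLog = log(0.02),
                        clockSdLog = 1.5, originMax = 200) {
  structure(list(dMean = dMean, clockMeanLog = clockMeanLog,
                 clockSdLog = clockSdLog, originMax = originMax),
            class = "priorConfig")
}

# joint log prior of the scalar parameters; -Inf outside supports
logPriorScalars <- function(d, nu, s, clockMean, origin, rootAge, prior,
                            withClock = TRUE) {
  if (d <= 0 || nu < 0 || nu >= 1 || s < 0 || s >= 1) return(-Inf)
  if (origin <= rootAge || origin > prior$originMax) return(-Inf)
  lp <- stats::dexp(d, rate = 1 / prior$dMean, log = TRUE) -
    log(prior$originMax)
  if (withClock) {
    if (clockMean <= 0) return(-Inf)
    lp <- lp + stats::dlnorm(clockMean, prior$clockMeanLog,
                             prior$clockSdLog, log = TRUE)
  }
  lp
}
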