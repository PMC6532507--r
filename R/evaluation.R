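#' Highest posterior density interval (Chen-Shao)
#'
#' Shortest contiguous interval containing \code{ceiling(level * n)} of the
#' sorted samples, found by scanning all windows of that size.
#'
#' @param samples numeric vector (>= 2 values, unless constant).
#' @param level probability mass, default 0.95.
#' @return numeric vector \code{c(lo, hi)}.
#' @export
hpdInterval <- function(samples, level = 0.95) {
  if (length(samples) == 0L) stop("empty sample")
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(level * n)
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Effective sample size of an MCMC trace
#'
#' \code{n / (1 + 2 * sum(rho_t))} with the autocorrelation sum truncated by
#' Geyer's initial monotone positive sequence: successive pairs
#' \code{rho_{2t} + rho_{2t+1}} are accumulated while positive and
#' non-increasing.  A constant series has ESS 1 by convention.
#'
#' @param samples numeric vector (>= 2 values).
#' @return effective sample size (capped at \code{length(samples)}).
#' @export
mcmcESS <- function(samples) {
  n <- length(samples)
  if (n < 2L || stats::sd(samples) == 0) return(1)
  maxLag <- min(n - 1L, 2000L)
  ac <- stats::acf(samples, lag.max = maxLag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  npair <- length(ac) %/% 2L
  s <- 0; prev <- Inf
  for (t in seq_len(npair)) {
    g <- ac[2L * t - 1L] + ac[2L * t]
    if (g < 0) break
    if (g > prev) g <- prev          # enforce monotone decrease
    s <- s + g
    prev <- g
  }
  min(n, n / (1 + 2 * s))
}

#' Relative error of a point estimate
#' @param estimate posterior median (or any point estimate).
#' @param truth true value (> 0).
#' @return \code{|estimate - truth| / truth}.
#' @export
relativeError <- function(estimate, truth) {
  if (any(truth <= 0)) stop("relative error undefined for truth <= 0")
  abs(estimate - truth) / truth
}

#' Summarize one MCMC run against the simulation truth
#'
#' Discards burn-in, then computes for each tracked quantity the posterior
#' median, the 95% HPD interval, the relative error of the median, the
#' coverage flag (truth inside the HPD) and the relative HPD width (width
#' divided by the true value).  Divergence-time metrics are averaged across
#' all extant-MRCA nodes of the tree; scalar parameters (diversification,
#' turnover, sampling proportion) are reported individually.  Convergence is
#' gated on the effective sample sizes of the log posterior and the root
#' age; a run below the gate is flagged, not dropped.
#'
#' @param trace an \code{fbdTrace} from \code{\link{runMCMC}}.
#' @param truth list with \code{nodeAges} (named numeric vector, names
#'   matching the \code{age_<node>} trace columns), and optionally \code{d},
#'   \code{nu}, \code{s}.
#' @param burnin fraction of samples discarded; defaults to the value
#'   recorded in the trace.
#' @param essGate minimum ESS considered converged.
#' @param level HPD level.
#' @return a list of class \code{"replicateSummary"}: per-parameter rows
#'   (data.frame \code{params}), per-node table (\code{nodes}), tree-level
#'   means (\code{divtime}), ESS values, CPU seconds, time per effective
#'   sample, convergence flag, handling method.
#' @export
summarizeReplicate <- function(trace, truth, burnin = NULL, essGate = 200,
                               level = 0.95) {
  if (is.null(burnin)) burnin <- attr(trace, "burnin")
  if (is.null(burnin)) burnin <- 0.1
  nb <- min(nrow(trace) - 1L, ceiling(burnin * nrow(trace)))
  post <- if (nb > 0L) trace[-seq_len(nb), , drop = FALSE] else trace

  one <- function(x, tv) {
    tv <- unname(tv)
    md <- stats::median(x)
    h <- hpdInterval(x, level)
    c(median = md, lo = unname(h[1]), hi = unname(h[2]),
      relError = relativeError(md, tv),
      covered = as.numeric(tv >= h[1] & tv <= h[2]),
      relWidth = (h[2] - h[1]) / tv)
  }
  nodeCols <- paste0("age_", names(truth$nodeAges))
  missing <- setdiff(nodeCols, colnames(trace))
  if (length(missing)) stop("trace lacks node columns: ",
                            paste(missing, collapse = ", "))
  nodes <- t(vapply(seq_along(nodeCols),
                    function(i) one(post[, nodeCols[i]],
                                    truth$nodeAges[i]),
                    numeric(6)))
  nodes <- data.frame(node = names(truth$nodeAges), truth = truth$nodeAges,
                      nodes, row.names = NULL)
  divtime <- c(relError = mean(nodes$relError),
               coverage = mean(nodes$covered),
               relWidth = mean(nodes$relWidth))

  pnames <- intersect(c("d", "nu", "s"), names(truth))
  params <- NULL
  if (length(pnames)) {
    params <- t(vapply(pnames,
                       function(p) one(post[, p], truth[[p]]), numeric(6)))
    params <- data.frame(param = pnames, truth = unlist(truth[pnames]),
                         params, row.names = NULL)
  }
  ess <- c(posterior = mcmcESS(post[, "posterior"]),
           rootAge = mcmcESS(post[, "rootAge"]))
  cpu <- attr(trace, "cpuTime")
  # a root age pinned by a fixed stem sampled ancestor is constant by
  # construction, not unconverged: exclude it from the time-per-ESS gate
  essGating <- ess
  if (stats::sd(post[, "rootAge"]) == 0) essGating <- ess["posterior"]
  structure(list(params = params, nodes = nodes, divtime = divtime,
                 ess = ess, cpu = cpu,
                 timePerESS = if (!is.null(cpu)) cpu / min(essGating)
                              else NA_real_,
                 converged = all(essGating >= essGate),
                 handling = attr(trace, "handling")),
            class = "replicateSummary")
}

#' Aggregate replicate summaries into a results table
#'
#' One row per handling method x parameter with the mean relative error,
#' the coverage proportion, the mean relative HPD width, the mean CPU time
#' per effective sample and the replicate count.  Divergence times appear as
#' parameter \code{"divtime"} (already averaged within each tree across its
#' extant-MRCA nodes); pooled per-node coverage across all trees is also
#' reported as \code{"divtime_pooled"}.
#'
#' @param summaries list of \code{replicateSummary} objects.
#' @return a data.frame with columns \code{handling}, \code{parameter},
#'   \code{relError}, \code{coverage}, \code{relWidth}, \code{timePerESS},
#'   \code{nReplicates}, \code{nConverged}.
#' @export
aggregateResults <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  hs <- vapply(summaries, function(s) s$handling, character(1))
  rows <- list()
  for (h in unique(hs)) {
    ss <- summaries[hs == h]
    dt <- t(vapply(ss, function(s) s$divtime, numeric(3)))
    tpe <- vapply(ss, function(s) s$timePerESS, numeric(1))
    conv <- sum(vapply(ss, function(s) s$converged, logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      handling = h, parameter = "divtime",
      relError = mean(dt[, "relError"]), coverage = mean(dt[, "coverage"]),
      relWidth = mean(dt[, "relWidth"]), timePerESS = mean(tpe),
      nReplicates = length(ss), nConverged = conv)
    pooled <- do.call(rbind, lapply(ss, function(s) s$nodes))
    rows[[length(rows) + 1L]] <- data.frame(
      handling = h, parameter = "divtime_pooled",
      relError = mean(pooled$relError), coverage = mean(pooled$covered),
      relWidth = mean(pooled$relWidth), timePerESS = mean(tpe),
      nReplicates = length(ss), nConverged = conv)
    if (!is.null(ss[[1]]$params)) {
      for (p in ss[[1]]$params$param) {
        pm <- t(vapply(ss, function(s) {
          r <- s$params[s$params$param == p, ]
          c(r$relError, r$covered, r$relWidth)
        }, numeric(3)))
        rows[[length(rows) + 1L]] <- data.frame(
          handling = h, parameter = p,
          relError = mean(pm[, 1]), coverage = mean(pm[, 2]),
          relWidth = mean(pm[, 3]), timePerESS = mean(tpe),
          nReplicates = length(ss), nConverged = conv)
      }
    }
  }
  do.call(rbind, rows)
}
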