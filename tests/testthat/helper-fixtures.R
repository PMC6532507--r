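# Hand-built trees and a cached small replicate shared across test files.

# complete 3-species tree: origin 20, root 15; A and B split at 6; C extinct
# at 4 after diverging at 15.  Node layout:
#   1 root (15) -> children 2 (AB split, 6) and 5 (extinct tip C, 4)
#   2 -> tips 3 (A, 0) and 4 (B, 0)
threeSpeciesComplete <- function() {
  timeTree(parent = c(0L, 1L, 2L, 2L, 1L),
           age = c(15, 6, 0, 0, 4),
           label = c("", "", "A", "B", "C"),
           status = c("internal", "internal", "extant", "extant", "extinct"),
           origin = 20)
}

# fossil table row targeting a given branch of a timeTree
fossilAt <- function(lineage, age, id = 1L) {
  out <- data.frame(id = id, lineage = lineage, true_age = age,
                    min_age = NA_real_, max_age = NA_real_,
                    operational_age = NA_real_)
  class(out) <- c("fossilTable", "data.frame")
  out
}

# cached accepted replicate at the study conditions (shared by tests that
# only need *a* realistic dataset, not an independent draw)
.fixtureEnv <- new.env()
studyReplicate <- function() {
  if (is.null(.fixtureEnv$rep)) {
    set.seed(424242)
    .fixtureEnv$rep <- simReplicate(simConfig())
    .fixtureEnv$lib <- simIntervalLibrary(800, 8, 120)
    .fixtureEnv$rep$fossils <-
      assignFossilIntervals(.fixtureEnv$rep$fossils, .fixtureEnv$lib)
  }
  .fixtureEnv$rep
}
studyLibrary <- function() {
  studyReplicate()
  .fixtureEnv$lib
}

# independent event-by-event forward birth-death simulator used as an
# oracle for the tree simulator: one lineage per vector slot, times drawn
# per event, written without reference to the package implementation
oracleForwardOrigin <- function(lambda, mu, psi, n, originMin, originMax,
                                fossilMin, fossilMax, nAccept,
                                maxIter = 1e6) {
  out <- numeric(0)
  for (i in seq_len(maxIter)) {
    # track elapsed time t and total tree length L (integral of the
    # lineage count); the fossil count given L is Poisson(psi * L)
    nAlive <- 1L; t <- 0; L <- 0
    repeat {
      dt <- rexp(1, nAlive * (lambda + mu))
      t <- t + dt; L <- L + nAlive * dt
      if (runif(1) < lambda / (lambda + mu)) {
        nAlive <- nAlive + 1L
        if (nAlive == n) break
      } else {
        nAlive <- nAlive - 1L
        if (nAlive == 0L) break
      }
    }
    if (nAlive != n) next
    dt <- rexp(1, nAlive * (lambda + mu))      # holding interval at n
    t <- t + dt; L <- L + nAlive * dt
    if (t < originMin || t > originMax) next
    nf <- rpois(1, psi * L)
    if (nf < fossilMin || nf > fossilMax) next
    out <- c(out, t)
    if (length(out) >= nAccept) return(out)
  }
  out
}
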