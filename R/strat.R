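#' Synthetic stratigraphic-interval library
#'
#' Generates a weighted library of geological (min, max) age intervals
#' emulating the empirical pattern of North-American mammal sampling
#' intervals in the Paleobiology Database: interval lengths average
#' \code{meanLength} Myr overall, and older intervals are stochastically
#' wider than younger ones (young fossils carry less age uncertainty).
#'
#' Generative form: interval midpoints are uniform on
#' \code{[0, maxFossilAge]}; conditional on midpoint m, the length is
#' Gamma-distributed with shape 2 and mean
#' \code{meanLength * (0.5 + m / maxFossilAge)}, so the marginal mean length
#' equals \code{meanLength} while the mean grows linearly with age.
#' Intervals are truncated at the present by shifting (length preserved).
#' Weights mimic the frequency of appearance of named intervals in
#' occurrence data and are i.i.d. 1 + Poisson(2).
#'
#' @param nEntries number of intervals (>= 1).
#' @param meanLength target mean interval length in Myr (default 8).
#' @param maxFossilAge oldest midpoint in Ma; the library covers fossils on
#'   \code{[0, maxFossilAge]}.
#' @return a data.frame of class \code{"intervalLibrary"} with columns
#'   \code{min_age}, \code{max_age}, \code{weight}.
#' @export
simIntervalLibrary <- function(nEntries = 1000L, meanLength = 8,
                               maxFossilAge = 120) {
  stopifnot(nEntries >= 1, meanLength > 0, maxFossilAge > 0)
  mid <- stats::runif(nEntries, 0, maxFossilAge)
  len <- stats::rgamma(nEntries, shape = 2,
                       scale = meanLength * (0.5 + mid / maxFossilAge) / 2)
  lo <- mid - len / 2
  shift <- pmax(0, -lo)              # truncate at present by shifting
  lo <- lo + shift
  hi <- lo + len
  out <- data.frame(min_age = lo, max_age = hi,
                    weight = 1L + stats::rpois(nEntries, 2))
  class(out) <- c("intervalLibrary", "data.frame")
  out
}

#' Read an interval library from CSV
#'
#' Expects columns \code{min_age} and \code{max_age} (Ma) and an optional
#' \code{weight} column (default 1).  Duplicate (min, max) rows accumulate
#' their weights into a single entry.
#'
#' @param file path to a CSV file.
#' @return an \code{intervalLibrary} data.frame.
#' @export
readIntervalLibrary <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("min_age", "max_age") %in% names(d)))
    stop("interval CSV must have columns min_age and max_age")
  if (is.null(d$weight)) d$weight <- 1L
  bad <- which(d$max_age <= d$min_age)
  if (length(bad))
    stop("max_age <= min_age at row(s): ", paste(bad, collapse = ", "))
  agg <- stats::aggregate(weight ~ min_age + max_age, data = d, FUN = sum)
  out <- agg[order(agg$max_age, agg$min_age), c("min_age", "max_age", "weight")]
  rownames(out) <- NULL
  class(out) <- c("intervalLibrary", "data.frame")
  out
}

#' Write an interval library to CSV
#' @param library an \code{intervalLibrary}.
#' @param file output path.
#' @export
writeIntervalLibrary <- function(library, file) {
  utils::write.csv(as.data.frame(library)[c("min_age", "max_age", "weight")],
                   file, row.names = FALSE)
}

#' Assign a stratigraphic interval to a fossil's true age
#'
#' Among the library intervals containing \code{trueAge}, one is selected at
#' random with probability proportional to its weight, so the simulated
#' interval always includes the correct age.  If no library interval
#' contains the age, a fallback interval of fixed length
#' \code{fallbackLength} (8 Myr by default) is drawn uniformly subject to
#' containing the age and having \code{min_age >= 0}.
#'
#' @param trueAge fossil age in Ma (>= 0).
#' @param library an \code{intervalLibrary}.
#' @param fallbackLength fixed length of the fallback interval in Myr.
#' @return numeric vector \code{c(min_age, max_age)}.
#' @export
assignInterval <- function(trueAge, library, fallbackLength = 8) {
  stopifnot(trueAge >= 0)
  hit <- which(library$min_age <= trueAge & library$max_age >= trueAge)
  if (length(hit) == 0L) {
    lo <- stats::runif(1L, max(0, trueAge - fallbackLength), trueAge)
    return(c(lo, lo + fallbackLength))
  }
  k <- if (length(hit) == 1L) hit else
    hit[sample.int(length(hit), 1L, prob = library$weight[hit])]
  c(library$min_age[k], library$max_age[k])
}

#' Symmetric interval around the true fossil age
#'
#' Returns the interval of the given length centred on \code{trueAge}.  When
#' the age is closer to the present than half the length, the interval is
#' shifted (not shrunk) so that \code{min_age = 0}; this clamping breaks the
#' symmetry for very young fossils.
#'
#' @param trueAge fossil age in Ma.
#' @param length interval length in Myr (> 0).
#' @return numeric vector \code{c(min_age, max_age)}.
#' @export
symmetricInterval <- function(trueAge, length) {
  stopifnot(length > 0, trueAge >= 0)
  lo <- trueAge - length / 2
  if (lo < 0) lo <- 0
  c(lo, lo + length)
}

#' Dress fossil occurrences with stratigraphic intervals
#'
#' Assigns each fossil a PBDB-style interval from the library (always
#' containing the true age) and, alongside, the symmetric interval of the
#' same length recentred on the true age.  The symmetric interval is used by
#' the \code{"symmetric"} age-handling arm, so the two sampled-ages arms
#' differ only in the centring of the bounds.
#'
#' @param fossils a \code{fossilTable}.
#' @param library an \code{intervalLibrary}.
#' @param fallbackLength fallback interval length in Myr.
#' @return the table with columns \code{min_age}, \code{max_age},
#'   \code{sym_min_age}, \code{sym_max_age} filled in.
#' @export
assignFossilIntervals <- function(fossils, library, fallbackLength = 8) {
  n <- nrow(fossils)
  mn <- mx <- smn <- smx <- numeric(n)
  for (i in seq_len(n)) {
    iv <- assignInterval(fossils$true_age[i], library, fallbackLength)
    mn[i] <- iv[1]; mx[i] <- iv[2]
    sv <- symmetricInterval(fossils$true_age[i], iv[2] - iv[1])
    smn[i] <- sv[1]; smx[i] <- sv[2]
  }
  fossils$min_age <- mn; fossils$max_age <- mx
  fossils$sym_min_age <- smn; fossils$sym_max_age <- smx
  fossils
}

#' The five fossil-age handling methods
#'
#' Converts stratigraphic intervals into what the inference sees:
#' \describe{
#'   \item{correct}{ages fixed to the true simulated ages;}
#'   \item{median}{ages fixed to the midpoint of the assigned interval;}
#'   \item{random}{ages fixed to a uniform draw within the interval;}
#'   \item{interval}{ages sampled during MCMC within the assigned interval;}
#'   \item{symmetric}{ages sampled during MCMC within the symmetric
#'     interval centred on the true age.}
#' }
#' Fixed methods set \code{operational_age}; sampling methods set the
#' \code{lower}/\code{upper} bounds handed to the sampler.
#'
#' @param fossils a \code{fossilTable} with intervals assigned (see
#'   \code{\link{assignFossilIntervals}}); the \code{correct} method only
#'   needs \code{true_age}.
#' @param method one of \code{"correct"}, \code{"median"}, \code{"random"},
#'   \code{"interval"}, \code{"symmetric"}.
#' @return the table with \code{method}, \code{operational_age} (NA for
#'   sampling methods) and \code{lower}/\code{upper} (NA for fixed methods)
#'   set.
#' @export
applyAgeHandling <- function(fossils, method = c("correct", "median",
                                                 "random", "interval",
                                                 "symmetric")) {
  method <- match.arg(method)
  n <- nrow(fossils)
  needBounds <- method != "correct"
  if (needBounds && (is.null(fossils$min_age) || anyNA(fossils$min_age)))
    stop("method '", method, "' requires stratigraphic bounds; ",
         "run assignFossilIntervals() first")
  if (method == "symmetric" && is.null(fossils$sym_min_age))
    stop("method 'symmetric' requires symmetric bounds; ",
         "run assignFossilIntervals() first")
  fossils$method <- method
  fossils$operational_age <- NA_real_
  fossils$lower <- NA_real_
  fossils$upper <- NA_real_
  if (method == "correct") {
    fossils$operational_age <- fossils$true_age
  } else if (method == "median") {
    fossils$operational_age <- (fossils$min_age + fossils$max_age) / 2
  } else if (method == "random") {
    fossils$operational_age <- stats::runif(n, fossils$min_age, fossils$max_age)
  } else if (method == "interval") {
    fossils$lower <- fossils$min_age
    fossils$upper <- fossils$max_age
  } else {
    fossils$lower <- fossils$sym_min_age
    fossils$upper <- fossils$sym_max_age
  }
  fossils
}

#' Write a per-replicate fossil age table as CSV
#' @param fossils a \code{fossilTable} after age handling.
#' @param file output path.
#' @export
writeFossilTable <- function(fossils, file) {
  keep <- intersect(c("id", "lineage", "true_age", "min_age", "max_age",
                      "sym_min_age", "sym_max_age", "method",
                      "operational_age", "lower", "upper", "node", "sa"),
                    names(fossils))
  utils::write.csv(as.data.frame(fossils)[keep], file, row.names = FALSE)
}

#' Read a fossil occurrence table from CSV
#'
#' Requires columns \code{true_age} or (\code{min_age}, \code{max_age});
#' validates \code{min_age <= max_age} row by row.
#'
#' @param file CSV path.
#' @return a \code{fossilTable}.
#' @export
readFossilTable <- function(file) {
  d <- utils::read.csv(file)
  if (is.null(d$min_age) || is.null(d$max_age))
    stop("fossil CSV must have min_age and max_age columns")
  bad <- which(d$min_age > d$max_age)
  if (length(bad))
    stop("min_age > max_age at row(s): ", paste(bad, collapse = ", "))
  if (is.null(d$id)) d$id <- seq_len(nrow(d))
  class(d) <- c("fossilTable", "data.frame")
  d
}
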