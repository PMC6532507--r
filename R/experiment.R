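#' Configuration of a full simulation experiment
#'
#' Bundles everything \code{\link{runExperiment}} needs: the generative
#' conditions (birth-death-fossilization settings, interval library,
#' sequence model and clock), the handling methods to compare, the MCMC
#' settings shared by all arms, the replicate count and the master seed.
#'
#' @param sim a \code{\link{simConfig}} (mammal-regime defaults).
#' @param model an \code{\link{hkyModel}}.
#' @param mcmc an \code{\link{mcmcConfig}}.
#' @param prior a \code{\link{priorConfig}}.
#' @param methods subset of the five handling methods.
#' @param nReplicates number of accepted replicates (>= 1).
#' @param seed master seed; every random draw derives from
#'   (seed, replicate, arm) so arms are paired on identical data.
#' @param nSites alignment length.
#' @param clockLogSd lognormal clock log-sd.
#' @param clockShape,clockBeta,betaIsScale gamma distribution of the mean
#'   clock rate (see \code{\link{simClock}}).
#' @param libEntries,libMeanLength,libMaxAge,fallbackLength synthetic
#'   interval-library settings (see \code{\link{simIntervalLibrary}}).
#' @param essGate convergence gate on effective sample sizes.
#' @param outDir optional output directory for artifacts.
#' @return a list of class \code{"experimentConfig"}.
#' @export
experimentConfig <- function(sim = simConfig(), model = hkyModel(),
                             mcmc = mcmcConfig(), prior = priorConfig(),
                             methods = c("correct", "median", "random",
                                         "interval", "symmetric"),
                             nReplicates = 10L, seed = 1L, nSites = 2000L,
                             clockLogSd = 0.1, clockShape = 2,
                             clockBeta = 2, betaIsScale = TRUE,
                             libEntries = 1000L, libMeanLength = 8,
                             libMaxAge = 120, fallbackLength = 8,
                             essGate = 200, outDir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(nReplicates >= 1)
  structure(list(sim = sim, model = model, mcmc = mcmc, prior = prior,
                 methods = methods, nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed), nSites = as.integer(nSites),
                 clockLogSd = clockLogSd, clockShape = clockShape,
                 clockBeta = clockBeta, betaIsScale = betaIsScale,
                 libEntries = as.integer(libEntries),
                 libMeanLength = libMeanLength, libMaxAge = libMaxAge,
                 fallbackLength = fallbackLength, essGate = essGate,
                 outDir = outDir),
            class = "experimentConfig")
}

# derived seeds, kept below 2^31
replicateSeed <- function(seed, rep) (seed + 7919L * rep) %% 2147483647L
armSeed <- function(seed, rep, arm)
  (seed + 7919L * rep + 104729L * arm) %% 2147483647L

#' Simulate one replicate dataset (tree, fossils, intervals, alignment)
#'
#' The dataset is shared by all handling arms of a replicate: an accepted
#' birth-death tree with fossils, stratigraphic intervals drawn from the
#' library, and a sequence alignment for the extant tips under HKY+Gamma
#' with an uncorrelated lognormal clock.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param library an \code{intervalLibrary}.
#' @param rep replicate number (seeds the draws).
#' @return list with \code{complete}, \code{sampled}, \code{fossils},
#'   \code{alignment}, \code{clock}, \code{truth} (node ages named by
#'   sampled-tree node index, plus d, nu, s), \code{seed}.
#' @export
simulateReplicateData <- function(config, library, rep = 1L) {
  set.seed(replicateSeed(config$seed, rep))
  repl <- simReplicate(config$sim)
  fossils <- assignFossilIntervals(repl$fossils, library,
                                   config$fallbackLength)
  et <- extantTree(repl$sampled)
  clock <- simClock(et$tree, logSd = config$clockLogSd,
                    shape = config$clockShape, beta = config$clockBeta,
                    betaIsScale = config$betaIsScale)
  aln <- simAlignment(et$tree, clock, config$model, config$nSites)
  tipsEt <- tipIndices(et$tree)
  mrcaIds <- et$nodeMap[setdiff(seq_along(et$tree$parent), tipsEt)]
  pars <- fbdParamsFromRates(config$sim$lambda, config$sim$mu,
                             config$sim$psi, config$sim$rho)
  truth <- list(nodeAges = stats::setNames(repl$sampled$age[mrcaIds],
                                           mrcaIds),
                d = pars$d, nu = pars$nu, s = pars$s)
  list(complete = repl$complete, sampled = repl$sampled, fossils = fossils,
       alignment = aln, clock = clock, truth = truth,
       seed = replicateSeed(config$seed, rep))
}

#' Run the full five-arm simulation experiment
#'
#' For each replicate, one simulated dataset is shared across all handling
#' arms; each arm applies its age-handling method, runs the MCMC and is
#' summarized against the truth.  Random draws derive from
#' (master seed, replicate, arm), so runs are reproducible and arms are
#' paired.  When \code{config$outDir} is set, trees (Newick), fossil tables
#' (CSV), alignments (FASTA), traces (TSV) and an audit log (JSON lines)
#' are written there.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param library optional pre-built \code{intervalLibrary}; by default a
#'   synthetic library is drawn from the master seed.
#' @param verbose print per-replicate progress.
#' @return a list of class \code{"fbdExperiment"}: \code{results}
#'   (aggregate table from \code{\link{aggregateResults}}),
#'   \code{summaries} (list of lists by replicate), \code{library},
#'   \code{config}.
#' @export
runExperiment <- function(config, library = NULL, verbose = FALSE) {
  outDir <- config$outDir
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir) || file.access(outDir, 2L) != 0L)
      stop("output directory not writable: ", outDir)
  }
  if (is.null(library)) {
    set.seed(config$seed)
    library <- simIntervalLibrary(config$libEntries, config$libMeanLength,
                                  config$libMaxAge)
  }
  hash <- configHash(config)
  audit <- if (!is.null(outDir)) file.path(outDir, "audit.jsonl") else NULL
  allSumm <- list()
  for (rep in seq_len(config$nReplicates)) {
    dat <- simulateReplicateData(config, library, rep)
    if (!is.null(outDir)) {
      rd <- file.path(outDir, sprintf("rep%03d", rep))
      dir.create(rd, showWarnings = FALSE)
      writeTimeTreeNewick(dat$complete, file.path(rd, "complete.nwk"))
      writeTimeTreeNewick(dat$sampled, file.path(rd, "sampled.nwk"))
      writeFossilTable(dat$fossils, file.path(rd, "fossils.csv"))
      writeAlignmentFasta(dat$alignment, file.path(rd, "alignment.fasta"))
    }
    repSumm <- list()
    for (ai in seq_along(config$methods)) {
      m <- config$methods[ai]
      set.seed(armSeed(config$seed, rep, ai))
      fos <- applyAgeHandling(dat$fossils, m)
      trace <- runMCMC(dat$sampled, fos, config$model, dat$alignment,
                       mode = "posterior", config = config$mcmc,
                       prior = config$prior,
                       init = list(d = config$sim$lambda - config$sim$mu,
                                   nu = config$sim$mu / config$sim$lambda,
                                   s = config$sim$psi /
                                     (config$sim$mu + config$sim$psi),
                                   clockRate = NULL, rho = config$sim$rho))
      summ <- summarizeReplicate(trace, dat$truth,
                                 essGate = config$essGate)
      repSumm[[m]] <- summ
      if (!is.null(outDir)) {
        rd <- file.path(outDir, sprintf("rep%03d", rep))
        writeTrace(trace, file.path(rd, paste0("trace_", m, ".tsv")),
                   seed = armSeed(config$seed, rep, ai))
        writeFossilTable(fos, file.path(rd, paste0("fossils_", m, ".csv")))
        line <- jsonlite::toJSON(list(
          replicate = rep, handling = m, seed = armSeed(config$seed, rep, ai),
          configHash = hash,
          version = as.character(utils::packageVersion("fbdage")),
          divtime = as.list(summ$divtime), ess = as.list(summ$ess),
          cpu = summ$cpu, converged = summ$converged), auto_unbox = TRUE)
        cat(line, "\n", sep = "", file = audit, append = TRUE)
      }
      if (verbose)
        message(sprintf("rep %d %s: relErr %.3f cov %.2f ess %.0f/%.0f",
                        rep, m, summ$divtime["relError"],
                        summ$divtime["coverage"], summ$ess[1], summ$ess[2]))
    }
    allSumm[[rep]] <- repSumm
  }
  res <- aggregateResults(unlist(allSumm, recursive = FALSE))
  if (!is.null(outDir))
    utils::write.csv(res, file.path(outDir, "results.csv"), row.names = FALSE)
  structure(list(results = res, summaries = allSumm, library = library,
                 config = config),
            class = "fbdExperiment")
}

#' Analyse a user-supplied dataset under several age-handling methods
#'
#' Runs the fixed-topology FBD analysis on an empirical-style dataset: a
#' FASTA alignment of extant taxa, a fossil occurrence CSV with
#' stratigraphic bounds and clade assignments, a YAML file defining the
#' clades by extant tip labels, and a fixed time-calibrated extant topology
#' (Newick).  Each fossil is attached along the stem lineage of its
#' assigned clade; attachment ages are sampled.  Since true fossil ages are
#' unknown, only \code{median}, \code{random} and \code{interval} handling
#' are available.
#'
#' @param alignmentFile FASTA of extant sequences (taxa must match the
#'   topology's tips).
#' @param fossilFile CSV with columns \code{id} (optional), \code{clade},
#'   \code{min_age}, \code{max_age}.
#' @param constraintsFile YAML mapping clade names to extant tip labels.
#' @param topologyFile Newick ultrametric extant tree with branch lengths
#'   in Myr.
#' @param methods handling methods to run.
#' @param model an \code{\link{hkyModel}}.
#' @param config an \code{\link{mcmcConfig}}.
#' @param prior a \code{\link{priorConfig}}.
#' @param seed RNG seed.
#' @return list of class \code{"userAnalysis"}: \code{traces} (by method),
#'   \code{nodeAges} (per extant MRCA node: truth-free comparison of
#'   posterior medians and HPDs across methods), \code{tree},
#'   \code{fossils}.
#' @export
runUserAnalysis <- function(alignmentFile, fossilFile, constraintsFile,
                            topologyFile,
                            methods = c("median", "random", "interval"),
                            model = hkyModel(), config = mcmcConfig(),
                            prior = priorConfig(), seed = 1L) {
  methods <- match.arg(methods, c("median", "random", "interval"),
                       several.ok = TRUE)
  aln <- readAlignmentFasta(alignmentFile)
  ext <- readTimeTreeNewick(topologyFile)
  fossils <- readFossilTable(fossilFile)
  if (is.null(fossils$clade)) stop("fossil CSV needs a 'clade' column")
  clades <- yaml::read_yaml(constraintsFile)
  bad <- setdiff(fossils$clade, names(clades))
  if (length(bad))
    stop("fossil(s) assigned to undefined clade(s): ",
         paste(fossils$id[fossils$clade %in% bad], collapse = ", "))
  built <- attachFossilsToTree(ext, fossils, clades)
  tree <- built$tree
  fossils <- built$fossils
  fossils$true_age <- (fossils$min_age + fossils$max_age) / 2  # unknown
  traces <- list()
  for (m in methods) {
    set.seed(seed + match(m, c("median", "random", "interval")))
    fos <- applyAgeHandling(fossils, m)
    traces[[m]] <- runMCMC(tree, fos, model, aln, mode = "posterior",
                           config = config, prior = prior)
  }
  # node-age comparison across methods over shared extant MRCA columns
  cols <- Reduce(intersect, lapply(traces, colnames))
  cols <- grep("^age_", cols, value = TRUE)
  cmp <- NULL
  for (m in methods) {
    tr <- traces[[m]]
    nb <- min(nrow(tr) - 1L, ceiling(attr(tr, "burnin") * nrow(tr)))
    post <- if (nb > 0) tr[-seq_len(nb), , drop = FALSE] else tr
    md <- apply(post[, cols, drop = FALSE], 2, stats::median)
    h <- apply(post[, cols, drop = FALSE], 2, hpdInterval)
    df <- data.frame(node = sub("^age_", "", cols), method = m,
                     median = md, lo = h[1, ], hi = h[2, ],
                     row.names = NULL)
    cmp <- rbind(cmp, df)
  }
  structure(list(traces = traces, nodeAges = cmp, tree = tree,
                 fossils = fossils),
            class = "userAnalysis")
}

# Insert fossil tips along the stem lineage of their assigned clades.
# Attachment nodes are spaced evenly inside the stem branch; their ages are
# sampled during inference, so the placement only seeds the chain.
attachFossilsToTree <- function(ext, fossils, clades) {
  n0 <- length(ext$parent)
  nf <- nrow(fossils)
  parent <- c(ext$parent, integer(2L * nf))
  age <- c(ext$age, numeric(2L * nf))
  label <- c(ext$label, character(2L * nf))
  status <- c(ext$status, character(2L * nf))
  # clade -> stem child node
  stemOf <- vapply(names(clades), function(cl) {
    labs <- clades[[cl]]
    if (length(labs) == 1L) {
      v <- match(labs, ext$label)
      if (is.na(v)) stop("clade ", cl, " names unknown tip ", labs)
      v
    } else mrcaNode(ext, labs)
  }, integer(1))
  if (is.null(fossils$id)) fossils$id <- seq_len(nf)
  fossils$node <- NA_integer_
  nxt <- n0
  for (cl in unique(fossils$clade)) {
    rows <- which(fossils$clade == cl)
    v <- stemOf[[cl]]
    p <- parent[v]
    top <- if (p == 0L) ext$origin else age[p]
    if (top <= age[v])
      stop("no stem branch to attach fossils of clade ", cl)
    k <- length(rows)
    at <- age[v] + seq_len(k) / (k + 1) * (top - age[v])
    rows <- rows[order(fossils$min_age[rows])]
    cur <- p
    for (j in rev(seq_len(k))) {       # oldest attachment first
      i <- rows[j]
      attach <- nxt + 1L; ftip <- nxt + 2L; nxt <- nxt + 2L
      parent[attach] <- cur; age[attach] <- at[j]
      status[attach] <- "internal"; label[attach] <- ""
      parent[ftip] <- attach
      age[ftip] <- min((fossils$min_age[i] + fossils$max_age[i]) / 2,
                       at[j] - 1e-6)
      age[ftip] <- max(age[ftip], 0)
      status[ftip] <- "fossil"
      label[ftip] <- paste0("fossil_", fossils$id[i])
      fossils$node[i] <- ftip
      cur <- attach
    }
    parent[v] <- cur
  }
  origin <- max(ext$origin, max(age[seq_len(nxt)]) + 1)
  tree <- timeTree(parent[seq_len(nxt)], age[seq_len(nxt)],
                   label[seq_len(nxt)], status[seq_len(nxt)], origin)
  fossils$sa <- FALSE
  list(tree = tree, fossils = fossils)
}
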