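#' Write an MCMC trace as Tracer-compatible TSV
#'
#' One header line of column names, tab-separated numeric rows; provenance
#' (package version, seed, handling, mode) is embedded as leading
#' \code{#}-comment lines, which Tracer ignores.
#'
#' @param trace an \code{fbdTrace}.
#' @param file output path.
#' @param seed optional seed to record.
#' @export
writeTrace <- function(trace, file, seed = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("fbdage"))
  writeLines(c(
    paste0("# fbdage ", ver),
    paste0("# mode=", attr(trace, "mode"), " handling=",
           attr(trace, "handling"),
           if (!is.null(seed)) paste0(" seed=", seed))), con)
  writeLines(paste(colnames(trace), collapse = "\t"), con)
  utils::write.table(trace, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' Read a trace TSV written by \code{\link{writeTrace}}
#' @param file path.
#' @return numeric matrix with column names.
#' @export
readTrace <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  m <- as.matrix(d)
  structure(m, class = c("fbdTrace", "matrix"), burnin = 0.1)
}

#' Write a timeTree as Newick
#'
#' Sampled ancestors are serialized with the zero-length-branch convention
#' (a degree-2 attachment appears as a tip child with branch length 0); the
#' stem branch is written as the root edge, so node ages are recoverable
#' from branch lengths plus the extant tips at age 0.
#'
#' @param tree a \code{timeTree}.
#' @param file output path.
#' @export
writeTimeTreeNewick <- function(tree, file) {
  ape::write.tree(asPhylo(tree), file)
}

#' @rdname writeTimeTreeNewick
#' @export
writeTimeTreeNexus <- function(tree, file) {
  ape::write.nexus(asPhylo(tree), file = file)
}

#' Read a Newick file as a timeTree
#' @param file path.
#' @param youngestTipAge age of the youngest tip (default 0 = present).
#' @return a \code{timeTree}.
#' @export
readTimeTreeNewick <- function(file, youngestTipAge = 0) {
  timeTreeFromPhylo(ape::read.tree(file), youngestTipAge = youngestTipAge)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param file path.
#' @export
writeExperimentConfig <- function(config, file) {
  flat <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(flat, file)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(experimentConfig, c(
    if (!is.null(y$sim)) list(sim = do.call(simConfig, y$sim)),
    if (!is.null(y$model)) list(model = do.call(hkyModel, y$model)),
    if (!is.null(y$mcmc)) list(mcmc = do.call(mcmcConfig, y$mcmc)),
    if (!is.null(y$prior)) list(prior = do.call(priorConfig, y$prior)),
    y[setdiff(names(y), c("sim", "model", "mcmc", "prior"))]))
}

# short md5 fingerprint of a configuration (provenance in output files)
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(lapply(config, unclass), f)
  substr(unname(tools::md5sum(f)), 1, 12)
}
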