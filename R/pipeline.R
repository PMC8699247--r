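#' Pipeline configuration
#'
#' A single nested configuration record driving [runPipeline()]. Either
#' supply input files (\code{traces_file}, optionally \code{truth_file}) or
#' simulation settings (\code{sim}); the simulator is used when no trace
#' file is given. The record serializes losslessly to YAML via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param out_dir output directory for all artifacts.
#' @param traces_file optional path to a traces file ([readTraces()]
#'   format).
#' @param truth_file optional path to a ground-truth edge list.
#' @param sim named list of [simConfig()] arguments plus \code{density} and
#'   optional \code{topology}; used when \code{traces_file} is NULL.
#' @param gamma,lambda deconvolution settings (see [deconvParams()]).
#' @param alpha thresholding strength.
#' @param kernel smoothing weights.
#' @param ridge starting ridge multiplier.
#' @param evaluate whether to score against ground truth.
#' @param seed global seed (overrides \code{sim$seed} when simulating).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir, traces_file = NULL, truth_file = NULL,
                           sim = NULL, gamma = "auto", lambda = 0,
                           alpha = 2, kernel = smoothingKernel(),
                           ridge = 0, evaluate = TRUE, seed = 1L) {
  cfg <- list(out_dir = out_dir, traces_file = traces_file,
              truth_file = truth_file, sim = sim, gamma = gamma,
              lambda = lambda, alpha = alpha, kernel = as.numeric(kernel),
              ridge = ridge, evaluate = isTRUE(evaluate),
              seed = as.integer(seed))
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config a [pipelineConfig()] record.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path input file path.
#' @return a [pipelineConfig()] record.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

.stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full inference pipeline and write all artifacts
#'
#' Executes simulate/load, deconvolve, threshold, smooth, partial
#' correlations, edge ranking and (optionally) evaluation, writing every
#' intermediate to \code{config$out_dir} together with a JSON manifest
#' (config hash, seed, package version, per-stage wall times, artifact
#' checksums). Identical configurations produce identical artifacts.
#'
#' @param config a [pipelineConfig()] record.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  timings <- list()
  artifacts <- character()

  truth <- NULL
  if (!is.null(config$traces_file)) {
    st <- .stage_time(readTraces(config$traces_file))
    traces <- st$value
    timings$load <- st$elapsed
    if (!is.null(config$truth_file)) truth <- readNetwork(config$truth_file)
  } else {
    if (is.null(config$sim))
      stop("stage simulate: config must provide either traces_file or sim")
    sim_args <- config$sim
    density <- sim_args$density
    topology <- if (is.null(sim_args$topology)) "random" else sim_args$topology
    sim_args$density <- NULL
    sim_args$topology <- NULL
    sim_args$seed <- config$seed
    st <- .stage_time({
      ds <- simulateDataset(do.call(simConfig, sim_args), density, topology)
      writeTraces(ds$traces, out("traces.tsv"))
      writeNetwork(ds$network, out("truth.tsv"))
      ds
    })
    traces <- st$value$traces
    truth <- st$value$network
    timings$simulate <- st$elapsed
  }

  params <- deconvParams(gamma = config$gamma, lambda = config$lambda)
  st <- .stage_time({
    x <- deconvolveAll(traces, params)
    writeSpikes(x, out("deconvolved.tsv"))
    x
  })
  x <- st$value; timings$deconvolve <- st$elapsed
  artifacts <- c(artifacts, deconvolved = out("deconvolved.tsv"))

  st <- .stage_time({
    y <- thresholdSpikes(x, alpha = config$alpha)
    writeSpikes(y, out("thresholded.tsv"))
    y
  })
  y <- st$value; timings$threshold <- st$elapsed
  artifacts <- c(artifacts, thresholded = out("thresholded.tsv"))

  st <- .stage_time({
    z <- smoothSpikes(y, config$kernel)
    writeSpikes(z, out("smoothed.tsv"))
    z
  })
  timings$smooth <- st$elapsed
  artifacts <- c(artifacts, smoothed = out("smoothed.tsv"))

  st <- .stage_time({
    conn <- connectomeFromSpikes(y, kernel = config$kernel,
                                 ridge = config$ridge)
    writeConnectome(conn, out("connectome.tsv"))
    conn
  })
  conn <- st$value; timings$connectome <- st$elapsed
  artifacts <- c(artifacts, connectome = out("connectome.tsv"))

  st <- .stage_time({
    ranked <- rankEdges(conn)
    writeRankedEdges(ranked, out("ranked_edges.tsv"))
    ranked
  })
  ranked <- st$value; timings$rank <- st$elapsed
  artifacts <- c(artifacts, ranked_edges = out("ranked_edges.tsv"))

  if (config$evaluate) {
    if (is.null(truth))
      stop("stage evaluate: evaluation is enabled but no ground-truth ",
           "network is available (supply truth_file or simulate)")
    st <- .stage_time({
      res <- scoreRanking(ranked, symmetrizeTruth(truth))
      writeEvalResult(res, out("eval.json"))
      res
    })
    timings$evaluate <- st$elapsed
    artifacts <- c(artifacts, eval = out("eval.json"))
  }

  cfg_file <- out("config.yaml")
  writePipelineConfig(config, cfg_file)
  manifest <- list(
    package = "fluoroconn",
    version = as.character(utils::packageVersion("fluoroconn")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    artifacts = lapply(as.list(artifacts), function(f)
      list(file = f, md5 = unname(tools::md5sum(f)))),
    stage_seconds = timings)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
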