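#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' default. A YAML file read by [readRunConfig()] overrides any subset of
#' these entries. The master \code{seed} fans out into deterministic
#' per-stage seeds, so a fixed configuration always produces identical
#' outputs.
#'
#' @param outDir output directory
#' @param seed master seed
#' @return nested configuration list
#' @export
defaultRunConfig <- function(outDir = "fluornet-run", seed = 1L) {
  list(
    outDir = outDir,
    seed = as.integer(seed),
    stages = c("synth", "simulate", "fluoresce", "pubs", "movie", "emd"),
    # key is nNeurons, not n: YAML 1.1 reads a bare "n" as a boolean
    network = list(nNeurons = 100, meanDegree = 15, lambda = 0.3),
    sim = list(duration = 200, dt = 0.1, alphaInt = 5, alphaExt = 10,
               extRate = 5),
    calibrate = list(target = 0.1, tolerance = 0.01, maxIter = 50),
    fluoresce = list(noiseSd = 0.03, scatter = TRUE),
    synth = list(nKeywords = 30, yearFrom = 1970, yearTo = 2014,
                 recordsPerYear = 60,
                 plantedPairs = list(
                   list(keywords = c("alpha", "beta"), rho = 0.95,
                        burstYears = 1990:1994))),
    pubs = list(corpus = NULL, dialect = "medline", topN = 20),
    movie = list(mode = "counts"),
    emd = list(maxClusters = 256),
    te = list(k = 1, nBins = 3, nNodesMax = 20)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults from
#' [defaultRunConfig()]; everything else keeps its default. File paths
#' referenced by the configuration are checked for existence here, before
#' any stage runs.
#'
#' @param path YAML file
#' @return validated configuration list
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  cfg <- utils::modifyList(cfg, user)
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @param cfg configuration list
#' @export
validateRunConfig <- function(cfg) {
  known <- c("synth", "simulate", "calibrate", "fluoresce", "pubs",
             "movie", "emd", "te")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$pubs$corpus) && !file.exists(cfg$pubs$corpus))
    stop("corpus file does not exist: ", cfg$pubs$corpus)
  if ("pubs" %in% cfg$stages && is.null(cfg$pubs$corpus) &&
      !("synth" %in% cfg$stages))
    stop("stage 'pubs' needs either a corpus file or the 'synth' stage")
  invisible(cfg)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order — synthetic corpus,
#' (optional) bursting-rate calibration, network simulation,
#' fluorescence + scattering, publication statistics, activity movie,
#' EMD curves, transfer entropy — writing every artifact under
#' \code{cfg$outDir} and returning a manifest that lists each output file
#' with its MD5 content hash and the per-stage parameters. A stage
#' failure stops the run with the failing stage named; artifacts of
#' completed stages are retained.
#'
#' @param cfg configuration list from [defaultRunConfig()] or
#'   [readRunConfig()]
#' @param quiet suppress progress messages
#' @return manifest list (also written to \code{manifest.json})
#' @export
runPipeline <- function(cfg = defaultRunConfig(), quiet = FALSE) {
  validateRunConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stageSeeds <- stats::setNames(
    sample.int(.Machine$integer.max, 8),
    c("synth", "simulate", "calibrate", "fluoresce", "pubs", "movie",
      "emd", "te"))
  say <- function(...) if (!quiet) message(...)
  outputs <- character()
  out <- function(name) {
    p <- file.path(cfg$outDir, name)
    outputs <<- c(outputs, p)
    p
  }
  env <- new.env()

  stageFun <- list(
    synth = function() {
      s <- cfg$synth
      spec <- CorpusSpec(nKeywords = s$nKeywords,
                         years = s$yearFrom:s$yearTo,
                         recordsPerYear = s$recordsPerYear,
                         plantedPairs = s$plantedPairs,
                         seed = stageSeeds[["synth"]])
      corpus <- generateCorpus(spec)
      env$records <- corpus$records
      writeCorpus(corpus$records, out("corpus_medline.txt"), "medline")
      jsonlite::write_json(corpus$truth, out("ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    calibrate = function() {
      .pipeTopology(cfg, stageSeeds, env)
      p <- .pipeSimParams(cfg, stageSeeds)
      cal <- calibrateBursting(env$topo, p, target = cfg$calibrate$target,
                               tolerance = cfg$calibrate$tolerance,
                               maxIter = cfg$calibrate$maxIter)
      env$alphaInt <- cal$alphaInt
      jsonlite::write_json(cal[c("alphaInt", "measuredRate", "iterations",
                                 "converged")],
                           out("calibration.json"), auto_unbox = TRUE,
                           digits = NA)
    },
    simulate = function() {
      .pipeTopology(cfg, stageSeeds, env)
      p <- .pipeSimParams(cfg, stageSeeds)
      if (!is.null(env$alphaInt)) p@alphaInt <- env$alphaInt
      env$raster <- simulateNetwork(env$topo, p)
      writeSpikeRaster(env$raster, out("spikes.tsv"))
      writePositions(positions(env$topo), out("positions.csv"))
    },
    fluoresce = function() {
      if (is.null(env$raster)) stop("stage 'simulate' must run first")
      cp <- CaParams(noiseSd = cfg$fluoresce$noiseSd,
                     seed = stageSeeds[["fluoresce"]])
      trace <- calciumFromSpikes(env$raster, cp)
      movie <- fluorescence(trace, cp, positions = positions(env$topo))
      if (isTRUE(cfg$fluoresce$scatter))
        movie <- applyScattering(movie, env$topo)
      env$neuronMovie <- movie
      writeFluorescence(movie, out("fluorescence.csv"))
    },
    pubs = function() {
      if (!is.null(cfg$pubs$corpus)) {
        env$records <- parseRecords(cfg$pubs$corpus, cfg$pubs$dialect)
      }
      if (is.null(env$records)) stop("no records available")
      env$kym <- countByYear(env$records)
      tab <- correlatePairs(env$kym, env$records)
      env$selection <- rankKeywords(tab, min(cfg$pubs$topN,
                                             nrow(keywordCounts(env$kym))))
      writeCorrelationTable(env$selection$ranking,
                            out("correlations.tsv"))
    },
    movie = function() {
      if (is.null(env$kym)) stop("stage 'pubs' must run first")
      pos <- if (!is.null(env$topo)) positions(env$topo) else
        generatePositions(length(env$selection$keywords),
                          stageSeeds[["movie"]])
      env$pubMovie <- buildActivityMovie(
        env$kym, env$selection$keywords, pos,
        seed = stageSeeds[["movie"]], mode = cfg$movie$mode)
      writeActivityMovie(env$pubMovie, out("activity.csv"))
    },
    emd = function() {
      mc <- cfg$emd$maxClusters
      if (!is.null(env$neuronMovie)) {
        curve <- movieEMDCurve(env$neuronMovie, maxClusters = mc)
        writeEMDCurve(curve, out("emd_neurons.csv"))
      }
      if (!is.null(env$pubMovie)) {
        curve <- movieEMDCurve(env$pubMovie, maxClusters = mc)
        writeEMDCurve(curve, out("emd_publications.csv"),
                      labels = env$pubMovie@frameLabels)
      }
      if (is.null(env$neuronMovie) && is.null(env$pubMovie))
        stop("no movie available; run 'fluoresce' or 'movie' first")
    },
    te = function() {
      if (is.null(env$neuronMovie)) stop("stage 'fluoresce' must run first")
      vals <- fluorValues(env$neuronMovie)
      keep <- seq_len(min(ncol(vals), cfg$te$nNodesMax))
      sub <- FluorescenceMovie(vals[, keep, drop = FALSE],
                               frameDt = env$neuronMovie@frameDt)
      tem <- transferEntropyMatrix(sub, TEParams(k = cfg$te$k,
                                                 nBins = cfg$te$nBins))
      writeTEMatrix(tem, out("te_matrix.tsv"))
    })

  order <- c("synth", "calibrate", "simulate", "fluoresce", "pubs",
             "movie", "emd", "te")
  for (st in intersect(order, cfg$stages)) {
    say("stage: ", st)
    tryCatch(stageFun[[st]](),
             error = function(e)
               stop("stage '", st, "' failed: ", conditionMessage(e),
                    call. = FALSE))
  }

  manifest <- list(
    seed = cfg$seed,
    stages = intersect(order, cfg$stages),
    parameters = cfg,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.pipeTopology <- function(cfg, stageSeeds, env) {
  if (is.null(env$topo))
    env$topo <- generateTopology(cfg$network$nNeurons, cfg$network$meanDegree,
                                 cfg$network$lambda,
                                 seed = stageSeeds[["simulate"]])
  env$topo
}

.pipeSimParams <- function(cfg, stageSeeds) {
  SimParams(duration = cfg$sim$duration, dt = cfg$sim$dt,
            alphaInt = cfg$sim$alphaInt, alphaExt = cfg$sim$alphaExt,
            extRate = cfg$sim$extRate, seed = stageSeeds[["simulate"]])
}
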