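#' Generate a synthetic publication corpus with planted correlated pairs
#'
#' Emulates the statistical structure of a topic's publication record
#' export: records carry a year and a keyword list; yearly keyword counts
#' fluctuate around log-normal latent intensities; selected keyword pairs
#' are planted with a target correlation \code{rho} by sharing a latent
#' channel; optional burst epochs multiply the shared channel of a planted
#' pair by \code{burstHeight}, producing the bursty, spiking-like activity
#' the downstream movie comparison looks for.
#'
#' For a planted pair the log latent intensity of each member is
#' \code{sqrt(rho) * u(y) + sqrt(1 - rho) * v_k(y)} with \code{u} shared
#' and \code{v_k} independent, both zero-mean Gaussian with the same
#' variance, so the log-latent correlation equals \code{rho} exactly;
#' Poisson count noise attenuates the realized correlation of the yearly
#' counts, and burst epochs (which live entirely in the shared channel)
#' raise it. Members of a planted pair are placed on the same record with
#' probability \code{coOccurrenceProb}; background records draw two
#' distinct keywords from the background vocabulary so noise pairs also
#' co-occur and enter the correlation table.
#'
#' If the requested \code{rho} exceeds what the Poisson count noise can
#' express at the configured baseline rate, a warning reports the
#' approximate achievable bound.
#'
#' @param spec a [CorpusSpec-class]
#' @return list with \code{records} (as from [parseRecords()]) and
#'   \code{truth}: planted pair list with realized latent intensity
#'   curves, burst epoch markers and the keyword vocabulary
#' @examples
#' spec <- CorpusSpec(plantedPairs = list(list(
#'   keywords = c("alpha", "beta"), rho = 0.95, burstYears = 1990:1994)))
#' corpus <- generateCorpus(spec)
#' length(corpus$records)
#' @export
generateCorpus <- function(spec) {
  stopifnot(is(spec, "CorpusSpec"))
  set.seed(spec@seed)
  years <- spec@years
  nY <- length(years)
  sigma <- 0.5   # log-latent SD of the yearly intensity fluctuations

  planted <- unlist(lapply(spec@plantedPairs, `[[`, "keywords"))
  if (anyDuplicated(planted))
    stop("planted pairs must use distinct keywords")
  nBackground <- spec@nKeywords - length(planted)
  if (nBackground < 2)
    stop("nKeywords must leave at least 2 background keywords")
  background <- sprintf("topic%03d", seq_len(nBackground))

  ## latent intensity curves for planted keywords
  truthPairs <- list()
  lambdas <- list()
  for (p in spec@plantedPairs) {
    rho <- abs(p$rho)
    u <- stats::rnorm(nY, 0, sigma)
    if (!is.null(p$burstYears))
      u <- u + log(spec@burstHeight) * as.numeric(years %in% p$burstYears)
    lam <- sapply(1:2, function(k) {
      v <- stats::rnorm(nY, 0, sigma)
      spec@baselineRate * exp(sqrt(rho) * u + sqrt(1 - rho) * v)
    })
    lambdas[[p$keywords[1]]] <- lam[, 1]
    lambdas[[p$keywords[2]]] <- lam[, 2]
    # rough feasibility: Poisson noise caps the count correlation near
    # var(latent) / (var(latent) + mean(latent))
    v <- stats::var(c(lam)); m <- mean(lam)
    bound <- v / (v + m)
    if (spec@countNoise == "poisson" && rho > bound + 0.05)
      warning(sprintf(
        "target rho %.2f likely unattainable at this noise level; achievable about %.2f",
        rho, bound))
    truthPairs[[length(truthPairs) + 1L]] <- list(
      keywords = p$keywords, rho = p$rho,
      burstYears = if (is.null(p$burstYears)) integer() else p$burstYears,
      latent = stats::setNames(as.data.frame(lam), p$keywords))
  }
  for (k in background)
    lambdas[[k]] <- spec@baselineRate *
      exp(stats::rnorm(nY, 0, sigma) - sigma^2 / 2)

  ## records
  records <- list()
  recId <- 0L
  addRec <- function(year, kws) {
    recId <<- recId + 1L
    records[[recId]] <<- list(id = sprintf("SYN%07d", recId),
                              year = year, keywords = kws,
                              dialect = "medline")
  }
  for (yi in seq_len(nY)) {
    y <- years[yi]
    for (p in spec@plantedPairs) {
      a <- p$keywords[1]; b <- p$keywords[2]
      nA <- .drawCount(lambdas[[a]][yi], spec@countNoise)
      nB <- .drawCount(lambdas[[b]][yi], spec@countNoise)
      nAB <- stats::rbinom(1, min(nA, nB), spec@coOccurrenceProb)
      if (nAB > 0) for (q in seq_len(nAB)) addRec(y, c(a, b))
      if (nA - nAB > 0) for (q in seq_len(nA - nAB)) addRec(y, a)
      if (nB - nAB > 0) for (q in seq_len(nB - nAB)) addRec(y, b)
    }
    nRec <- stats::rpois(1, spec@recordsPerYear)
    w <- vapply(background, function(k) lambdas[[k]][yi], numeric(1))
    for (q in seq_len(nRec)) {
      kws <- sample(background, 2, prob = w)
      addRec(y, kws)
    }
  }
  list(records = records,
       truth = list(pairs = truthPairs, years = years,
                    keywords = c(planted, background)))
}

.drawCount <- function(lambda, noise) {
  if (noise == "poisson") stats::rpois(1, lambda) else round(lambda)
}

#' Write a record list in a supported dialect
#'
#' Serializes records in the MEDLINE tagged-field format (default), the
#' tab-delimited WoS-style export, or the tab-delimited patent
#' classification format, so the full parser path can be exercised on
#' generated corpora. [parseRecords()] reads the files back.
#'
#' @param records record list from [generateCorpus()]
#' @param path output file
#' @param dialect \code{"medline"}, \code{"wos"} or \code{"patent"}
#' @return \code{path}, invisibly
#' @export
writeCorpus <- function(records, path,
                        dialect = c("medline", "wos", "patent")) {
  dialect <- match.arg(dialect)
  if (dialect == "medline") {
    blocks <- vapply(records, function(r) {
      paste(c(paste0("PMID- ", r$id),
              paste0("DP  - ", r$year),
              paste0("MH  - ", r$keywords)), collapse = "\n")
    }, character(1))
    writeLines(paste(blocks, collapse = "\n\n"), path)
  } else {
    kw <- vapply(records, function(r)
      paste(r$keywords, collapse = ";"), character(1))
    yr <- vapply(records, function(r) as.integer(r$year), integer(1))
    id <- vapply(records, `[[`, character(1), "id")
    df <- if (dialect == "wos")
      data.frame(UT = id, PY = yr, WC = kw, SC = "") else
      data.frame(PATNO = id, PY = yr, CPC = kw, ICL = "")
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Uniform random positions in the unit square
#'
#' i.i.d. uniform coordinates emulating the neuron-position files of the
#' 1 mm^2 dish; deterministic per seed.
#'
#' @param n number of points (>= 1)
#' @param seed RNG seed
#' @return n x 2 matrix of coordinates in \[0, 1\]^2
#' @export
generatePositions <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  cbind(stats::runif(n), stats::runif(n))
}

#' Generate a raster of synchronous population bursts
#'
#' Population events occur at Poisson times with the given rate; at each
#' event every neuron participates independently with probability
#' \code{participation}, spiking at the event time plus a non-negative
#' jitter. The ground-truth event times are attached as attribute
#' \code{"eventTimes"} — the fixture for testing burst detection and
#' calibration plumbing against a known rate.
#'
#' @param n number of neurons
#' @param rate population-event rate (Hz)
#' @param duration raster duration (s)
#' @param seed RNG seed
#' @param participation per-neuron participation probability per event
#' @param jitterSd spike-time jitter SD within a burst (ms)
#' @param eventTimes optional explicit event times (ms) overriding the
#'   Poisson draw
#' @return a [SpikeRaster-class] with attribute \code{"eventTimes"}
#' @export
generateBurstRaster <- function(n, rate, duration, seed = 1L,
                                participation = 1.0, jitterSd = 5,
                                eventTimes = NULL) {
  if (is.null(eventTimes) && rate * duration < 1)
    stop("rate * duration must be >= 1")
  set.seed(seed)
  durMs <- duration * 1000
  if (is.null(eventTimes)) {
    nEvents <- stats::rpois(1, rate * duration)
    eventTimes <- sort(stats::runif(nEvents, 0, durMs))
  }
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    part <- stats::runif(length(eventTimes)) < participation
    t <- eventTimes[part] + abs(stats::rnorm(sum(part), 0, jitterSd))
    spikes[[i]] <- sort(pmin(t, durMs))
  }
  raster <- SpikeRaster(spikes, duration = durMs)
  attr(raster, "eventTimes") <- eventTimes
  raster
}
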