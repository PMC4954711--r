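#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Simulation parameters for the LIF network
#'
#' Bundles the membrane, synapse and short-term-depression constants of the
#' excitatory leaky integrate-and-fire network together with the integration
#' settings. Defaults are the standard constants for cultured-network
#' simulations: leak conductance 50 pS, membrane time constant 20 ms, spike
#' threshold 20 mV, refractory period 2 ms, synaptic time constant 2 ms,
#' synaptic delay 2 ms, release fraction U = 0.3, inactivation time scale
#' 3 ms and recovery time scale 500 ms.
#'
#' @slot gL leak conductance (pS)
#' @slot tauM membrane time constant (ms)
#' @slot vThr spike threshold (mV)
#' @slot tRef refractory period (ms)
#' @slot tauS synaptic time constant (ms)
#' @slot tD synaptic delay (ms)
#' @slot alphaInt recurrent synaptic weight (pA)
#' @slot alphaExt external-input weight (pA)
#' @slot extRate external Poisson rate per neuron (Hz)
#' @slot U release fraction moved from the recovered to the effective
#'   synaptic pool per presynaptic spike (dimensionless)
#' @slot tauInact inactivation time scale of the effective pool (ms)
#' @slot tauRec recovery time scale of the recovered pool (ms)
#' @slot dt integration step (ms)
#' @slot duration simulated time (s)
#' @slot seed RNG seed
#' @export
setClass("SimParams", representation(
  gL = "numeric", tauM = "numeric", vThr = "numeric", tRef = "numeric",
  tauS = "numeric", tD = "numeric", alphaInt = "numeric",
  alphaExt = "numeric", extRate = "numeric", U = "numeric",
  tauInact = "numeric", tauRec = "numeric", dt = "numeric",
  duration = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  tc <- c(tauM = object@tauM, tRef = object@tRef, tauS = object@tauS,
          tauInact = object@tauInact, tauRec = object@tauRec)
  if (any(tc <= 0)) msg <- c(msg, "all time constants must be > 0")
  if (object@gL <= 0) msg <- c(msg, "gL must be > 0")
  if (object@U <= 0 || object@U > 1) msg <- c(msg, "U must be in (0, 1]")
  if (object@dt <= 0 || object@dt >= min(object@tauS, object@tRef))
    msg <- c(msg, "dt must satisfy 0 < dt < min(tauS, tRef)")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@extRate < 0) msg <- c(msg, "extRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param gL,tauM,vThr,tRef,tauS,tD,alphaInt,alphaExt,extRate,U,tauInact,tauRec,dt,duration,seed
#'   see the corresponding slots.
#' @return `SimParams()` returns a validated \code{SimParams} object.
#' @rdname SimParams-class
#' @export
SimParams <- function(gL = 50, tauM = 20, vThr = 20, tRef = 2, tauS = 2,
                      tD = 2, alphaInt = 5, alphaExt = 10, extRate = 5,
                      U = 0.3, tauInact = 3, tauRec = 500, dt = 0.1,
                      duration = 200, seed = 1L) {
  new("SimParams", gL = gL, tauM = tauM, vThr = vThr, tRef = tRef,
      tauS = tauS, tD = tD, alphaInt = alphaInt, alphaExt = alphaExt,
      extRate = extRate, U = U, tauInact = tauInact, tauRec = tauRec,
      dt = dt, duration = duration, seed = as.integer(seed))
}

#' Network-burst detector settings
#'
#' A network burst is called when at least \code{fracThreshold} of the
#' neurons spike within a sliding window of \code{binWidth} ms; onsets
#' closer than \code{mergeGap} ms are merged into one burst.
#'
#' @slot binWidth sliding window width (ms)
#' @slot fracThreshold fraction of neurons that must spike within a window
#' @slot mergeGap minimum separation between distinct bursts (ms)
#' @export
setClass("BurstParams", representation(
  binWidth = "numeric", fracThreshold = "numeric", mergeGap = "numeric"))

setValidity("BurstParams", function(object) {
  if (object@fracThreshold <= 0 || object@fracThreshold > 1)
    return("fracThreshold must be in (0, 1]")
  if (object@binWidth <= 0 || object@mergeGap < 0)
    return("binWidth must be > 0 and mergeGap >= 0")
  TRUE
})

#' @param binWidth,fracThreshold,mergeGap see the corresponding slots.
#' @return `BurstParams()` returns a validated \code{BurstParams} object.
#' @rdname BurstParams-class
#' @export
BurstParams <- function(binWidth = 50, fracThreshold = 0.2, mergeGap = 100) {
  new("BurstParams", binWidth = binWidth, fracThreshold = fracThreshold,
      mergeGap = mergeGap)
}

#' Calcium-fluorescence model parameters
#'
#' Constants of the discrete calcium dynamics and the saturating indicator:
#' per-spike calcium increment A_Ca = 50 uM, decay constant tau_Ca = 1 s,
#' saturation concentration K_d = 300 uM, Gaussian readout noise with
#' standard deviation 0.03, frames sampled every 20 ms.
#'
#' @slot tauCa calcium decay constant (s)
#' @slot aCa per-spike calcium increment (uM)
#' @slot kD indicator saturation concentration (uM)
#' @slot noiseSd standard deviation of the additive Gaussian noise
#' @slot frameDt sampling interval (ms)
#' @slot seed RNG seed for the noise
#' @export
setClass("CaParams", representation(
  tauCa = "numeric", aCa = "numeric", kD = "numeric", noiseSd = "numeric",
  frameDt = "numeric", seed = "integer"))

setValidity("CaParams", function(object) {
  if (object@tauCa <= 0 || object@aCa <= 0 || object@kD <= 0 ||
      object@frameDt <= 0)
    return("tauCa, aCa, kD and frameDt must all be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@frameDt / 1000 >= object@tauCa)
    return("frameDt must be smaller than tauCa for a stable update")
  TRUE
})

#' @param tauCa,aCa,kD,noiseSd,frameDt,seed see the corresponding slots.
#' @return `CaParams()` returns a validated \code{CaParams} object.
#' @rdname CaParams-class
#' @export
CaParams <- function(tauCa = 1, aCa = 50, kD = 300, noiseSd = 0.03,
                     frameDt = 20, seed = 1L) {
  new("CaParams", tauCa = tauCa, aCa = aCa, kD = kD, noiseSd = noiseSd,
      frameDt = frameDt, seed = as.integer(seed))
}

#' Light-scattering parameters
#'
#' Additive Gaussian-kernel cross-talk between nearby sources: a neuron at
#' distance d contributes its fluorescence times
#' \code{aSc * exp(-(d/lambdaSc)^2)}.
#'
#' @slot lambdaSc scattering length scale (mm)
#' @slot aSc scattering amplitude (dimensionless)
#' @export
setClass("ScatterParams",
         representation(lambdaSc = "numeric", aSc = "numeric"))

setValidity("ScatterParams", function(object) {
  if (object@lambdaSc <= 0) return("lambdaSc must be > 0")
  if (object@aSc < 0) return("aSc must be >= 0")
  TRUE
})

#' @param lambdaSc,aSc see the corresponding slots.
#' @return `ScatterParams()` returns a validated \code{ScatterParams} object.
#' @rdname ScatterParams-class
#' @export
ScatterParams <- function(lambdaSc = 0.15, aSc = 0.15) {
  new("ScatterParams", lambdaSc = lambdaSc, aSc = aSc)
}

#' Transfer-entropy estimator settings
#'
#' @slot k Markov order (history length) of the conditioning vectors
#' @slot nBins number of discretization levels
#' @slot binMethod \code{"quantile"} (near-equal-mass bins) or
#'   \code{"fixed"} (user-supplied edges)
#' @slot edges bin edges for \code{binMethod = "fixed"}
#' @slot base logarithm base (2 reports bits)
#' @export
setClass("TEParams", representation(
  k = "integer", nBins = "integer", binMethod = "character",
  edges = "numeric", base = "numeric"))

setValidity("TEParams", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@nBins < 2L) return("nBins must be >= 2")
  if (!object@binMethod %in% c("quantile", "fixed"))
    return("binMethod must be 'quantile' or 'fixed'")
  if (object@binMethod == "fixed" && length(object@edges) < 1L)
    return("fixed binning requires at least one edge")
  if (object@base <= 0 || object@base == 1) return("invalid log base")
  TRUE
})

#' @param k,nBins,binMethod,edges,base see the corresponding slots.
#' @return `TEParams()` returns a validated \code{TEParams} object.
#' @rdname TEParams-class
#' @export
TEParams <- function(k = 1, nBins = 3, binMethod = "quantile",
                     edges = numeric(), base = 2) {
  new("TEParams", k = as.integer(k), nBins = as.integer(nBins),
      binMethod = binMethod, edges = edges, base = base)
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Network topology: adjacency, positions and pairwise distances
#'
#' Directed graph of synaptic connections together with the neuron
#' coordinates in the 1 mm^2 dish. Entry \code{adjacency[j, i] = 1} means a
#' synapse from neuron j onto neuron i.
#'
#' @slot adjacency n x n 0/1 matrix, zero diagonal
#' @slot positions n x 2 matrix of coordinates (mm) in the unit square
#' @slot distances n x n symmetric Euclidean distance matrix (mm)
#' @export
setClass("NetworkTopology", representation(
  adjacency = "matrix", positions = "matrix", distances = "matrix"))

setValidity("NetworkTopology", function(object) {
  msg <- character()
  A <- object@adjacency
  n <- nrow(A)
  if (ncol(A) != n) msg <- c(msg, "adjacency must be square")
  else {
    if (any(diag(A) != 0)) msg <- c(msg, "self-edges are not allowed")
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0/1")
  }
  if (nrow(object@positions) != n || ncol(object@positions) != 2)
    msg <- c(msg, "positions must be an n x 2 matrix")
  else if (any(object@positions < 0) || any(object@positions > 1))
    msg <- c(msg, "positions must lie in the unit square")
  D <- object@distances
  if (!all(dim(D) == c(n, n)) || any(abs(D - t(D)) > 1e-12) ||
      any(abs(diag(D)) > 1e-12))
    msg <- c(msg, "distances must be symmetric with zero diagonal")
  if (length(msg)) msg else TRUE
})

#' @param adjacency,positions see the corresponding slots; the distance
#'   matrix is computed from the positions.
#' @return `NetworkTopology()` returns a validated \code{NetworkTopology}.
#' @rdname NetworkTopology-class
#' @export
NetworkTopology <- function(adjacency, positions) {
  adjacency <- unname(as.matrix(adjacency))
  positions <- unname(as.matrix(positions))
  storage.mode(adjacency) <- "double"
  D <- unname(as.matrix(stats::dist(positions)))
  new("NetworkTopology", adjacency = adjacency, positions = positions,
      distances = D)
}

#' Spike raster
#'
#' Per-neuron sorted spike times plus the external (Poisson) event times
#' that drove the simulation. All times in ms.
#'
#' @slot spikes list of numeric vectors, one sorted vector per neuron
#' @slot external list of numeric vectors of external event times
#' @slot duration simulated time (ms)
#' @export
setClass("SpikeRaster", representation(
  spikes = "list", external = "list", duration = "numeric"))

setValidity("SpikeRaster", function(object) {
  msg <- character()
  for (s in object@spikes) {
    if (is.unsorted(s)) { msg <- c(msg, "spike times must be sorted"); break }
    if (length(s) && (s[1] < 0 || s[length(s)] > object@duration + 1e-9)) {
      msg <- c(msg, "spike times must lie within [0, duration]"); break
    }
  }
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param spikes,external,duration see the corresponding slots.
#' @return `SpikeRaster()` returns a validated \code{SpikeRaster}.
#' @rdname SpikeRaster-class
#' @export
SpikeRaster <- function(spikes, duration, external = NULL) {
  if (is.null(external)) external <- rep(list(numeric()), length(spikes))
  new("SpikeRaster", spikes = lapply(spikes, as.numeric),
      external = lapply(external, as.numeric), duration = duration)
}

#' Calcium concentration traces at frame resolution
#'
#' @slot calcium frames x neurons matrix of concentrations (uM)
#' @slot counts frames x neurons matrix of per-frame spike counts
#' @slot frameDt sampling interval (ms)
#' @export
setClass("CalciumTrace", representation(
  calcium = "matrix", counts = "matrix", frameDt = "numeric"))

setValidity("CalciumTrace", function(object) {
  if (any(object@calcium < 0)) return("concentrations must be >= 0")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("spike counts must be non-negative integers")
  if (!all(dim(object@calcium) == dim(object@counts)))
    return("calcium and counts must have identical dimensions")
  TRUE
})

#' Fluorescence movie
#'
#' Frames x neurons matrix of fluorescence values, one row per sampled
#' frame. \code{scattered} records whether light scattering has been
#' applied.
#'
#' @slot values frames x neurons matrix of fluorescence
#' @slot frameDt sampling interval (ms)
#' @slot positions neuron coordinates (may have zero rows when unknown)
#' @slot scattered logical
#' @export
setClass("FluorescenceMovie", representation(
  values = "matrix", frameDt = "numeric", positions = "matrix",
  scattered = "logical"))

setValidity("FluorescenceMovie", function(object) {
  if (!all(is.finite(object@values)))
    return("fluorescence values must be finite")
  if (nrow(object@positions) > 0 &&
      nrow(object@positions) != ncol(object@values))
    return("positions must have one row per neuron")
  TRUE
})

#' @param values,frameDt,positions,scattered see the corresponding slots.
#' @return `FluorescenceMovie()` returns a validated
#'   \code{FluorescenceMovie}.
#' @rdname FluorescenceMovie-class
#' @export
FluorescenceMovie <- function(values, frameDt = 20,
                              positions = matrix(numeric(), 0, 2),
                              scattered = FALSE) {
  new("FluorescenceMovie", values = as.matrix(values), frameDt = frameDt,
      positions = as.matrix(positions), scattered = scattered)
}

#' Keyword-by-year appearance counts
#'
#' Rows are keywords, columns a contiguous span of years; entry (k, y) is
#' the number of records in year y whose keyword list contains k.
#'
#' @slot counts keywords x years integer matrix with dimnames
#' @slot years the contiguous year axis
#' @export
setClass("KeywordYearMatrix",
         representation(counts = "matrix", years = "integer"))

setValidity("KeywordYearMatrix", function(object) {
  if (any(object@counts < 0) ||
      any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (ncol(object@counts) != length(object@years))
    return("one column per year required")
  if (length(object@years) > 1 && any(diff(object@years) != 1L))
    return("year axis must be contiguous")
  TRUE
})

#' Activity movie over a node layout
#'
#' One frame per time step (year for publication data), one column per
#' laid-out node; intensities are globally min-max normalized to \[0, 1\] so
#' that different movies show comparable shades.
#'
#' @slot intensity frames x nodes matrix in \[0, 1\]
#' @slot layout data.frame with columns \code{node}, \code{x}, \code{y}
#' @slot frameLabels label per frame (e.g. years)
#' @export
setClass("ActivityMovie", representation(
  intensity = "matrix", layout = "data.frame", frameLabels = "character"))

setValidity("ActivityMovie", function(object) {
  if (any(object@intensity < -1e-9) || any(object@intensity > 1 + 1e-9))
    return("intensities must lie in [0, 1]")
  if (!all(c("node", "x", "y") %in% names(object@layout)))
    return("layout must have columns node, x, y")
  if (nrow(object@layout) != ncol(object@intensity))
    return("one layout row per node required")
  if (length(object@frameLabels) != nrow(object@intensity))
    return("one frame label per frame required")
  TRUE
})

#' Signature: a weighted point set
#'
#' Sparse representation of a spatial distribution as cluster centers with
#' non-negative weights, the input representation for the Earth Mover's
#' Distance.
#'
#' @slot points m x 2 matrix of cluster centers
#' @slot weights non-negative cluster weights
#' @export
setClass("Signature", representation(points = "matrix", weights = "numeric"))

setValidity("Signature", function(object) {
  if (nrow(object@points) != length(object@weights))
    return("one weight per cluster center required")
  if (ncol(object@points) != 2) return("points must be m x 2")
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (!any(object@weights > 0)) return("at least one positive weight required")
  TRUE
})

#' @param points,weights see the corresponding slots.
#' @param normalize if \code{TRUE} (default) rescale weights to sum to 1,
#'   the equal-total-weight condition under which the EMD is a metric.
#' @return `Signature()` returns a validated \code{Signature}.
#' @rdname Signature-class
#' @export
Signature <- function(points, weights, normalize = TRUE) {
  points <- as.matrix(points)
  if (!any(weights > 0)) stop("at least one positive weight required")
  if (normalize) weights <- weights / sum(weights)
  new("Signature", points = points, weights = as.numeric(weights))
}

#' Synthetic-corpus specification
#'
#' Describes a synthetic publication corpus: keyword vocabulary size, year
#' span, records per year, planted high-correlation keyword pairs riding on
#' shared bursty latent intensities, and the background noise level.
#'
#' @slot nKeywords vocabulary size (planted keywords included)
#' @slot years contiguous integer year axis
#' @slot recordsPerYear expected number of records per year
#' @slot plantedPairs list of lists with elements \code{keywords}
#'   (character(2)), \code{rho} (target correlation) and optional
#'   \code{burstYears} (years of shared burst epochs)
#' @slot coOccurrenceProb probability that both members of a planted pair
#'   appear on the same record when either is drawn
#' @slot baselineRate baseline expected appearances per keyword per year
#' @slot burstHeight multiplicative height of burst epochs
#' @slot countNoise \code{"poisson"} (counts drawn around the latent
#'   intensity) or \code{"none"} (counts are the rounded latent intensity,
#'   so identical latent curves give identical series)
#' @slot seed RNG seed
#' @export
setClass("CorpusSpec", representation(
  nKeywords = "integer", years = "integer", recordsPerYear = "numeric",
  plantedPairs = "list", coOccurrenceProb = "numeric",
  baselineRate = "numeric", burstHeight = "numeric",
  countNoise = "character", seed = "integer"))

setValidity("CorpusSpec", function(object) {
  msg <- character()
  if (object@nKeywords < 1L) msg <- c(msg, "nKeywords must be >= 1")
  if (length(object@years) < 2L || any(diff(object@years) != 1L))
    msg <- c(msg, "years must be a contiguous span of length >= 2")
  for (p in object@plantedPairs) {
    if (abs(p$rho) > 1) msg <- c(msg, "|rho| must be <= 1")
    if (!is.null(p$burstYears) && !all(p$burstYears %in% object@years))
      msg <- c(msg, "burst epochs must lie within the year span")
  }
  if (object@coOccurrenceProb < 0 || object@coOccurrenceProb > 1)
    msg <- c(msg, "coOccurrenceProb must be in [0, 1]")
  if (!object@countNoise %in% c("poisson", "none"))
    msg <- c(msg, "countNoise must be 'poisson' or 'none'")
  if (length(msg)) msg else TRUE
})

#' @param nKeywords,years,recordsPerYear,plantedPairs,coOccurrenceProb,baselineRate,burstHeight,countNoise,seed
#'   see the corresponding slots.
#' @return `CorpusSpec()` returns a validated \code{CorpusSpec}.
#' @rdname CorpusSpec-class
#' @export
CorpusSpec <- function(nKeywords = 30, years = 1970:2014,
                       recordsPerYear = 60, plantedPairs = list(),
                       coOccurrenceProb = 0.8, baselineRate = 3,
                       burstHeight = 8, countNoise = "poisson",
                       seed = 1L) {
  new("CorpusSpec", nKeywords = as.integer(nKeywords),
      years = as.integer(years), recordsPerYear = recordsPerYear,
      plantedPairs = plantedPairs, coOccurrenceProb = coOccurrenceProb,
      baselineRate = baselineRate, burstHeight = burstHeight,
      countNoise = countNoise, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' Adjacency matrix of a topology
#' @param x a \code{NetworkTopology}
#' @return the n x n 0/1 adjacency matrix
#' @rdname NetworkTopology-class
#' @aliases adjacency
#' @export
setMethod("adjacency", "NetworkTopology", function(x) x@adjacency)

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname NetworkTopology-class
#' @aliases positions
#' @export
setMethod("positions", "NetworkTopology", function(x) x@positions)
#' @rdname FluorescenceMovie-class
#' @aliases positions,FluorescenceMovie-method
#' @export
setMethod("positions", "FluorescenceMovie", function(x) x@positions)

#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname NetworkTopology-class
#' @aliases distances
#' @export
setMethod("distances", "NetworkTopology", function(x) x@distances)

#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname NetworkTopology-class
#' @aliases nNodes
#' @export
setMethod("nNodes", "NetworkTopology", function(x) nrow(x@adjacency))
#' @rdname SpikeRaster-class
#' @aliases nNodes,SpikeRaster-method
#' @export
setMethod("nNodes", "SpikeRaster", function(x) length(x@spikes))
#' @rdname FluorescenceMovie-class
#' @aliases nNodes,FluorescenceMovie-method
#' @export
setMethod("nNodes", "FluorescenceMovie", function(x) ncol(x@values))

#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname SpikeRaster-class
#' @aliases spikeTimes
#' @export
setMethod("spikeTimes", "SpikeRaster", function(x) x@spikes)

#' @export
setGeneric("fluorValues", function(x) standardGeneric("fluorValues"))
#' @rdname FluorescenceMovie-class
#' @aliases fluorValues
#' @export
setMethod("fluorValues", "FluorescenceMovie", function(x) x@values)

#' @export
setGeneric("keywordCounts", function(x) standardGeneric("keywordCounts"))
#' @rdname KeywordYearMatrix-class
#' @aliases keywordCounts
#' @export
setMethod("keywordCounts", "KeywordYearMatrix", function(x) x@counts)

#' @export
setGeneric("yearAxis", function(x) standardGeneric("yearAxis"))
#' @rdname KeywordYearMatrix-class
#' @aliases yearAxis
#' @export
setMethod("yearAxis", "KeywordYearMatrix", function(x) x@years)

#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname ActivityMovie-class
#' @aliases intensityMatrix
#' @export
setMethod("intensityMatrix", "ActivityMovie", function(x) x@intensity)

#' @export
setGeneric("nodeLayout", function(x) standardGeneric("nodeLayout"))
#' @rdname ActivityMovie-class
#' @aliases nodeLayout
#' @export
setMethod("nodeLayout", "ActivityMovie", function(x) x@layout)

#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname Signature-class
#' @aliases clusterCenters
#' @export
setMethod("clusterCenters", "Signature", function(x) x@points)

#' @export
setGeneric("clusterWeights", function(x) standardGeneric("clusterWeights"))
#' @rdname Signature-class
#' @aliases clusterWeights
#' @export
setMethod("clusterWeights", "Signature", function(x) x@weights)

setMethod("show", "NetworkTopology", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("NetworkTopology: %d neurons, %d directed edges (density %.3f)\n",
              n, sum(object@adjacency),
              sum(object@adjacency) / max(1, n * (n - 1))))
})

setMethod("show", "SpikeRaster", function(object) {
  ns <- sum(lengths(object@spikes))
  cat(sprintf("SpikeRaster: %d neurons, %d spikes over %.1f s\n",
              length(object@spikes), ns, object@duration / 1000))
})

setMethod("show", "FluorescenceMovie", function(object) {
  cat(sprintf("FluorescenceMovie: %d frames x %d neurons every %g ms%s\n",
              nrow(object@values), ncol(object@values), object@frameDt,
              if (object@scattered) " (scattered)" else ""))
})

setMethod("show", "KeywordYearMatrix", function(object) {
  cat(sprintf("KeywordYearMatrix: %d keywords x years %d-%d (%d occurrences)\n",
              nrow(object@counts), min(object@years), max(object@years),
              sum(object@counts)))
})

setMethod("show", "ActivityMovie", function(object) {
  cat(sprintf("ActivityMovie: %d frames x %d nodes\n",
              nrow(object@intensity), ncol(object@intensity)))
})

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature: %d clusters, total weight %.6g\n",
              nrow(object@points), sum(object@weights)))
})
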