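#' Generate a clustered network topology in the unit square
#'
#' Places \code{n} neurons uniformly at random in the 1 mm^2 dish and draws
#' directed synapses with a distance-dependent probability
#' \code{p(d) = p0 * exp(-(d / lambda)^2)}, where \code{p0} is chosen so the
#' expected mean out-degree equals \code{meanDegree}. Short-range
#' connectivity makes connected triangles more likely than in a uniform
#' random graph, i.e. it raises the clustering coefficient — the knob is
#' \code{lambda}: smaller values give more local, more clustered wiring.
#'
#' @param n number of neurons (>= 2)
#' @param meanDegree target expected out-degree
#' @param lambda length scale of the connection-probability kernel (mm)
#' @param seed RNG seed; the same seed always yields the same topology
#' @param positions optional n x 2 matrix of coordinates in the unit
#'   square; when supplied only the edges are drawn at random
#' @return a [NetworkTopology-class] object
#' @examples
#' topo <- generateTopology(50, seed = 1)
#' nNodes(topo)
#' @export
generateTopology <- function(n, meanDegree = 15, lambda = 0.3, seed = 1L,
                             positions = NULL) {
  if (n < 2) stop("a network needs at least 2 neurons")
  if (meanDegree <= 0 || meanDegree > n - 1)
    stop("meanDegree must be in (0, n - 1]")
  set.seed(seed)
  if (is.null(positions)) {
    positions <- cbind(stats::runif(n), stats::runif(n))
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != n) stop("positions must have n rows")
  }
  D <- as.matrix(stats::dist(positions))
  K <- exp(-(D / lambda)^2)
  diag(K) <- 0
  # scale the kernel so the expected edge count is n * meanDegree,
  # capping probabilities at 1
  target <- n * meanDegree
  p0 <- target / sum(K)
  P <- pmin(1, p0 * K)
  for (rep in 1:20) {   # fixed-point correction for the capping
    err <- target / sum(P)
    if (abs(err - 1) < 1e-6) break
    P <- pmin(1, P * err)
  }
  A <- matrix(0, n, n)
  A[stats::runif(n * n) < P] <- 1
  diag(A) <- 0
  NetworkTopology(adjacency = A, positions = positions)
}

#' Mean local clustering coefficient of a topology
#'
#' Computed on the undirected skeleton of the synapse graph with
#' \pkg{igraph}; isolated and degree-1 vertices count as zero.
#'
#' @param topo a [NetworkTopology-class]
#' @return mean local clustering coefficient in \[0, 1\]
#' @export
clusteringCoefficient <- function(topo) {
  g <- igraph::graph_from_adjacency_matrix(adjacency(topo) > 0,
                                           mode = "max")
  igraph::transitivity(g, type = "average", isolates = "zero")
}

#' Number of weakly connected components of the synapse graph
#'
#' @param topo a [NetworkTopology-class]
#' @return integer component count
#' @export
componentCount <- function(topo) {
  g <- igraph::graph_from_adjacency_matrix(adjacency(topo) > 0,
                                           mode = "max")
  igraph::count_components(g)
}

#' One integration step of the LIF network (reference implementation)
#'
#' Advances membrane potentials, synaptic currents and the full n x n
#' synaptic-resource matrices by one step \code{dt}, in the same order of
#' operations as the compiled simulation loop: exponential decay of all
#' states, delivery of delayed arrivals, threshold detection with reset,
#' refractory clamp and the depression jump (a fraction \code{U} of the
#' recovered pool moves to the effective pool at each presynaptic spike).
#' This R-level stepper exists as an executable statement of the update
#' equations and for tests; [simulateNetwork()] runs the same dynamics in
#' compiled code.
#'
#' @param state list with elements \code{V} (mV), \code{Isyn} (pA),
#'   \code{refUntil} (ms) — vectors of length n — and \code{t} (ms)
#' @param syn list with n x n matrices \code{E} and \code{R} (entry
#'   \code{[j, i]} is the state of synapse j -> i)
#' @param topo a [NetworkTopology-class]
#' @param params a [SimParams-class]
#' @param arrivals list with \code{recurrent}: integer vector of
#'   presynaptic neurons whose spikes arrive during this step, and
#'   \code{external}: integer vector of neurons receiving an external event
#' @return list with updated \code{state}, \code{syn} and \code{spiked}
#'   (indices of neurons that fired in this step)
#' @export
stepNetwork <- function(state, syn, topo, params,
                        arrivals = list(recurrent = integer(),
                                        external = integer())) {
  if (!all(is.finite(state$V)) || !all(is.finite(state$Isyn)))
    stop("non-finite neuron state entering the integration step")
  A <- adjacency(topo)
  n <- nrow(A)
  dt <- params@dt
  t <- state$t + dt

  decV <- exp(-dt / params@tauM)
  decI <- exp(-dt / params@tauS)
  decE <- exp(-dt / params@tauInact)
  decR <- exp(-dt / params@tauRec)

  ## 1. decay: V toward the current drive, Isyn, E; R relaxes toward 1 - E
  drive <- 1000 * state$Isyn / params@gL   # pA / pS = V, expressed in mV
  V <- state$V * decV + drive * (1 - decV)
  V[t < state$refUntil - 0.5 * dt] <- 0   # half-step tolerance: FP-safe
  Isyn <- state$Isyn * decI
  E <- syn$E * decE
  R <- (1 - E) + (syn$R - (1 - E)) * decR

  ## 2. delayed arrivals: recurrent spikes weighted by alpha_int * E_ji,
  ##    external events by alpha_ext
  for (j in arrivals$recurrent) {
    Isyn <- Isyn + params@alphaInt * E[j, ] * A[j, ]
  }
  for (i in arrivals$external) {
    Isyn[i] <- Isyn[i] + params@alphaExt
  }

  ## 3. threshold: reset to 0, clamp for tRef, move U of R into E
  spiked <- which(V >= params@vThr & t >= state$refUntil - 0.5 * dt)
  refUntil <- state$refUntil
  if (length(spiked)) {
    V[spiked] <- 0
    refUntil[spiked] <- t + params@tRef
    moved <- params@U * R[spiked, , drop = FALSE]
    E[spiked, ] <- E[spiked, , drop = FALSE] + moved
    R[spiked, ] <- R[spiked, , drop = FALSE] - moved
  }
  if (!all(is.finite(V)) || !all(is.finite(Isyn)))
    stop("non-finite neuron state produced by the integration step")

  list(state = list(V = V, Isyn = Isyn, refUntil = refUntil, t = t),
       syn = list(E = E, R = R), spiked = spiked)
}

#' Initial neuron and synapse state
#'
#' All membrane potentials and currents at zero, all synaptic resources
#' recovered (R = 1, E = 0).
#'
#' @param n number of neurons
#' @return list with \code{state} and \code{syn} as used by [stepNetwork()]
#' @export
initialState <- function(n) {
  list(state = list(V = numeric(n), Isyn = numeric(n),
                    refUntil = rep(-1, n), t = 0),
       syn = list(E = matrix(0, n, n), R = matrix(1, n, n)))
}

#' Simulate the excitatory LIF network with synaptic depression
#'
#' Runs the compiled event loop: leaky integrate-and-fire membranes driven
#' by exponentially decaying synaptic currents, short-term depression of
#' the recurrent synapses, delayed spike delivery and independent external
#' Poisson drive per neuron. The raster is fully determined by
#' \code{(topo, params, params@seed)}.
#'
#' @param topo a [NetworkTopology-class]
#' @param params a [SimParams-class]; \code{params@duration} is in seconds
#' @param recordState record V/E/R trajectories every \code{recordEvery}
#'   steps (for diagnostics and tests; memory grows accordingly)
#' @param recordEvery recording stride in steps
#' @return a [SpikeRaster-class]; with \code{recordState = TRUE} the raster
#'   carries an attribute \code{"stateTrace"} with matrices \code{V},
#'   \code{E}, \code{R} and the sample \code{times}
#' @examples
#' topo <- generateTopology(20, seed = 1)
#' raster <- simulateNetwork(topo, SimParams(duration = 2, seed = 1))
#' raster
#' @export
simulateNetwork <- function(topo, params, recordState = FALSE,
                            recordEvery = 10L) {
  stopifnot(is(topo, "NetworkTopology"), is(params, "SimParams"))
  A <- adjacency(topo)
  storage.mode(A) <- "integer"
  set.seed(params@seed)
  res <- sim_lif_cpp(A, params@dt, params@duration * 1000,
                     params@tauM, params@gL, params@vThr, params@tRef,
                     params@tauS, params@tD, params@alphaInt,
                     params@alphaExt, params@extRate,
                     params@U, params@tauInact, params@tauRec,
                     recordState, as.integer(recordEvery))
  raster <- SpikeRaster(res$spikes, duration = params@duration * 1000,
                        external = res$external)
  if (recordState) {
    attr(raster, "stateTrace") <- list(V = res$V, E = res$E, R = res$R,
                                       Isyn = res$Isyn, times = res$times)
  }
  raster
}

#' Detect network bursts in a spike raster
#'
#' Slides a window of \code{bp@binWidth} ms over the raster and calls a
#' network burst whenever at least \code{bp@fracThreshold} of the neurons
#' spike within one window; onsets closer than \code{bp@mergeGap} ms are
#' merged. An empty raster yields a rate of 0 Hz.
#'
#' @param raster a [SpikeRaster-class]
#' @param bp a [BurstParams-class]
#' @return list with \code{times} (burst onset times, ms), \code{count}
#'   and \code{rate} (Hz, count / duration)
#' @export
detectBursts <- function(raster, bp = BurstParams()) {
  n <- nNodes(raster)
  durS <- raster@duration / 1000
  if (durS <= 0) stop("raster duration must be > 0")
  times <- unlist(raster@spikes, use.names = FALSE)
  ids <- rep.int(seq_len(n), lengths(raster@spikes))
  if (length(times) == 0)
    return(list(times = numeric(), count = 0L, rate = 0))
  o <- order(times)
  times <- times[o]; ids <- ids[o]
  need <- ceiling(bp@fracThreshold * n)

  ## two-pointer sweep: for each spike as window start, count distinct
  ## neurons in [t, t + binWidth)
  onsets <- numeric()
  cnt <- integer(n)
  distinct <- 0L
  lo <- 1L
  lastBurst <- -Inf
  for (hi in seq_along(times)) {
    i <- ids[hi]
    cnt[i] <- cnt[i] + 1L
    if (cnt[i] == 1L) distinct <- distinct + 1L
    while (times[hi] - times[lo] >= bp@binWidth) {
      j <- ids[lo]
      cnt[j] <- cnt[j] - 1L
      if (cnt[j] == 0L) distinct <- distinct - 1L
      lo <- lo + 1L
    }
    if (distinct >= need && times[lo] - lastBurst >= bp@mergeGap) {
      lastBurst <- times[lo]
      onsets <- c(onsets, times[lo])
    }
  }
  list(times = onsets, count = length(onsets), rate = length(onsets) / durS)
}

#' Calibrate the recurrent synaptic weight to a target bursting rate
#'
#' Implements the iterative weight adjustment: each iteration simulates
#' \code{params@duration} seconds (200 s by default) at the current
#' \code{alpha_int} and measures the network bursting rate. While the
#' target is not yet bracketed, the weight is decreased by 10% when the
#' measured rate exceeds the target and increased by 10% when it falls
#' short; once two evaluations straddle the target, linear extrapolation
#' between the bracketing (weight, rate) pairs refines the weight until
#' the measured rate is within \code{tolerance} of the target.
#'
#' Each iteration draws its own simulation seed from \code{params@seed} so
#' the whole calibration is reproducible.
#'
#' @param topo a [NetworkTopology-class]
#' @param params a [SimParams-class]; \code{params@alphaInt} is the initial
#'   weight (5.0 pA by default)
#' @param target target network bursting rate (Hz)
#' @param tolerance acceptable |rate - target| (Hz)
#' @param maxIter iteration cap
#' @param bp a [BurstParams-class] passed to [detectBursts()]
#' @param rateFun rate oracle used in tests: a function
#'   \code{function(alphaInt, iter) -> rate}; when \code{NULL} (default)
#'   each evaluation is a full simulation plus burst detection
#' @return list with \code{alphaInt} (final weight, pA),
#'   \code{measuredRate} (Hz, from a full-length run at the final weight),
#'   \code{iterations}, \code{converged} and \code{history}
#'   (data.frame of all (alphaInt, rate) evaluations)
#' @export
calibrateBursting <- function(topo, params, target = 0.1, tolerance = 0.01,
                              maxIter = 50L, bp = BurstParams(),
                              rateFun = NULL) {
  set.seed(params@seed)
  iterSeeds <- sample.int(.Machine$integer.max, maxIter)
  evalRate <- function(alpha, iter) {
    if (!is.null(rateFun)) return(rateFun(alpha, iter))
    p <- params
    p@alphaInt <- alpha
    p@seed <- iterSeeds[iter]
    detectBursts(simulateNetwork(topo, p), bp)$rate
  }

  alpha <- params@alphaInt
  hist_a <- numeric()
  hist_r <- numeric()
  iter <- 0L
  # strict stopping rule: burst counts are discrete (1 burst / run =
  # 1/duration Hz), so a measured deviation can equal the tolerance
  # exactly; a small guard keeps FP rounding from accepting that case
  hit <- function(rate) abs(rate - target) < tolerance - 1e-9

  record <- function(a, r) {
    hist_a <<- c(hist_a, a); hist_r <<- c(hist_r, r)
  }

  ## phase 1: multiplicative +/-10% until the target is bracketed
  repeat {
    iter <- iter + 1L
    rate <- evalRate(alpha, iter)
    record(alpha, rate)
    if (hit(rate))
      return(list(alphaInt = alpha, measuredRate = rate, iterations = iter,
                  converged = TRUE,
                  history = data.frame(alphaInt = hist_a, rate = hist_r)))
    bracketed <- length(hist_r) >= 2 &&
      (min(hist_r) - target) * (max(hist_r) - target) < 0
    if (bracketed) break
    if (iter >= maxIter)
      stop("calibration did not bracket the target rate in ", maxIter,
           " iterations; history rates: ",
           paste(signif(hist_r, 3), collapse = ", "))
    alpha <- if (rate > target) alpha * 0.9 else alpha * 1.1
  }

  ## phase 2: linear extrapolation between the bracketing evaluations
  repeat {
    below <- which(hist_r < target)
    above <- which(hist_r > target)
    iLo <- below[which.max(hist_r[below])]   # closest from below
    iHi <- above[which.min(hist_r[above])]   # closest from above
    a1 <- hist_a[iLo]; r1 <- hist_r[iLo]
    a2 <- hist_a[iHi]; r2 <- hist_r[iHi]
    alpha <- if (abs(r2 - r1) < 1e-12) (a1 + a2) / 2 else
      a1 + (target - r1) * (a2 - a1) / (r2 - r1)
    iter <- iter + 1L
    rate <- evalRate(alpha, iter)
    record(alpha, rate)
    if (hit(rate))
      return(list(alphaInt = alpha, measuredRate = rate, iterations = iter,
                  converged = TRUE,
                  history = data.frame(alphaInt = hist_a, rate = hist_r)))
    if (iter >= maxIter)
      stop("calibration exceeded ", maxIter, " iterations; history rates: ",
           paste(signif(hist_r, 3), collapse = ", "))
  }
}

#' Read and write spike rasters as two-column text
#'
#' Format: one row per spike, columns \code{neuron} (0-based index) and
#' \code{time_ms}, tab separated, with a header line.
#'
#' @param raster a [SpikeRaster-class]
#' @param path file path
#' @param n number of neurons (needed on read: silent neurons leave no rows)
#' @param duration raster duration in ms (on read)
#' @return \code{readSpikeRaster} returns a [SpikeRaster-class];
#'   \code{writeSpikeRaster} returns \code{path} invisibly
#' @export
writeSpikeRaster <- function(raster, path) {
  n <- nNodes(raster)
  df <- data.frame(
    neuron = rep.int(seq_len(n) - 1L, lengths(raster@spikes)),
    time_ms = unlist(raster@spikes, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSpikeRaster
#' @export
readSpikeRaster <- function(path, n, duration) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("neuron", "time_ms") %in% names(df)))
    stop("expected columns 'neuron' and 'time_ms' in ", path)
  if (any(df$neuron < 0 | df$neuron >= n))
    stop("neuron indices out of range in ", path)
  spikes <- split(df$time_ms, factor(df$neuron, levels = 0:(n - 1)))
  SpikeRaster(lapply(spikes, sort), duration = duration)
}

#' Read an adjacency matrix from dense CSV or a coordinate list
#'
#' Dense: an n x n table of 0/1 values. Coordinate list: two or three
#' columns (\code{from}, \code{to} and optionally \code{weight}) of
#' 1-based indices.
#'
#' @param path file path
#' @param format \code{"dense"} or \code{"edgelist"}
#' @param n number of neurons (required for \code{"edgelist"})
#' @return a 0/1 adjacency matrix
#' @export
readAdjacency <- function(path, format = c("dense", "edgelist"), n = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    A <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A)) stop("dense adjacency must be square")
    return(A)
  }
  el <- utils::read.table(path, header = FALSE)
  if (is.null(n)) stop("n is required for edge-list input")
  A <- matrix(0, n, n)
  A[cbind(el[[1]], el[[2]])] <- 1
  A
}
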