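#' Calcium concentration traces from a spike raster
#'
#' Applies the discrete per-frame update
#' \deqn{[Ca]_t - [Ca]_{t-1} = -(\Delta t/\tau_{Ca}) [Ca]_{t-1} + A_{Ca} n_t}
#' where \eqn{n_t} is the number of action potentials the neuron fired in
#' frame t. Spikes are binned to frames of \code{params@frameDt} ms; each
#' spike raises the concentration by \code{params@aCa} uM and the
#' concentration decays by the factor \code{1 - frameDt/tauCa} per frame.
#'
#' @param raster a [SpikeRaster-class]
#' @param params a [CaParams-class]
#' @param duration duration to cover in seconds (default: raster duration)
#' @param ca0 initial concentration (uM), a scalar or per-neuron vector
#' @return a [CalciumTrace-class] with one row per frame
#' @export
calciumFromSpikes <- function(raster, params = CaParams(), duration = NULL,
                              ca0 = 0) {
  stopifnot(is(raster, "SpikeRaster"), is(params, "CaParams"))
  durMs <- if (is.null(duration)) raster@duration else duration * 1000
  if (any(unlist(raster@spikes) > durMs + 1e-9))
    stop("duration must cover all spike times")
  nFrames <- floor(durMs / params@frameDt)
  n <- nNodes(raster)
  counts <- matrix(0L, nFrames, n)
  for (i in seq_len(n)) {
    s <- raster@spikes[[i]]
    if (!length(s)) next
    # frame t covers ((t-1) * frameDt, t * frameDt]
    f <- pmin(nFrames, pmax(1L, ceiling(s / params@frameDt)))
    tab <- tabulate(f, nbins = nFrames)
    counts[, i] <- tab
  }
  keep <- 1 - params@frameDt / (params@tauCa * 1000)
  ca <- matrix(0, nFrames, n)
  prev <- rep_len(ca0, n)
  for (t in seq_len(nFrames)) {
    prev <- prev * keep + params@aCa * counts[t, ]
    ca[t, ] <- prev
  }
  new("CalciumTrace", calcium = ca, counts = counts,
      frameDt = params@frameDt)
}

#' Fluorescence from calcium concentration
#'
#' Saturating static non-linearity followed by additive Gaussian noise:
#' \deqn{F_{i,t} = [Ca]_{i,t} / ([Ca]_{i,t} + K_d) + \eta_t}
#' with \eqn{\eta_t} i.i.d. Gaussian, zero mean, standard deviation
#' \code{params@noiseSd}. With \code{noiseSd = 0} the output is the bare
#' saturation curve, which lies in \[0, 1) and is monotone in the
#' concentration. Noise is not clipped, so noisy values may leave \[0, 1\].
#'
#' @param trace a [CalciumTrace-class]
#' @param params a [CaParams-class]; \code{params@seed} seeds the noise
#' @param positions optional neuron coordinates carried into the movie
#' @return a [FluorescenceMovie-class]
#' @export
fluorescence <- function(trace, params = CaParams(),
                         positions = matrix(numeric(), 0, 2)) {
  stopifnot(is(trace, "CalciumTrace"), is(params, "CaParams"))
  ca <- trace@calcium
  if (any(ca < 0)) stop("negative calcium concentration")
  F <- ca / (ca + params@kD)
  if (params@noiseSd > 0) {
    set.seed(params@seed)
    F <- F + matrix(stats::rnorm(length(F), 0, params@noiseSd),
                    nrow(F), ncol(F))
  }
  FluorescenceMovie(F, frameDt = trace@frameDt, positions = positions)
}

#' Apply light scattering to a fluorescence movie
#'
#' Adds Gaussian-kernel cross-talk between neurons:
#' \deqn{F^{sc}_{i,t} = F_{i,t} + A_{sc} \sum_{j \neq i} F_{j,t}
#'   \exp\{-(d_{ij}/\lambda_{sc})^2\}}
#' The input movie is left unmodified; a new movie flagged as scattered is
#' returned. With \code{sp@aSc = 0} the output equals the input.
#'
#' @param movie a [FluorescenceMovie-class]
#' @param topo a [NetworkTopology-class] supplying the pairwise distances
#' @param sp a [ScatterParams-class]
#' @return a new [FluorescenceMovie-class] with \code{scattered = TRUE}
#' @export
applyScattering <- function(movie, topo, sp = ScatterParams()) {
  stopifnot(is(movie, "FluorescenceMovie"), is(topo, "NetworkTopology"))
  n <- nNodes(movie)
  if (n != nNodes(topo))
    stop("movie and topology disagree on the number of neurons")
  K <- sp@aSc * exp(-(distances(topo) / sp@lambdaSc)^2)
  diag(K) <- 0
  Fsc <- movie@values + movie@values %*% K
  FluorescenceMovie(Fsc, frameDt = movie@frameDt,
                    positions = positions(topo), scattered = TRUE)
}

#' Read and write fluorescence movies and neuron positions
#'
#' The on-disk layout follows the connectomics-challenge convention:
#' the fluorescence file is comma-separated with one row per frame
#' (sampled every 20 ms) and one column per neuron, no header; the
#' position file has two comma-separated columns (X, Y) and one row per
#' neuron.
#'
#' @param movie a [FluorescenceMovie-class]
#' @param path file path
#' @param digits significant digits written
#' @return readers return a [FluorescenceMovie-class] or an n x 2 position
#'   matrix; writers return \code{path} invisibly
#' @export
writeFluorescence <- function(movie, path, digits = 8) {
  m <- signif(fluorValues(movie), digits)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @param frameDt sampling interval of the file (ms)
#' @rdname writeFluorescence
#' @export
readFluorescence <- function(path, frameDt = 20) {
  vals <- .readNumericGrid(path, what = "fluorescence")
  FluorescenceMovie(vals, frameDt = frameDt)
}

#' @param positions an n x 2 matrix of coordinates
#' @rdname writeFluorescence
#' @export
writePositions <- function(positions, path, digits = 8) {
  utils::write.table(signif(as.matrix(positions), digits), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFluorescence
#' @export
readPositions <- function(path) {
  pos <- .readNumericGrid(path, what = "positions")
  if (ncol(pos) != 2)
    stop("position file must have exactly two columns (X, Y)")
  pos
}

# strict delimited-numeric reader: uniform row length, numeric cells,
# parse errors report the offending line
.readNumericGrid <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ", what, " file: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  width <- length(cells[[1]])
  bad <- which(lengths(cells) != width)
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1], ": expected ",
         width, " cells, found ", length(cells[[bad[1]]]))
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    badCell <- which(is.na(vals))[1]
    stop("parse error in ", path, " at line ",
         (badCell - 1) %/% width + 1, ": non-numeric cell")
  }
  matrix(vals, nrow = length(cells), ncol = width, byrow = TRUE)
}

#' Export a movie as per-frame PNG images
#'
#' Renders each frame as a scatter of the node positions shaded by
#' intensity, using the common rendering path for neural fluorescence
#' movies and publication activity movies.
#'
#' @param movie a [FluorescenceMovie-class] or [ActivityMovie-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @param frames which frames to export (default all)
#' @param pointCex symbol size
#' @return invisibly, the vector of files written
#' @export
exportFrames <- function(movie, dir, prefix = "frame", frames = NULL,
                         pointCex = 2) {
  if (is(movie, "FluorescenceMovie")) {
    vals <- fluorValues(movie)
    pos <- positions(movie)
    if (nrow(pos) == 0) stop("movie carries no node positions")
  } else if (is(movie, "ActivityMovie")) {
    vals <- intensityMatrix(movie)
    pos <- as.matrix(nodeLayout(movie)[, c("x", "y")])
  } else stop("unsupported movie class")
  rng <- range(vals)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  if (is.null(frames)) frames <- seq_len(nrow(vals))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (f in frames) {
    shade <- (vals[f, ] - rng[1]) / diff(rng)
    file <- file.path(dir, sprintf("%s_%05d.png", prefix, f))
    grDevices::png(file, width = 320, height = 320)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(pos[, 1], pos[, 2], pch = 16, cex = pointCex,
                   col = grDevices::gray(pmin(1, pmax(0, shade))),
                   xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
                   xlab = "", ylab = "")
    grDevices::dev.off()
    files <- c(files, file)
  }
  invisible(files)
}
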