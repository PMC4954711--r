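#' Convert an activity frame to a signature
#'
#' Every node with positive intensity becomes a cluster at its position
#' with weight proportional to its intensity; weights are normalized to a
#' total of 1, the equal-total-weight condition under which the EMD with a
#' metric ground distance is itself a metric. When the frame has more
#' active nodes than \code{maxClusters}, nodes are aggregated onto a
#' coarser square grid (cluster center = weight-weighted mean position),
#' which conserves the total weight.
#'
#' An all-zero frame has no unit-mass signature; with
#' \code{baseline = TRUE} it is replaced by the uniform signature over all
#' node positions (the "no localized activity" reference), otherwise it is
#' an error.
#'
#' @param intensity numeric vector of node intensities (>= 0)
#' @param positions matrix of node coordinates, one row per node
#' @param maxClusters cap on the number of clusters (LP size)
#' @param baseline substitute the uniform signature for all-zero frames
#' @return a [Signature-class] with total weight 1
#' @export
frameToSignature <- function(intensity, positions, maxClusters = 256,
                             baseline = FALSE) {
  positions <- as.matrix(positions)
  if (length(intensity) != nrow(positions))
    stop("one intensity per position required")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  active <- which(intensity > 0)
  if (!length(active)) {
    if (!baseline)
      stop("all-zero frame has no signature; enable baseline substitution")
    return(uniformSignature(positions))
  }
  pts <- positions[active, , drop = FALSE]
  w <- intensity[active]
  if (length(active) > maxClusters) {
    g <- ceiling(sqrt(maxClusters))
    lim <- apply(positions, 2, range)
    cx <- pmin(g, 1L + floor((pts[, 1] - lim[1, 1]) /
                               max(1e-12, diff(lim[, 1])) * g))
    cy <- pmin(g, 1L + floor((pts[, 2] - lim[1, 2]) /
                               max(1e-12, diff(lim[, 2])) * g))
    cell <- (cy - 1L) * g + cx
    wSum <- tapply(w, cell, sum)
    xSum <- tapply(w * pts[, 1], cell, sum)
    ySum <- tapply(w * pts[, 2], cell, sum)
    pts <- cbind(xSum / wSum, ySum / wSum)
    w <- as.numeric(wSum)
  }
  Signature(pts, w, normalize = TRUE)
}

#' Uniform baseline signature over a set of node positions
#'
#' Equal weight on every node: the reference distribution representing
#' "no localized activity" against which per-frame EMD activity curves
#' are measured.
#'
#' @param positions matrix of node coordinates
#' @return a [Signature-class]
#' @export
uniformSignature <- function(positions) {
  positions <- as.matrix(positions)
  Signature(positions, rep(1, nrow(positions)), normalize = TRUE)
}

#' Earth Mover's Distance between two signatures
#'
#' Solves the transportation linear program
#' \deqn{\min_F \sum_{ij} d_{ij} f_{ij}} subject to \eqn{f_{ij} \ge 0},
#' row sums bounded by the weights of P, column sums bounded by the
#' weights of Q, and total flow equal to the smaller total weight; the
#' EMD is the optimal work normalized by the total flow. The ground
#' distance is the Euclidean distance between cluster centers. Unequal
#' total weights are handled by a zero-cost dummy cluster absorbing the
#' surplus, which realizes the inequality constraints exactly.
#'
#' @param P,Q [Signature-class] objects
#' @return list with \code{emd}, \code{work}, \code{totalFlow} and the
#'   optimal \code{flow} matrix (rows = clusters of P, dummy column/row
#'   dropped)
#' @examples
#' P <- Signature(rbind(c(0, 0)), 1)
#' Q <- Signature(rbind(c(0.3, 0.4)), 1)
#' emd(P, Q)$emd  # 0.5, the only feasible flow moves all mass
#' @export
emd <- function(P, Q) {
  stopifnot(is(P, "Signature"), is(Q, "Signature"))
  wp <- clusterWeights(P)
  wq <- clusterWeights(Q)
  sp <- sum(wp); sq <- sum(wq)
  m <- length(wp); n <- length(wq)
  D <- .crossDistances(clusterCenters(P), clusterCenters(Q))
  dummy <- abs(sp - sq) > 1e-12 * max(sp, sq)
  if (dummy) {
    if (sp > sq) {            # dummy sink for the surplus of P
      D <- cbind(D, 0)
      wq <- c(wq, sp - sq)
    } else {                  # dummy source for the surplus of Q
      D <- rbind(D, 0)
      wp <- c(wp, sq - sp)
    }
  }
  sol <- transport_simplex_cpp(wp, wq, D)
  flow <- sol$flow[seq_len(m), seq_len(n), drop = FALSE]
  work <- sum(D[seq_len(m), seq_len(n), drop = FALSE] * flow)
  totalFlow <- min(sp, sq)
  list(emd = work / totalFlow, work = work, totalFlow = totalFlow,
       flow = flow)
}

.crossDistances <- function(A, B) {
  # Euclidean distances between two point sets (m x 2, n x 2);
  # squared distances at rounding-noise level are exact-zero matches
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 1e-14] <- 0
  sqrt(d2)
}

.movieFrames <- function(movie) {
  if (is(movie, "FluorescenceMovie")) {
    pos <- positions(movie)
    if (nrow(pos) == 0) stop("movie carries no node positions")
    list(vals = fluorValues(movie), pos = pos)
  } else if (is(movie, "ActivityMovie")) {
    list(vals = intensityMatrix(movie),
         pos = as.matrix(nodeLayout(movie)[, c("x", "y")]))
  } else stop("unsupported movie class")
}

#' Per-frame EMD of a movie against a baseline signature
#'
#' Calibrates the movie by global min-max normalization (so both kinds of
#' movie show comparable shades), converts each frame to a signature and
#' computes its EMD to the baseline — by default the uniform signature
#' over the movie's node positions. Higher values mean activity
#' concentrated farther from the no-activity reference; the curve of a
#' movie identical to the baseline in every frame is zero.
#'
#' @param movie a [FluorescenceMovie-class] or [ActivityMovie-class]
#' @param baseline a [Signature-class]; default uniform over the node
#'   positions
#' @param maxClusters cluster cap per frame (see [frameToSignature()])
#' @return numeric vector with one EMD value per frame
#' @export
movieEMDCurve <- function(movie, baseline = NULL, maxClusters = 256) {
  mf <- .movieFrames(movie)
  vals <- mf$vals
  rng <- range(vals)
  vals <- if (diff(rng) == 0) matrix(0, nrow(vals), ncol(vals)) else
    (vals - rng[1]) / diff(rng)
  if (is.null(baseline)) baseline <- uniformSignature(mf$pos)
  vapply(seq_len(nrow(vals)), function(f) {
    sig <- frameToSignature(vals[f, ], mf$pos, maxClusters,
                            baseline = TRUE)
    emd(sig, baseline)$emd
  }, numeric(1))
}

#' Frame-by-frame EMD between two movies
#'
#' Computes the EMD for every aligned frame pair. The time scales of the
#' two movies generally differ (20 ms frames vs yearly frames), so the
#' alignment is never inferred silently: pass an explicit two-column
#' matrix of frame indices (rows = pairs), \code{"identity"} for movies
#' with equal frame counts, or \code{"peak"} to shift the movies so their
#' frames of maximum total activity coincide (overlapping frames only).
#'
#' @param A,B movies ([FluorescenceMovie-class] or [ActivityMovie-class])
#' @param alignment \code{"identity"}, \code{"peak"}, or a two-column
#'   integer matrix of (frame in A, frame in B) pairs
#' @param maxClusters cluster cap per frame
#' @return list with \code{series} (EMD per aligned pair),
#'   \code{alignment} (the index pairs used), \code{mean} and \code{min}
#' @export
compareMovies <- function(A, B, alignment, maxClusters = 256) {
  fa <- .movieFrames(A)
  fb <- .movieFrames(B)
  nA <- nrow(fa$vals); nB <- nrow(fb$vals)
  if (missing(alignment)) stop("an explicit frame alignment is required")
  if (is.character(alignment)) {
    alignment <- match.arg(alignment, c("identity", "peak"))
    if (alignment == "identity") {
      if (nA != nB)
        stop("identity alignment requires equal frame counts")
      pairs <- cbind(seq_len(nA), seq_len(nB))
    } else {
      pkA <- which.max(rowSums(fa$vals))
      pkB <- which.max(rowSums(fb$vals))
      off <- pkB - pkA
      ia <- seq_len(nA)
      ib <- ia + off
      keep <- ib >= 1 & ib <= nB
      if (!any(keep)) stop("peak alignment produced no overlapping frames")
      pairs <- cbind(ia[keep], ib[keep])
    }
  } else {
    pairs <- as.matrix(alignment)
    if (ncol(pairs) != 2 || nrow(pairs) == 0)
      stop("alignment must be a non-empty two-column matrix")
  }
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) matrix(0, nrow(v), ncol(v)) else
      (v - rng[1]) / diff(rng)
  }
  va <- norm01(fa$vals); vb <- norm01(fb$vals)
  series <- vapply(seq_len(nrow(pairs)), function(q) {
    sa <- frameToSignature(va[pairs[q, 1], ], fa$pos, maxClusters,
                           baseline = TRUE)
    sb <- frameToSignature(vb[pairs[q, 2], ], fb$pos, maxClusters,
                           baseline = TRUE)
    emd(sa, sb)$emd
  }, numeric(1))
  list(series = series, alignment = pairs, mean = mean(series),
       min = min(series))
}

#' Write a signature, an EMD curve, or plot a curve to PNG
#'
#' @param sig a [Signature-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSignature <- function(sig, path) {
  df <- data.frame(x = clusterCenters(sig)[, 1],
                   y = clusterCenters(sig)[, 2],
                   weight = clusterWeights(sig))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @param curve numeric EMD series
#' @param labels optional frame labels (defaults to indices)
#' @rdname writeSignature
#' @export
writeEMDCurve <- function(curve, path, labels = NULL) {
  if (is.null(labels)) labels <- seq_along(curve)
  utils::write.csv(data.frame(frame = labels, emd = curve), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
plotEMDCurve <- function(curve, path, labels = NULL) {
  if (is.null(labels)) labels <- seq_along(curve)
  grDevices::png(path, width = 640, height = 400)
  graphics::plot(seq_along(curve), curve, type = "l", xlab = "frame",
                 ylab = "EMD to baseline", xaxt = "n")
  at <- pretty(seq_along(curve))
  at <- at[at >= 1 & at <= length(curve)]
  graphics::axis(1, at = at, labels = labels[at])
  grDevices::dev.off()
  invisible(path)
}
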