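#' Discrete differencing of a fluorescence movie
#'
#' Isolates candidate spike events by first-order differencing of each
#' node's series: \eqn{x_n = F_{x,n+1} - F_{x,n}}, which suppresses the
#' slow calcium decay and improves the signal-to-noise ratio of the
#' subsequent probability estimates. The result has one row fewer than
#' the input.
#'
#' @param movie a [FluorescenceMovie-class] or a frames x nodes matrix
#' @return (frames - 1) x nodes matrix of differences
#' @export
differenceSeries <- function(movie) {
  vals <- if (is(movie, "FluorescenceMovie")) fluorValues(movie) else
    as.matrix(movie)
  if (nrow(vals) < 2)
    stop("differencing requires at least two frames")
  diff(vals)
}

#' Discretize a series into symbols
#'
#' Quantile mode places the bin edges at the empirical quantiles so the
#' bins hold near-equal mass; fixed mode uses the user-supplied edges.
#' Symbols are integers starting at 1. If the series has fewer distinct
#' quantile edges than requested, bins collapse and a warning reports the
#' effective number of symbols.
#'
#' @param x numeric series
#' @param params a [TEParams-class]
#' @return integer vector of symbols in \code{1:nBins}
#' @export
discretizeSeries <- function(x, params = TEParams()) {
  if (!all(is.finite(x))) stop("series must be finite")
  if (params@binMethod == "fixed") {
    return(findInterval(x, sort(params@edges)) + 1L)
  }
  probs <- seq_len(params@nBins - 1L) / params@nBins
  edges <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  if (length(edges) < params@nBins - 1L)
    warning("degenerate binning: only ", length(edges) + 1L,
            " distinct bins available")
  # right-closed bins match the quantile definition of near-equal mass
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' Transfer entropy between two symbol series
#'
#' Plug-in estimate of
#' \deqn{TE_{Y \to X} = \sum P(x_{n+1}, x_n^{(k)}, y_n^{(k)})
#'   \log \frac{P(x_{n+1} \mid x_n^{(k)}, y_n^{(k)})}
#'             {P(x_{n+1} \mid x_n^{(k)})}}
#' from the empirical joint frequencies of the order-k history vectors.
#' The sum runs over all observed states; terms with zero joint mass
#' contribute zero. No bias correction is applied, so short series
#' overestimate small TE values. Reported in bits for \code{base = 2}.
#'
#' @param x,y equal-length integer symbol series (see
#'   [discretizeSeries()]); \code{x} is the target, \code{y} the putative
#'   driver
#' @param params a [TEParams-class]
#' @return non-negative TE estimate
#' @seealso [transferEntropyExact()] for the closed-form evaluation from
#'   a known joint distribution
#' @export
transferEntropy <- function(x, y, params = TEParams()) {
  k <- params@k
  N <- length(x)
  if (length(y) != N) stop("series must have equal length")
  if (N <= k + 1) stop("series too short for order-", k, " histories")
  idx <- k:(N - 1)
  xp <- x[idx + 1]
  hx <- rep(0L, length(idx))
  hy <- rep(0L, length(idx))
  B <- max(x, y)
  for (i in 0:(k - 1)) {
    hx <- hx * B + (x[idx - i] - 1L)
    hy <- hy * B + (y[idx - i] - 1L)
  }
  M <- length(xp)

  key3 <- paste(xp, hx, hy)
  keyHxy <- paste(hx, hy)
  keyXpHx <- paste(xp, hx)
  keyHx <- as.character(hx)
  n3 <- table(key3)
  nHxy <- table(keyHxy)
  nXpHx <- table(keyXpHx)
  nHx <- table(keyHx)

  u <- !duplicated(key3)
  c3 <- as.numeric(n3[key3[u]])
  cHxy <- as.numeric(nHxy[keyHxy[u]])
  cXpHx <- as.numeric(nXpHx[keyXpHx[u]])
  cHx <- as.numeric(nHx[keyHx[u]])
  te <- sum(c3 / M * log((c3 * cHx) / (cHxy * cXpHx))) / log(params@base)
  max(0, te)
}

#' Transfer entropy from an exact joint distribution
#'
#' Evaluates the TE sum in closed form from a known joint probability
#' array \code{p[a, b, c] = P(x_{n+1} = a, x_n^{(k)} = b, y_n^{(k)} = c)}
#' (histories encoded as single states). By the Kullback-Leibler
#' non-negativity the result is >= 0, and it is exactly 0 when the
#' one-node and two-node transition matrices coincide, i.e. when
#' \eqn{P(x_{n+1} \mid x_n^{(k)}, y_n^{(k)}) = P(x_{n+1} \mid x_n^{(k)})}
#' for every state.
#'
#' @param p 3-dimensional non-negative array summing to 1
#' @param base logarithm base (2 reports bits)
#' @return the exact TE value
#' @export
transferEntropyExact <- function(p, base = 2) {
  p <- as.array(p)
  if (length(dim(p)) != 3) stop("p must be a 3-d array [x+, x, y]")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability distribution")
  pHxy <- apply(p, c(2, 3), sum)    # P(x_n, y_n)
  pXpHx <- apply(p, c(1, 2), sum)   # P(x_{n+1}, x_n)
  pHx <- apply(p, 2, sum)           # P(x_n)
  te <- 0
  d <- dim(p)
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    pj <- p[a, b, cc]
    if (pj <= 0) next
    te <- te + pj * log((pj * pHx[b]) / (pHxy[b, cc] * pXpHx[a, b]))
  }
  te / log(base)
}

#' Pairwise transfer-entropy matrix of a movie
#'
#' Differences each node's fluorescence series, discretizes it, and
#' estimates \eqn{TE_{Y \to X}} for every ordered node pair. Entry
#' \code{[y, x]} is the TE from driver y to target x; the diagonal is
#' \code{NA}.
#'
#' @param movie a [FluorescenceMovie-class] or frames x nodes matrix
#' @param params a [TEParams-class]
#' @return n x n matrix of TE estimates with \code{NA} diagonal
#' @export
transferEntropyMatrix <- function(movie, params = TEParams()) {
  d <- differenceSeries(movie)
  n <- ncol(d)
  sym <- lapply(seq_len(n), function(i) discretizeSeries(d[, i], params))
  out <- matrix(NA_real_, n, n)
  for (yi in seq_len(n)) for (xi in seq_len(n)) {
    if (xi == yi) next
    out[yi, xi] <- transferEntropy(sym[[xi]], sym[[yi]], params)
  }
  cn <- colnames(if (is(movie, "FluorescenceMovie")) fluorValues(movie)
                 else movie)
  if (!is.null(cn)) dimnames(out) <- list(cn, cn)
  out
}

#' Write a transfer-entropy matrix, optionally as a thresholded edge list
#'
#' @param te n x n TE matrix from [transferEntropyMatrix()]
#' @param path output TSV path
#' @param threshold if given, additionally writes
#'   \code{paste0(path, ".edges")} with rows \code{(from, to, te)} for all
#'   entries >= threshold
#' @return \code{path}, invisibly
#' @export
writeTEMatrix <- function(te, path, threshold = NULL) {
  utils::write.table(te, path, sep = "\t", row.names = TRUE,
                     col.names = NA, quote = FALSE)
  if (!is.null(threshold)) {
    idx <- which(!is.na(te) & te >= threshold, arr.ind = TRUE)
    lab <- if (is.null(rownames(te))) as.character(seq_len(nrow(te))) else
      rownames(te)
    edges <- data.frame(from = lab[idx[, 1]], to = lab[idx[, 2]],
                        te = te[idx])
    utils::write.table(edges, paste0(path, ".edges"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
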