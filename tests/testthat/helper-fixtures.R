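# small fixtures and independent oracles shared across test files

# two-neuron dish at a fixed distance
twoNeuronTopo <- function(d = 0.15) {
  NetworkTopology(matrix(0, 2, 2), rbind(c(0.2, 0.5), c(0.2 + d, 0.5)))
}

# hand-built records (already-parsed form)
makeRecord <- function(id, year, keywords) {
  list(id = id, year = year, keywords = keywords, dialect = "medline")
}

# independent EMD oracle: dense-simplex LP (boot) on the balanced
# transportation problem, with the redundant last equality dropped
emdOracle <- function(P, Q) {
  wp <- clusterWeights(P); wq <- clusterWeights(Q)
  m <- length(wp); n <- length(wq)
  A <- clusterCenters(P); B <- clusterCenters(Q)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D <- sqrt(pmax(d2, 0))
  # one-cluster cases are forced: all mass crosses the single distance
  if (m == 1) return(sum(wq / sum(wq) * D[1, ]))
  if (n == 1) return(sum(wp / sum(wp) * D[, 1]))
  A3 <- matrix(0, m + n - 1, m * n)
  for (i in 1:m) for (j in 1:n) {
    A3[i, (j - 1) * m + i] <- 1
    if (j < n) A3[m + j, (j - 1) * m + i] <- 1
  }
  sol <- boot::simplex(a = as.vector(D), A3 = A3,
                       b3 = c(wp, wq[-n]), maxi = FALSE)
  unname(sol$value) / min(sum(wp), sum(wq))
}

# independent TE oracle: literal nested-loop sum over all state triples
# of the conditional-probability ratio definition
teOracle <- function(p, base = 2) {
  d <- dim(p)
  pHx <- apply(p, 2, sum)
  pHxy <- apply(p, c(2, 3), sum)
  pXpHx <- apply(p, c(1, 2), sum)
  total <- 0
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (p[a, b, cc] <= 0) next
    condFull <- p[a, b, cc] / pHxy[b, cc]
    condMarg <- pXpHx[a, b] / pHx[b]
    total <- total + p[a, b, cc] * log(condFull / condMarg, base = base)
  }
  total
}

# random exact joint distribution over given state-space sizes
randomJoint <- function(nx, ny) {
  p <- array(stats::rexp(nx * nx * ny), c(nx, nx, ny))
  p / sum(p)
}

# joint distribution with P(x'|x,y) = P(x'|x): transition independent of y
nullJoint <- function(nx, ny) {
  trans <- matrix(stats::rexp(nx * nx), nx, nx)
  trans <- sweep(trans, 2, colSums(trans), "/")   # P(x'|x) column-wise
  marg <- matrix(stats::rexp(nx * ny), nx, ny)
  marg <- marg / sum(marg)                        # P(x, y)
  p <- array(0, c(nx, nx, ny))
  for (a in seq_len(nx)) for (b in seq_len(nx)) for (cc in seq_len(ny))
    p[a, b, cc] <- trans[a, b] * marg[b, cc]
  p
}

# random small signature in the unit square
randomSignature <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Signature(matrix(stats::runif(2 * m), m, 2), stats::runif(m) + 0.05)
}
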