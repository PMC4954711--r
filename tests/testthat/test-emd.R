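test_that("EMD basics: identity, single-cluster distance, normalization", {
  P <- randomSignature(4, seed = 1)
  expect_lt(emd(P, P)$emd, 1e-9)

  # single unit clusters: the only feasible flow moves all mass over d
  A <- Signature(rbind(c(0.1, 0.1)), 1)
  B <- Signature(rbind(c(0.4, 0.5)), 1)
  expect_equal(emd(A, B)$emd, 0.5)

  # weights normalize to 1
  S <- Signature(rbind(c(0, 0), c(1, 1)), c(1, 3))
  expect_equal(clusterWeights(S), c(0.25, 0.75))
  expect_error(Signature(rbind(c(0, 0)), 0), "positive weight")
})

test_that("transportation simplex agrees with an independent LP solver", {
  # >= 100 random instances with m, n <= 5 against the dense simplex
  set.seed(2)
  worst <- 0
  for (q in 1:120) {
    P <- randomSignature(sample(1:5, 1))
    Q <- randomSignature(sample(1:5, 1))
    worst <- max(worst, abs(emd(P, Q)$emd - emdOracle(P, Q)))
  }
  expect_lt(worst, 1e-9)
})

test_that("flow solutions satisfy the transportation constraints", {
  set.seed(3)
  for (q in 1:25) {
    P <- randomSignature(sample(2:6, 1))
    Q <- randomSignature(sample(2:6, 1))
    sol <- emd(P, Q)
    f <- sol$flow
    expect_true(all(f >= -1e-12))
    expect_true(all(rowSums(f) <= clusterWeights(P) + 1e-9))
    expect_true(all(colSums(f) <= clusterWeights(Q) + 1e-9))
    expect_equal(sum(f), min(sum(clusterWeights(P)),
                             sum(clusterWeights(Q))), tolerance = 1e-9)
  }
})

test_that("EMD on equal-weight signatures is a metric", {
  set.seed(4)
  for (q in 1:100) {
    A <- randomSignature(sample(2:4, 1))
    B <- randomSignature(sample(2:4, 1))
    C <- randomSignature(sample(2:4, 1))
    ab <- emd(A, B)$emd; ba <- emd(B, A)$emd
    ac <- emd(A, C)$emd; cb <- emd(C, B)$emd
    expect_gte(ab, 0)
    expect_equal(ab, ba, tolerance = 1e-9)          # symmetry
    expect_lte(ab, ac + cb + 1e-9)                  # triangle inequality
  }
  # identity of indiscernibles
  A <- randomSignature(3, seed = 5)
  expect_lt(emd(A, A)$emd, 1e-9)
})

test_that("EMD is invariant under joint rigid translation", {
  set.seed(6)
  for (q in 1:10) {
    A <- randomSignature(3)
    B <- randomSignature(4)
    shift <- runif(2, -2, 2)
    A2 <- Signature(sweep(clusterCenters(A), 2, shift, "+"),
                    clusterWeights(A), normalize = FALSE)
    B2 <- Signature(sweep(clusterCenters(B), 2, shift, "+"),
                    clusterWeights(B), normalize = FALSE)
    expect_equal(emd(A2, B2)$emd, emd(A, B)$emd, tolerance = 1e-9)
  }
})

test_that("unequal totals are handled by the minimum-flow convention", {
  A <- Signature(rbind(c(0, 0)), 1, normalize = FALSE)
  B <- Signature(rbind(c(1, 0), c(3, 0)), c(1, 1), normalize = FALSE)
  sol <- emd(A, B)
  # all of A's single unit goes to the nearest cluster: work 1, flow 1
  expect_equal(sol$totalFlow, 1)
  expect_equal(sol$emd, 1)
})

test_that("frames become signatures with intensity-proportional weights", {
  pos <- generatePositions(4, seed = 7)
  sig <- frameToSignature(c(1, 3, 0, 0), pos)
  expect_equal(nrow(clusterCenters(sig)), 2L)
  expect_equal(clusterWeights(sig), c(0.25, 0.75))
  expect_equal(clusterCenters(sig), pos[1:2, ], ignore_attr = TRUE)

  expect_error(frameToSignature(c(0, 0, 0, 0), pos), "all-zero")
  base <- frameToSignature(c(0, 0, 0, 0), pos, baseline = TRUE)
  expect_equal(clusterWeights(base), rep(0.25, 4))

  # aggregation conserves total weight and caps the cluster count
  pos1k <- generatePositions(1000, seed = 8)
  set.seed(8)
  sigBig <- frameToSignature(runif(1000), pos1k, maxClusters = 100)
  expect_lte(nrow(clusterCenters(sigBig)), 100L)
  expect_equal(sum(clusterWeights(sigBig)), 1)
})

test_that("EMD curves flag the burst frame and vanish at baseline", {
  pos <- generatePositions(30, seed = 2)
  # movie equal to the uniform baseline in every frame
  flat <- FluorescenceMovie(matrix(0.4, 6, 30), positions = pos)
  expect_equal(movieEMDCurve(flat), rep(0, 6))

  # single planted burst: curve maximum at the burst frame, every seed
  for (sd in 1:5) {
    set.seed(sd)
    burstFrame <- sample(2:19, 1)
    vals <- matrix(0.02, 20, 30)
    vals[burstFrame, sample(30, 5)] <- 1
    curve <- movieEMDCurve(FluorescenceMovie(vals, positions = pos))
    expect_equal(which.max(curve), burstFrame)
  }
})

test_that("movie comparison needs an explicit alignment and finds zeros", {
  pos <- generatePositions(12, seed = 3)
  set.seed(3)
  vals <- matrix(runif(60), 5, 12)
  mv <- FluorescenceMovie(vals, positions = pos)
  expect_error(compareMovies(mv, mv), "alignment")

  selfCmp <- compareMovies(mv, mv, "identity")
  expect_equal(selfCmp$series, rep(0, 5), tolerance = 1e-9)

  # frame-shuffled copy with the matching permutation alignment
  perm <- sample(5)
  shuffled <- FluorescenceMovie(vals[perm, ], positions = pos)
  cmp <- compareMovies(mv, shuffled, cbind(perm, seq_len(5)))
  expect_equal(cmp$series, rep(0, 5), tolerance = 1e-9)

  # peak alignment on a shifted copy of a bursty movie
  bursty <- matrix(0.01, 10, 12); bursty[7, ] <- 1
  shifted <- rbind(bursty[3:10, ], bursty[1:2, ])   # peak moves to frame 5
  pk <- compareMovies(FluorescenceMovie(bursty, positions = pos),
                      FluorescenceMovie(shifted, positions = pos), "peak")
  expect_equal(pk$series, rep(0, nrow(pk$alignment)), tolerance = 1e-9)

  # neuron-style vs publication-style movie: finite non-negative series
  recs <- lapply(1:5, function(y)
    makeRecord(paste0("r", y), 1999 + y,
               sample(letters[1:6], 2)))
  am <- buildActivityMovie(countByYear(recs), letters[1:6],
                           generatePositions(12, 5), seed = 4)
  cross <- compareMovies(mv, am, "identity")
  expect_true(all(is.finite(cross$series)))
  expect_true(all(cross$series >= 0))
  expect_equal(cross$mean, mean(cross$series))
})

test_that("signatures and EMD curves serialize", {
  sig <- randomSignature(3, seed = 9)
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeSignature(sig, sp)
  df <- read.delim(sp)
  expect_equal(df$weight, clusterWeights(sig))

  cp <- withr::local_tempfile(fileext = ".csv")
  writeEMDCurve(c(0.1, 0.3), cp, labels = c(1990, 1991))
  expect_equal(read.csv(cp)$emd, c(0.1, 0.3))

  pp <- withr::local_tempfile(fileext = ".png")
  plotEMDCurve(c(0.1, 0.3, 0.2), pp)
  expect_true(file.exists(pp))
})
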