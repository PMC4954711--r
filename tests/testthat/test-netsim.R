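test_that("topology generation honors size, determinism and degeneracy", {
  # two neurons with target degree 1: the only possible edges are the two
  # off-diagonal ones, and the density correction drives both to p = 1
  topo2 <- generateTopology(2, meanDegree = 1, seed = 1)
  expect_equal(adjacency(topo2), rbind(c(0, 1), c(1, 0)))

  expect_error(generateTopology(1), "at least 2")
  expect_error(generateTopology(10, meanDegree = 20), "meanDegree")

  t1 <- generateTopology(40, seed = 9)
  t2 <- generateTopology(40, seed = 9)
  expect_identical(adjacency(t1), adjacency(t2))
  expect_identical(positions(t1), positions(t2))
  expect_true(all(positions(t1) >= 0 & positions(t1) <= 1))
  expect_true(all(diag(adjacency(t1)) == 0))
  expect_gte(componentCount(t1), 1L)
})

test_that("distance-dependent wiring clusters more than a uniform graph", {
  topo <- generateTopology(100, seed = 5)
  ccLocal <- clusteringCoefficient(topo)
  nEdges <- sum(adjacency(topo) > 0 | t(adjacency(topo)) > 0) / 2
  set.seed(5)
  er <- igraph::sample_gnm(100, nEdges)
  ccER <- igraph::transitivity(er, type = "average", isolates = "zero")
  expect_gt(ccLocal, ccER)
})

test_that("membrane leak follows the closed-form exponential decay", {
  # zero input: V(t) = V(0) exp(-t / tau_m); per-term exponential update
  # reproduces it for any step size
  topo <- twoNeuronTopo()
  for (dt in c(0.5, 0.1, 0.05)) {
    p <- SimParams(dt = dt, alphaExt = 0, extRate = 0)
    st <- initialState(2)
    st$state$V <- c(10, 5)
    nSteps <- round(20 / dt)
    for (s in seq_len(nSteps)) {
      res <- stepNetwork(st$state, st$syn, topo, p)
      st$state <- res$state; st$syn <- res$syn
    }
    expect_equal(st$state$V, c(10, 5) * exp(-1), tolerance = 1e-9)
  }
})

test_that("a presynaptic spike moves fraction U of the recovered pool", {
  topo <- twoNeuronTopo()
  p <- SimParams(alphaExt = 0, extRate = 0)
  st <- initialState(2)
  st$state$V <- c(25, 0)   # above threshold: neuron 1 fires this step
  res <- stepNetwork(st$state, st$syn, topo, p)
  expect_equal(res$spiked, 1L)
  expect_equal(res$syn$E[1, ], c(0.3, 0.3))   # E jumps to U * R = 0.3
  expect_equal(res$syn$R[1, ], c(0.7, 0.7))
  expect_equal(res$state$V[1], 0)             # reset
  # refractory: V stays clamped at zero on the next steps
  st2 <- res
  for (s in 1:10) {
    st2 <- stepNetwork(st2$state, st2$syn, topo, p)
  }
  expect_equal(st2$state$V[1], 0)
})

test_that("coarse integration tracks a fine-step reference trajectory", {
  # one external arrival drives a two-neuron net; dt = 0.1 ms trajectory
  # must stay close to the dt = 0.01 ms reference at the shared times
  topo <- NetworkTopology(rbind(c(0, 1), c(0, 0)),
                          rbind(c(0.2, 0.5), c(0.6, 0.5)))
  run <- function(dt) {
    p <- SimParams(dt = dt, alphaInt = 300, alphaExt = 12,
                   extRate = 0, duration = 0.1)
    st <- initialState(2)
    nSteps <- round(60 / dt)
    extStep <- round(1 / dt)          # arrival at t = 1 ms
    out <- matrix(0, 60, 2)
    for (s in seq_len(nSteps)) {
      arr <- list(recurrent = integer(),
                  external = if (s == extStep) 1L else integer())
      res <- stepNetwork(st$state, st$syn, topo, p, arr)
      st$state <- res$state; st$syn <- res$syn
      if (s %% round(1 / dt) == 0) out[s / round(1 / dt), ] <- st$state$V
    }
    out
  }
  coarse <- run(0.1)
  fine <- run(0.01)
  expect_true(any(fine > 1))   # trajectory is non-trivial
  # holding I_syn over a step makes the coupling first-order accurate:
  # error scale ~ V_peak * dt / tau_s ~ 19 mV * 0.1 / 2 ~ 1 mV bound
  expect_lt(max(abs(coarse - fine)), 0.5)
})

test_that("simulation is silent without drive and deterministic with it", {
  topo <- generateTopology(10, meanDegree = 4, seed = 2)
  quiet <- simulateNetwork(topo, SimParams(alphaInt = 0, alphaExt = 0,
                                           extRate = 0, duration = 2))
  expect_equal(sum(lengths(spikeTimes(quiet))), 0L)

  p <- SimParams(alphaInt = 15, duration = 3, seed = 31)
  r1 <- simulateNetwork(topo, p)
  r2 <- simulateNetwork(topo, p)
  expect_identical(spikeTimes(r1), spikeTimes(r2))
})

test_that("compiled loop and R reference stepper produce identical dynamics", {
  set.seed(3)
  topo <- generateTopology(5, meanDegree = 3, seed = 3)
  p <- SimParams(alphaInt = 20, alphaExt = 15, extRate = 50,
                 duration = 0.2, dt = 0.1, seed = 9)
  r <- simulateNetwork(topo, p, recordState = TRUE, recordEvery = 1L)
  tr <- attr(r, "stateTrace")
  dSteps <- round(p@tD / p@dt)
  nSteps <- round(p@duration * 1000 / p@dt)
  pendSpk <- vector("list", nSteps + dSteps + 1)
  pendExt <- vector("list", nSteps + dSteps + 1)
  for (i in seq_along(r@external)) for (tt in r@external[[i]]) {
    s <- round(tt / p@dt) + dSteps
    if (s <= nSteps + dSteps) pendExt[[s + 1]] <- c(pendExt[[s + 1]], i)
  }
  st <- initialState(5)
  RV <- RI <- matrix(0, nSteps, 5)
  spikesR <- rep(0L, 5)
  for (s in seq_len(nSteps)) {
    res <- stepNetwork(st$state, st$syn, topo, p,
                       arrivals = list(recurrent = pendSpk[[s + 1]],
                                       external = pendExt[[s + 1]]))
    st$state <- res$state; st$syn <- res$syn
    spikesR[res$spiked] <- spikesR[res$spiked] + 1L
    if (length(res$spiked))
      pendSpk[[s + dSteps + 1]] <- c(pendSpk[[s + dSteps + 1]], res$spiked)
    RV[s, ] <- st$state$V
    RI[s, ] <- st$state$Isyn
  }
  expect_equal(RV, tr$V[2:(nSteps + 1), ], tolerance = 1e-12)
  expect_equal(RI, tr$Isyn[2:(nSteps + 1), ], tolerance = 1e-12)
  expect_equal(spikesR, lengths(spikeTimes(r)))
})

test_that("synaptic resource fractions conserve E + R + I = 1 in [0, 1]", {
  topo <- generateTopology(20, meanDegree = 8, seed = 4)
  r <- simulateNetwork(topo, SimParams(alphaInt = 15, duration = 5,
                                       seed = 8),
                       recordState = TRUE, recordEvery = 50L)
  tr <- attr(r, "stateTrace")
  expect_true(all(tr$E >= 0 & tr$E <= 1))
  expect_true(all(tr$R >= 0 & tr$R <= 1))
  inact <- 1 - tr$E - tr$R   # I is the remainder: conservation is exact
  expect_true(all(inact >= -1e-12 & inact <= 1))
})

test_that("no inter-spike interval violates the refractory period", {
  topo <- generateTopology(30, meanDegree = 10, seed = 6)
  r <- simulateNetwork(topo, SimParams(alphaInt = 16, duration = 10,
                                       seed = 12))
  p <- SimParams()
  for (s in spikeTimes(r)) {
    if (length(s) > 1) expect_gte(min(diff(s)), p@tRef - 1e-9)
  }
  expect_gt(sum(lengths(spikeTimes(r))), 0)
})

test_that("mean spike count is non-decreasing in the recurrent weight", {
  topo <- generateTopology(50, meanDegree = 12, seed = 21)
  meanCount <- function(alpha) {
    mean(vapply(1:5, function(sd) {
      r <- simulateNetwork(topo, SimParams(alphaInt = alpha, duration = 5,
                                           seed = 100 + sd))
      sum(lengths(spikeTimes(r)))
    }, numeric(1)))
  }
  counts <- vapply(c(2, 8, 14), meanCount, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("burst detection counts planted synchronous events", {
  # empty raster
  empty <- SpikeRaster(rep(list(numeric()), 10), duration = 10000)
  expect_equal(detectBursts(empty)$rate, 0)

  # one synchronous event among 100 neurons in a 10 s run: 0.1 Hz
  one <- SpikeRaster(rep(list(1000), 100), duration = 10000)
  b <- detectBursts(one)
  expect_equal(b$count, 1L)
  expect_equal(b$rate, 0.1)

  # 20 planted events in 200 s at full participation
  ev <- seq(5000, 195000, length.out = 20)
  raster <- generateBurstRaster(100, rate = 0.1, duration = 200,
                                seed = 3, eventTimes = ev)
  b20 <- detectBursts(raster)
  expect_equal(b20$count, 20L)
  expect_equal(b20$rate, 0.1)
})

test_that("calibration brackets with +/-10% steps then interpolates", {
  topo <- generateTopology(5, meanDegree = 2, seed = 1)
  p <- SimParams(alphaInt = 5, seed = 1)

  # linear rate oracle: rate(alpha) = alpha / 50, target at alpha = 5
  cal <- calibrateBursting(topo, p, target = 0.1, tolerance = 0.01,
                           rateFun = function(a, i) a / 50)
  expect_true(cal$converged)
  expect_equal(cal$iterations, 1L)        # 5 / 50 = 0.1: stop immediately
  expect_equal(cal$alphaInt, 5)

  # off-target start: bracket then secant onto the linear oracle
  p2 <- SimParams(alphaInt = 2, seed = 1)
  cal2 <- calibrateBursting(topo, p2, target = 0.1, tolerance = 0.001,
                            rateFun = function(a, i) a / 50)
  expect_true(cal2$converged)
  expect_lt(abs(cal2$alphaInt - 5), 0.05)
  # phase 1 increases by exactly 10% while the rate is too low
  expect_equal(cal2$history$alphaInt[2], 2 * 1.1)

  # rate above target: the first correction is a 10% decrease
  rates <- c(0.2, 0.15, 0.11, 0.095)
  k <- 0
  cal3 <- calibrateBursting(topo, p, target = 0.1, tolerance = 0.01,
                            rateFun = function(a, i) {
                              k <<- k + 1
                              rates[min(k, length(rates))]
                            })
  expect_equal(cal3$history$alphaInt[2], 4.5)

  # non-convergence carries the history in the error
  expect_error(
    calibrateBursting(topo, p, target = 0.1, tolerance = 1e-9,
                      maxIter = 5L, rateFun = function(a, i) 0.5),
    "did not bracket")
})

test_that("spike rasters and adjacency matrices round-trip through files", {
  raster <- generateBurstRaster(8, rate = 0.5, duration = 20, seed = 2,
                                participation = 0.8)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSpikeRaster(raster, path)
  back <- readSpikeRaster(path, n = 8, duration = 20000)
  expect_equal(spikeTimes(back), spikeTimes(raster), ignore_attr = TRUE)

  topo <- generateTopology(6, meanDegree = 2, seed = 3)
  dense <- withr::local_tempfile(fileext = ".csv")
  write.table(adjacency(topo), dense, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_equal(readAdjacency(dense, "dense"), adjacency(topo),
               ignore_attr = TRUE)

  el <- withr::local_tempfile(fileext = ".txt")
  idx <- which(adjacency(topo) == 1, arr.ind = TRUE)
  write.table(idx, el, row.names = FALSE, col.names = FALSE)
  expect_equal(readAdjacency(el, "edgelist", n = 6), adjacency(topo),
               ignore_attr = TRUE)
})

test_that("parameter validity is enforced", {
  expect_error(SimParams(dt = 3), "dt must satisfy")
  expect_error(SimParams(U = 0), "U must be")
  expect_error(SimParams(duration = -1), "duration")
  expect_error(BurstParams(fracThreshold = 1.5), "fracThreshold")
  expect_error(NetworkTopology(matrix(1, 2, 2), matrix(0.5, 2, 2)),
               "self-edges")
})
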