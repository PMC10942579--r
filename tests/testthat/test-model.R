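test_that("shifted Hill function matches direct substitution", {
  expect_equal(shiftedHill(0, 200, 2, 2), 1)
  expect_equal(shiftedHill(200, 200, 2, 0), 0.5)
  expect_equal(shiftedHill(200, 200, 2, 2), 1.5)
  # range bounds for activation and inhibition
  x <- seq(0, 1e4, length.out = 50)
  expect_true(all(shiftedHill(x, 200, 5, 2) >= 1 & shiftedHill(x, 200, 5, 2) <= 2))
  expect_true(all(shiftedHill(x, 200, 2, 0) >= 0 & shiftedHill(x, 200, 2, 0) <= 1))
  expect_error(shiftedHill(1, 0, 2, 2), "X0")
  expect_error(shiftedHill(1, 200, 0.5, 2), "coefficient")
})

test_that("activated VEGFR signal is the quasi-steady complex level", {
  p <- modelParameters()
  expect_equal(activatedVegfr(1e4, 0, p), 0)
  expect_equal(activatedVegfr(1e4, 100, p), 250)   # 2.5e-5 * 1e4 * 100 / 0.1
  expect_equal(activatedVegfr(1e4, 10, p), 25)     # straddles V0 = 80 across 10 -> 100
})

test_that("default parameters reproduce the published simulation values", {
  p <- modelParameters()
  expect_equal(p@production, c(N0 = 1200, D0 = 1000, J0 = 800, VR0 = 1000))
  expect_equal(p@degradation, c(gamma = 0.1, gammaI = 0.5))
  expect_equal(p@binding, c(kT = 2.5e-5, kC = 5e-4, kTV = 2.5e-5))
  expect_equal(p@thresholds, c(I0 = 200, V0 = 80))
  expect_equal(p@foldChange, c(N = 2, D = 0, VR = 0, J = 2, V = 2))
  expect_equal(p@hillCoef, c(N = 2, D = 2, VR = 2, J = 5, V = 2))
  expect_error(modelParameters(gamma = -1), "> 0")
  expect_error(updateParameter(p, "bogus", 1), "unknown parameter")
})

test_that("cell derivatives implement the circuit equations", {
  p <- modelParameters()
  zero <- c(N = 0, D = 0, J = 0, I = 0, VR = 0)
  nb0 <- c(N = 0, D = 0, J = 0)
  expect_equal(cellDerivatives(zero, nb0, 0, p),
               c(N = 1200, D = 1000, J = 800, I = 0, VR = 1000))
  # NICD production: kT * N * (Dext + Jext) = 2.5e-5 * 1000 * 400 = 10
  st <- c(N = 1000, D = 0, J = 0, I = 123, VR = 0)
  d <- cellDerivatives(st, c(N = 0, D = 300, J = 100), 0, p)
  expect_equal(d[["I"]], 10 - 0.5 * 123)
  expect_error(cellDerivatives(c(N = NA, D = 0, J = 0, I = 0, VR = 0), nb0, 0, p), "NA")
  expect_error(cellDerivatives(zero - 1, nb0, 0, p), "non-negative")
})

test_that("an isolated cell without cis-inhibition reaches its closed-form steady state", {
  # production/degradation balance: X* = X0 / gamma, I* = 0
  g <- cellGraph(rbind(c(0, 0), c(10, 0)), matrix(integer(0), 0L, 2L))
  p <- modelParameters(kC = 0)
  cfg <- simulationConfig(vExt = 0, convergenceTol = 1e-6, seed = 4L,
                          initRanges = rbind(rep(0, 5), rep(500, 5)))
  res <- equilibrate(g, initializeLattice(g, cfg), cfg, p)
  expect_true(res$converged)
  expected <- c(N = 12000, D = 10000, J = 8000, I = 0, VR = 10000)
  for (s in c("N", "D", "J", "VR")) {
    expect_equal(res$states[, s], rep(expected[[s]], 2L), tolerance = 1e-6)
  }
  expect_true(all(abs(res$states[, "I"]) < 1e-3))
})

test_that("lattice initialisation is reproducible and respects its bounds", {
  lat <- buildHexLattice(6, 6)
  cfg <- simulationConfig(seed = 9L)
  a <- initializeLattice(lat, cfg)
  b <- initializeLattice(lat, cfg)
  expect_identical(a, b)
  r <- cfg@initRanges
  for (k in 1:5) {
    expect_true(all(a[, k] >= r[1L, k] & a[, k] <= r[2L, k]))
  }
  zeroCfg <- simulationConfig(initRanges = matrix(0, 2L, 5L))
  expect_true(all(initializeLattice(lat, zeroCfg) == 0))
  badR <- rbind(rep(1, 5), rep(0, 5))
  expect_error(simulationConfig(initRanges = badR), "exceed")
})

test_that("the lattice field equations are permutation equivariant", {
  lat <- buildHexLattice(4, 6)
  n <- nCells(lat)
  set.seed(21)
  perm <- sample.int(n)
  inv <- integer(n); inv[perm] <- seq_len(n)
  permLat <- cellGraph(centroids(lat)[perm, ],
                       cbind(inv[cellEdges(lat)[, 1L]], inv[cellEdges(lat)[, 2L]]),
                       periodic = TRUE, box = lat@box)
  cfg <- simulationConfig(vExt = 100, seed = 2L)
  st <- initializeLattice(lat, cfg)
  pe1 <- angiopattern:::.rhsParms(lat, modelParameters(), 100)
  pe2 <- angiopattern:::.rhsParms(permLat, modelParameters(), 100)
  f1 <- matrix(angiopattern:::.latticeRHS(0, as.vector(st), pe1)[[1L]], ncol = 5L)
  f2 <- matrix(angiopattern:::.latticeRHS(0, as.vector(st[perm, ]), pe2)[[1L]], ncol = 5L)
  expect_equal(f2, f1[perm, ], tolerance = 1e-12)
  # short-time integration preserves the equivalence
  y1 <- angiopattern:::.integrateChunk(as.vector(st), c(0, 5), pe1)
  y2 <- angiopattern:::.integrateChunk(as.vector(st[perm, ]), c(0, 5), pe2)
  expect_equal(matrix(y2, ncol = 5L), matrix(y1, ncol = 5L)[perm, ], tolerance = 1e-4)
})

test_that("two coupled cells break symmetry into Tip and Stalk states", {
  g <- cellGraph(rbind(c(0, 0), c(1, 0)), rbind(c(1L, 2L)))
  cfg <- simulationConfig(vExt = 0, seed = 5L)
  res <- equilibrate(g, initializeLattice(g, cfg), cfg)
  d <- sort(res$states[, "D"])
  expect_lt(d[1L], 1000)   # one low-Delta (Stalk) cell
  expect_gt(d[2L], 1000)   # one high-Delta (Tip) cell
  n <- res$states[order(res$states[, "D"]), "N"]
  expect_gt(n[1L], n[2L])  # Delta-low cell is NOTCH-high
})

test_that("equilibrated lattices are non-negative with a converged residual", {
  lat <- buildHexLattice(6, 6)
  cfg <- simulationConfig(vExt = 100, seed = 3L, tMax = 2000)
  res <- equilibrate(lat, initializeLattice(lat, cfg), cfg)
  expect_true(res$converged)
  expect_lt(res$residual, cfg@convergenceTol)
  expect_true(all(res$states > -1e-6))
  # residual really is the max derivative at the reported states
  pe <- angiopattern:::.rhsParms(lat, modelParameters(), 100)
  expect_equal(max(abs(angiopattern:::.latticeRHS(0, as.vector(res$states), pe)[[1L]])),
               res$residual, tolerance = 1e-8)
})

test_that("equilibrated Delta distributions at high VEGF are bimodal", {
  lat <- buildHexLattice(10, 10)
  cfg <- simulationConfig(vExt = 100, seed = 31L, nReplicates = 3L)
  runs <- suppressWarnings(simulateEnsemble(lat, cfg))
  d <- unlist(lapply(runs, function(r) r$states[, "D"]))
  # a wide empty valley separates the Stalk and Tip modes
  expect_gt(sum(d < 300), 0L)
  expect_gt(sum(d > 3000), 0L)
  expect_equal(sum(d >= 300 & d <= 3000), 0L)
})

test_that("lattice states write to delimited tables with a JSON manifest and read back", {
  lat <- buildHexLattice(4, 4)
  cfg <- simulationConfig(vExt = 10, seed = 8L, nReplicates = 1L)
  run <- suppressWarnings(simulateLattice(lat, cfg, seed = 8L))
  f <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".json")
  writeLatticeStates(run$states, lat, f, manifestFile = mf, run = run,
                     params = modelParameters(), config = cfg)
  back <- readLatticeStates(f)
  expect_equal(back, run$states, tolerance = 1e-12)
  man <- jsonlite::read_json(mf)
  expect_equal(man$seed, 8L)
  expect_equal(man$parameters$thresholds$V0, 80)
  expect_equal(man$config$vExt, 10)
})
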