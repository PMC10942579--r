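# Synthetic-data generators with known ground truth for every analysis stage:
# phenotype patterns, fate time series, fibronectin maps and irregular cell
# graphs. All generators are deterministic given their seed.

#' Perfect salt-and-pepper pattern
#'
#' The ordered lateral-inhibition arrangement on the hexagonal lattice: Tips
#' on the even-row/even-column sublattice, so that every Tip is surrounded by
#' six Stalk cells, the Tip fraction is exactly 1/4, and the hop distance from
#' any Tip to its closest Tip is exactly 1. Requires even dimensions for the
#' tiling (and the periodic seam) to close.
#'
#' @param rows,cols even lattice dimensions.
#' @param periodic build on a torus (default `TRUE`).
#' @return a [PhenotypePattern-class].
#' @examples
#' tipFraction(perfectSaltPepper(30, 30))  # exactly 0.25
#' @export
perfectSaltPepper <- function(rows, cols, periodic = TRUE) {
  if (rows %% 2L != 0L || cols %% 2L != 0L) {
    stop("rows and cols must both be even for the alternating tiling")
  }
  lat <- buildHexLattice(rows, cols, periodic)
  row0 <- (seq_len(rows * cols) - 1L) %/% cols
  col0 <- (seq_len(rows * cols) - 1L) %% cols
  phenotypePattern(lat, row0 %% 2L == 0L & col0 %% 2L == 0L)
}

#' Disordered Tip-Stalk pattern with tunable Tip-Tip adjacency
#'
#' Gibbs-style sampler over patterns with a fixed number of Tips
#' (`round(tipFraction * nCells)`, so the realised fraction is within one cell
#' of the target). The energy is `adjacencyBias` times the number of Tip-Tip
#' adjacent pairs; Metropolis swap moves (one Tip with one Stalk) are run with
#' the bias annealed linearly from 0 to its full value. `adjacencyBias = 0`
#' yields i.i.d. Tip placement (every subset equally likely), for which the
#' probability that a Tip has at least one Tip neighbor follows the binomial
#' closed form `1 - (1 - f)^6`; large biases approach the ordered
#' salt-and-pepper limit (disorder index near 0 at `tipFraction <= 0.25`).
#'
#' @param rows,cols lattice dimensions (rows even when `periodic`).
#' @param tipFraction target Tip fraction in (0, 1).
#' @param adjacencyBias repulsion strength, >= 0.
#' @param seed RNG seed.
#' @param periodic build on a torus (default `TRUE`).
#' @param sweeps Metropolis sweeps (proposals per cell).
#' @return a [PhenotypePattern-class].
#' @export
disorderedPattern <- function(rows, cols, tipFraction, adjacencyBias = 0,
                              seed = 1L, periodic = TRUE, sweeps = 120L) {
  if (tipFraction <= 0 || tipFraction >= 1) stop("tipFraction must be in (0, 1)")
  if (adjacencyBias < 0) stop("adjacencyBias must be >= 0")
  lat <- buildHexLattice(rows, cols, periodic)
  n <- nCells(lat)
  nTip <- round(tipFraction * n)
  if (nTip < 1L || nTip >= n) stop("unattainable tipFraction for this lattice size")
  set.seed(seed)
  isTip <- logical(n)
  isTip[sample.int(n, nTip)] <- TRUE
  if (adjacencyBias > 0) {
    nb <- neighborList(lat)
    nIter <- as.integer(sweeps) * n
    tips <- which(isTip)
    stalks <- which(!isTip)
    biasLadder <- adjacencyBias * seq_len(nIter) / nIter
    ti <- sample.int(nTip, nIter, replace = TRUE)
    si <- sample.int(n - nTip, nIter, replace = TRUE)
    u <- runif(nIter)
    for (it in seq_len(nIter)) {
      t <- tips[ti[it]]
      s <- stalks[si[it]]
      nbT <- nb[[t]]
      nbS <- nb[[s]]
      dE <- sum(isTip[nbS]) - any(nbS == t) - sum(isTip[nbT])
      if (dE <= 0 || u[it] < exp(-biasLadder[it] * dE)) {
        isTip[t] <- FALSE
        isTip[s] <- TRUE
        tips[ti[it]] <- s
        stalks[si[it]] <- t
      }
    }
  }
  phenotypePattern(lat, isTip)
}

#' Simulate per-cell fate trajectories with an absorbing Sprout state
#'
#' Markov chain per cell over the states Stalk, MiniSprout, Sprout. Every cell
#' starts as Stalk (before the first observation); at each observation a Stalk
#' cell extends into a mini-sprout with probability `pExtend` (the same
#' probability governs first extension and re-extension after retraction); a
#' MiniSprout maintains, commits to the absorbing Sprout state, or retracts to
#' Stalk with probabilities `(pMaintain, pSprout, pRetract)` (must sum to 1);
#' a Sprout stays a Sprout. The returned cohort is filtered to cells that were
#' MiniSprout at least once, matching the tracking protocol.
#'
#' @param nCells number of cells to simulate (before cohort filtering).
#' @param timePoints observation times in hours.
#' @param pMaintain,pSprout,pRetract MiniSprout outcome probabilities.
#' @param pExtend Stalk to MiniSprout probability per observation step.
#' @param seed RNG seed.
#' @return a [FateSeries-class] containing the cohort.
#' @export
simulateFateSeries <- function(nCells, timePoints = c(1, 3, 7, 28),
                               pMaintain, pSprout, pRetract,
                               pExtend = 0.3, seed = 1L) {
  if (abs(pMaintain + pSprout + pRetract - 1) > 1e-9 ||
      any(c(pMaintain, pSprout, pRetract, pExtend) < 0) ||
      any(c(pMaintain, pSprout, pRetract, pExtend) > 1)) {
    stop("(pMaintain, pSprout, pRetract) must be a probability simplex")
  }
  set.seed(seed)
  nT <- length(timePoints)
  st <- matrix("Stalk", nCells, nT)
  prev <- rep("Stalk", nCells)
  for (j in seq_len(nT)) {
    u <- runif(nCells)
    cur <- prev
    stalk <- prev == "Stalk"
    cur[stalk & u < pExtend] <- "MiniSprout"
    mini <- prev == "MiniSprout"
    cur[mini & u < pSprout] <- "Sprout"
    cur[mini & u >= pSprout & u < pSprout + pRetract] <- "Stalk"
    cur[mini & u >= pSprout + pRetract] <- "MiniSprout"
    st[, j] <- cur
    prev <- cur
  }
  cohort <- rowSums(st == "MiniSprout") > 0L
  fateSeries(st[cohort, , drop = FALSE], timePoints = timePoints,
             cellIds = as.character(which(cohort)))
}

#' Synthetic tracked mini-sprout cohort
#'
#' A deterministic synthetic state table of 118 cells over the 1, 3, 7, 28 hr
#' observation schedule, constructed so that its counting statistics emulate
#' the dynamics of VEGF-stimulated (100 ng/ml) vessel tracking: mini-sprout to
#' sprout conversion in 13.6%, 2.9% and 7.5% of mini-sprouts over the three
#' intervals (9/66, 1/34, 3/40), final state fractions of 45.8% retracted,
#' 41.5% mini-sprout and 12.7% sprout (54/49/15 of 118), and 86.7% (13/15) of
#' sprouts arising from newly formed mini-sprouts, the remaining two forming
#' directly from the Stalk state. This is a synthetic stand-in, not measured
#' data: individual trajectories are exchangeable within their summary
#' classes.
#'
#' @return a [FateSeries-class] of 118 cells x 4 time points.
#' @export
syntheticTrackingCohort <- function() {
  S <- "Stalk"; M <- "MiniSprout"; P <- "Sprout"
  blocks <- list(
    list(n = 9L,  states = c(M, P, P, P)),   # convert in interval 1 (newly formed)
    list(n = 1L,  states = c(S, M, P, P)),   # convert in interval 2 (newly formed)
    list(n = 3L,  states = c(S, S, M, P)),   # convert in interval 3 (newly formed)
    list(n = 2L,  states = c(M, S, S, P)),   # direct Stalk->Sprout at the end
    list(n = 16L, states = c(M, M, M, M)),   # persistent mini-sprouts
    list(n = 28L, states = c(M, S, S, S)),   # early retraction
    list(n = 11L, states = c(M, M, S, S)),   # retraction after maintaining
    list(n = 6L,  states = c(S, M, M, M)),   # late extension, maintained
    list(n = 15L, states = c(S, S, M, S)),   # transient mid-course extension
    list(n = 27L, states = c(S, S, S, M))    # extension at the last time point
  )
  st <- do.call(rbind, lapply(blocks, function(b) {
    matrix(b$states, nrow = b$n, ncol = 4L, byrow = TRUE)
  }))
  fateSeries(st, timePoints = c(1, 3, 7, 28))
}

#' Simulate a fibronectin intensity map with label-dependent levels
#'
#' Per-cell lognormal intensities with label-dependent location: a cell with
#' label l gets `labelMeans[l] * exp(sdlog * Z - sdlog^2 / 2)` with
#' `sdlog = labelSds[l]` and standard normal Z, so the expected intensity
#' equals the label mean exactly and zero SDs reproduce the means exactly.
#' Intensities are non-negative by construction.
#'
#' @param graph a [CellGraph-class].
#' @param labels per-cell activity labels (see [intensityMap()]).
#' @param labelMeans,labelSds named vectors over the label levels; `labelSds`
#'   on the log scale, >= 0.
#' @param seed RNG seed.
#' @return an [IntensityMap-class].
#' @export
simulateIntensityMap <- function(graph, labels,
                                 labelMeans = c(SproutLeading = 25,
                                                SproutFollowing = 55,
                                                MiniSprout = 18,
                                                Quiescent = 22),
                                 labelSds = c(SproutLeading = 0.3,
                                              SproutFollowing = 0.3,
                                              MiniSprout = 0.3,
                                              Quiescent = 0.3),
                                 seed = 1L) {
  if (any(labelSds < 0)) stop("labelSds must be >= 0")
  lv <- c("SproutLeading", "SproutFollowing", "MiniSprout", "Quiescent")
  labels <- factor(as.character(labels), levels = lv)
  set.seed(seed)
  m <- labelMeans[as.character(labels)]
  s <- labelSds[as.character(labels)]
  z <- stats::rnorm(length(labels))
  intensityMap(graph, pmax(m * exp(s * z - s^2 / 2), 0), labels)
}

#' Jittered irregular cell graph
#'
#' A synthetic stand-in for experimentally segmented cell maps: hexagonal
#' centroids perturbed by independent uniform jitter in each coordinate, with
#' adjacency from the Gabriel graph (an edge is kept if no third centroid lies
#' inside the circle having the edge as diameter). The Gabriel criterion is a
#' Delaunay-like proximity rule that excludes corner/point contacts, restores
#' the exact hexagonal adjacency at zero jitter, and always yields a connected
#' graph (it contains the Euclidean minimum spanning tree).
#'
#' @param rows,cols lattice dimensions of the template.
#' @param jitter uniform perturbation half-width, < 0.5 center-to-center
#'   units.
#' @param seed RNG seed.
#' @return a planar [CellGraph-class].
#' @export
jitteredGraph <- function(rows, cols, jitter = 0.1, seed = 1L) {
  if (jitter >= 0.5) stop("jitter must be < 0.5")
  lat <- buildHexLattice(rows, cols, periodic = FALSE)
  n <- nCells(lat)
  for (attempt in 1:5) {
    set.seed(seed + attempt - 1L)
    xy <- lat@centroids + matrix(runif(2L * n, -jitter, jitter), n, 2L)
    edges <- .gabrielEdges(xy)
    g <- cellGraph(xy, edges)
    comp <- igraph::components(.asIgraph(g))
    if (comp$no == 1L) return(g)
    warning("jittered graph disconnected; regenerating with a shifted seed")
  }
  stop("failed to generate a connected jittered graph")
}

# Gabriel graph edges among candidate pairs closer than `cutoff`
.gabrielEdges <- function(xy, cutoff = 2.5) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  cand <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    mx <- (xy[i, 1L] + xy[j, 1L]) / 2
    my <- (xy[i, 2L] + xy[j, 2L]) / 2
    r2 <- d2[i, j] / 4
    dd <- (xy[, 1L] - mx)^2 + (xy[, 2L] - my)^2
    dd[i] <- Inf; dd[j] <- Inf
    all(dd >= r2)
  }, logical(1L))
  cand[keep, , drop = FALSE]
}
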