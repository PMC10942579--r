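# Phenomenological models of sprout selection: which Tip cells commit to the
# Sprout state. Three alternatives are compared through their sprout-sprout
# spacing statistics: cell-autonomous (location-independent), repulsion (no
# two sprouts in contact) and random-uniform (greedy maximal dispersion).

.newSelection <- function(model, ids, target, seed) {
  new("SproutSelection", model = model, sproutIds = as.integer(ids),
      targetCount = as.integer(target), seed = as.integer(seed))
}

#' Cell-autonomous sprout selection
#'
#' Sprouts are chosen uniformly at random among Tip cells, independently of
#' the phenotype of their neighbors; Stalk cells are never selectable. This
#' model permits adjacent sprouts, its characteristic failure mode.
#'
#' @param pattern a [PhenotypePattern-class].
#' @param nSprouts number of sprouts to select (<= number of Tips).
#' @param seed RNG seed.
#' @return a [SproutSelection-class].
#' @export
selectCellAutonomous <- function(pattern, nSprouts, seed = 1L) {
  tips <- tipCells(pattern)
  nSprouts <- as.integer(nSprouts)
  if (nSprouts > length(tips)) stop("nSprouts exceeds the number of Tip cells")
  set.seed(seed)
  .newSelection("cell_autonomous", sample(tips, nSprouts), nSprouts, seed)
}

#' Repulsion sprout selection
#'
#' Sprouts cannot be in direct contact. Tips are drawn one at a time,
#' uniformly at random; a draw is promoted to the Sprout state only if it is
#' not adjacent to a previously selected sprout, otherwise it is rejected and
#' a new Tip is drawn. Iteration stops when the target count is reached or the
#' retry budget (`100 * nSprouts` rejections) is exhausted, in which case the
#' target is declared infeasible.
#'
#' @inheritParams selectCellAutonomous
#' @param maxRejections retry budget before declaring infeasibility.
#' @return a [SproutSelection-class] whose sprout set is an independent set of
#'   the adjacency graph.
#' @export
selectRepulsion <- function(pattern, nSprouts, seed = 1L,
                            maxRejections = 100L * as.integer(nSprouts)) {
  tips <- tipCells(pattern)
  nSprouts <- as.integer(nSprouts)
  if (nSprouts > length(tips)) stop("nSprouts exceeds the number of Tip cells")
  nb <- neighborList(pattern@graph)
  set.seed(seed)
  chosen <- integer(0L)
  blocked <- logical(nCells(pattern))   # adjacent to a chosen sprout
  rejections <- 0L
  while (length(chosen) < nSprouts) {
    avail <- setdiff(tips, chosen)
    if (length(avail) == 0L) {
      stop("repulsion selection infeasible: no admissible Tip cells remain")
    }
    cand <- if (length(avail) == 1L) avail else sample(avail, 1L)
    if (!blocked[cand]) {
      chosen <- c(chosen, cand)
      blocked[nb[[cand]]] <- TRUE
    } else {
      rejections <- rejections + 1L
      if (rejections > maxRejections) {
        stop(sprintf(
          "repulsion selection infeasible: retry budget (%d rejections) exhausted at %d of %d sprouts",
          maxRejections, length(chosen), nSprouts))
      }
    }
  }
  .newSelection("repulsion", chosen, nSprouts, seed)
}

#' Random-uniform (maximal dispersion) sprout selection
#'
#' Sprouts are selected to maximise their overall spread in the lattice
#' (greedy farthest-point sampling). The first sprout is a uniformly random
#' Tip; the second is the Tip farthest from it (hop distance); every
#' subsequent sprout is the Tip maximising the *minimum* hop distance to the
#' sprouts already selected, with ties broken first by the larger sum of
#' pairwise hop distances and then by the seeded RNG. Maximising the minimum
#' separation is what "maximal spread" requires: the raw sum of pairwise
#' distances is a degenerate objective on a torus (it is maximised by two
#' antipodal clumps of mutually adjacent sprouts), whereas farthest-point
#' sampling never places two sprouts in contact until the Tip set forces it,
#' reproducing the model's defining behavior. Distances inside the objective
#' are plain hop distances; shielding applies only to reported spacing
#' statistics.
#'
#' @inheritParams selectCellAutonomous
#' @return a [SproutSelection-class].
#' @export
selectRandomUniform <- function(pattern, nSprouts, seed = 1L) {
  tips <- tipCells(pattern)
  nSprouts <- as.integer(nSprouts)
  if (nSprouts > length(tips)) stop("nSprouts exceeds the number of Tip cells")
  set.seed(seed)
  if (nSprouts == 0L) return(.newSelection("random_uniform", integer(0L), 0L, seed))
  dm <- .hopDistanceMatrix(pattern@graph, tips, tips)
  dm[is.na(dm)] <- 0
  k <- length(tips)
  first <- sample.int(k, 1L)
  chosen <- first
  minD <- dm[first, ]                      # min distance to the chosen set
  sumD <- dm[first, ]                      # tie-break: total spread
  while (length(chosen) < nSprouts) {
    minD[chosen] <- -Inf
    best <- which(minD == max(minD))
    if (length(best) > 1L) {
      best <- best[sumD[best] == max(sumD[best])]
      if (length(best) > 1L) best <- sample(best, 1L)
    }
    chosen <- c(chosen, best)
    minD <- pmin(minD, dm[best, ])
    sumD <- sumD + dm[best, ]
  }
  .newSelection("random_uniform", tips[chosen], nSprouts, seed)
}

#' Select sprouts with a named model
#'
#' Dispatcher over [selectCellAutonomous()], [selectRepulsion()] and
#' [selectRandomUniform()].
#'
#' @inheritParams selectCellAutonomous
#' @param model one of `"cell_autonomous"`, `"repulsion"`, `"random_uniform"`.
#' @return a [SproutSelection-class].
#' @export
selectSprouts <- function(pattern, nSprouts,
                          model = c("cell_autonomous", "repulsion", "random_uniform"),
                          seed = 1L) {
  model <- match.arg(model)
  switch(model,
         cell_autonomous = selectCellAutonomous(pattern, nSprouts, seed),
         repulsion = selectRepulsion(pattern, nSprouts, seed),
         random_uniform = selectRandomUniform(pattern, nSprouts, seed))
}

#' Sprout-sprout spacing distribution
#'
#' Rank-1 (closest-neighbor) shielded hop-distance distribution over the
#' selected sprouts, computed with the same machinery as
#' [tipDistanceDistribution()] but restricted to the sprout set: only sprouts
#' act as shields.
#'
#' @param selection a [SproutSelection-class] with >= 2 sprouts.
#' @param pattern the [PhenotypePattern-class] the selection was made on.
#' @param seed tie-breaking RNG seed.
#' @return data.frame with columns `rank, distance, count, probability,
#'   nPairs` (rank 1 only).
#' @export
sproutSpacing <- function(selection, pattern, seed = NULL) {
  ids <- sproutIds(selection)
  if (length(ids) < 2L) stop("at least two sprouts are required")
  .shieldedDistanceDistribution(pattern@graph, ids, maxRank = 1L, seed = seed)
}

#' Mean closest-sprout distance versus sprout fraction
#'
#' For each sprout fraction, selects `round(fraction * nCells)` sprouts on
#' every supplied pattern with every seed, and averages the rank-1
#' sprout-sprout distance. Repulsion infeasibilities are reported per point
#' (`nFailed`), not silently dropped. Across fractions the mean distance is
#' non-increasing, and at matched fractions the model ordering is
#' random_uniform >= repulsion >= cell_autonomous.
#'
#' @param patterns list of [PhenotypePattern-class] objects (the ensemble).
#' @param model selection model name.
#' @param fractions sprout fractions in (0, 1] (of all cells).
#' @param seeds integer seeds; each seed is applied to each pattern.
#' @return data.frame with columns `fraction, model, meanDistance, nRuns,
#'   nFailed`.
#' @export
spacingVsFractionCurve <- function(patterns, model, fractions, seeds = 1:5) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  rows <- lapply(fractions, function(f) {
    dists <- c(); failed <- 0L
    for (pat in patterns) {
      nS <- max(2L, round(f * nCells(pat)))
      if (nS > length(tipCells(pat))) { failed <- failed + length(seeds); next }
      for (s in seeds) {
        sel <- tryCatch(selectSprouts(pat, nS, model, seed = s),
                        error = function(e) NULL)
        if (is.null(sel)) { failed <- failed + 1L; next }
        sp <- sproutSpacing(sel, pat, seed = s)
        dists <- c(dists, meanRankDistance(sp, 1L))
      }
    }
    data.frame(fraction = f, model = model,
               meanDistance = if (length(dists)) mean(dists, na.rm = TRUE) else NA_real_,
               nRuns = length(dists), nFailed = failed)
  })
  do.call(rbind, rows)
}
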