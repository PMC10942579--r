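# Order-disorder statistics of Tip-Stalk patterns: classification, Tip
# fraction, disorder index, pseudopotential landscapes, dose-response
# transition fits and shielded rank-k Tip-Tip hop-distance distributions.

#' Classify Tip and Stalk cells from equilibrated states
#'
#' At steady state the distribution of cellular Delta is bimodal for any VEGF
#' input, with a wide gap between the Delta-low (Stalk) and Delta-high (Tip)
#' populations; cells with more than `deltaThreshold` Delta molecules
#' (default 1000) are labeled Tip.
#'
#' @param states state matrix with a `D` column (from [equilibrate()]), or a
#'   numeric vector of per-cell Delta levels.
#' @param graph the [CellGraph-class] the cells live on.
#' @param deltaThreshold Tip classification threshold, molecules.
#' @return a [PhenotypePattern-class].
#' @export
classifyTips <- function(states, graph, deltaThreshold = 1000) {
  d <- if (is.matrix(states)) states[, "D"] else as.numeric(states)
  if (length(d) != nCells(graph)) stop("one Delta level per cell required")
  labels <- factor(ifelse(d > deltaThreshold, "Tip", "Stalk"),
                   levels = c("Stalk", "Tip"))
  new("PhenotypePattern", graph = graph, labels = labels)
}

#' Construct a PhenotypePattern from labels
#'
#' @param graph a [CellGraph-class].
#' @param labels character/factor of per-cell `"Tip"`/`"Stalk"` labels, or a
#'   logical vector (`TRUE` = Tip).
#' @return a [PhenotypePattern-class].
#' @export
phenotypePattern <- function(graph, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "Tip", "Stalk")
  labels <- factor(as.character(labels), levels = c("Stalk", "Tip"))
  new("PhenotypePattern", graph = graph, labels = labels)
}

#' Fraction of Tip cells
#'
#' @param pattern a [PhenotypePattern-class].
#' @return `|Tips| / |cells|`, in `[0, 1]`. A perfect salt-and-pepper pattern
#'   gives exactly 0.25.
#' @export
tipFraction <- function(pattern) {
  n <- nCells(pattern)
  if (n == 0L) stop("empty graph")
  length(tipCells(pattern)) / n
}

#' Disorder index of a Tip-Stalk pattern
#'
#' Quantifies deviation from the perfect alternating ("salt-and-pepper")
#' arrangement through Tip-Tip adjacency: the fraction of Tip cells that have
#' at least one adjacent Tip. It is 0 for a perfect pattern and 1 for an
#' all-Tip lattice. This is the package's default metric; pass a different
#' `metric` function (pattern -> scalar) to plug in another definition.
#'
#' @param pattern a [PhenotypePattern-class].
#' @param metric optional replacement metric function.
#' @return disorder index in `[0, 1]`; `NA` with a warning when the pattern
#'   has no Tips (undefined).
#' @export
disorderIndex <- function(pattern, metric = NULL) {
  if (!is.null(metric)) return(metric(pattern))
  tips <- tipCells(pattern)
  if (length(tips) == 0L) {
    warning("disorder index is undefined for a pattern with zero Tips")
    return(NA_real_)
  }
  counts <- .tipNeighborCounts(pattern)
  mean(counts >= 1L)
}

# number of adjacent Tips for every Tip cell
.tipNeighborCounts <- function(pattern) {
  tips <- tipCells(pattern)
  isTip <- pattern@labels == "Tip"
  e <- pattern@graph@edges
  n <- nCells(pattern)
  cnt <- tabulate(c(e[isTip[e[, 2L]], 1L], e[isTip[e[, 1L]], 2L]), nbins = n)
  cnt[tips]
}

#' Tip-Tip adjacency probabilities
#'
#' Fraction of Tip cells whose neighborhood contains at least k other Tips,
#' for k = 1, 2, 3. In the disordered regime at high VEGF these approach
#' (0.8, 0.4, 0.2); in a perfect salt-and-pepper pattern they are all 0.
#'
#' @param pattern a [PhenotypePattern-class] with at least one Tip.
#' @return named numeric `c(p1, p2, p3)`.
#' @export
adjacencyProbabilities <- function(pattern) {
  if (length(tipCells(pattern)) == 0L) stop("pattern has no Tips")
  counts <- .tipNeighborCounts(pattern)
  c(p1 = mean(counts >= 1L), p2 = mean(counts >= 2L), p3 = mean(counts >= 3L))
}

#' Pseudopotential landscape over (NOTCH, Delta)
#'
#' Minus the log of the normalised 2D histogram of pooled per-cell (N, D)
#' samples, shifted so the deepest basin sits at 0. Empty bins are reported as
#' `+Inf`. In the bimodal regime the landscape has exactly two finite basins,
#' the Tip (high D, low N) and Stalk (low D, high N) attractors.
#'
#' @param samples matrix/data.frame with columns `N` and `D`, pooled over
#'   cells and replicates.
#' @param bins number of bins per axis (>= 2).
#' @return numeric `bins x bins` matrix (rows = N bins, columns = D bins) with
#'   attributes `"nBreaks"` and `"dBreaks"`.
#' @export
pseudopotential <- function(samples, bins = 50L) {
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  N <- samples[, "N"]
  D <- samples[, "D"]
  nBreaks <- seq(min(N), max(N), length.out = bins + 1L)
  dBreaks <- seq(min(D), max(D), length.out = bins + 1L)
  # widen degenerate axes so single-valued input lands in one bin
  if (nBreaks[1L] == nBreaks[bins + 1L]) nBreaks <- nBreaks[1L] + seq(-0.5, 0.5, length.out = bins + 1L)
  if (dBreaks[1L] == dBreaks[bins + 1L]) dBreaks <- dBreaks[1L] + seq(-0.5, 0.5, length.out = bins + 1L)
  iN <- findInterval(N, nBreaks, rightmost.closed = TRUE, all.inside = TRUE)
  iD <- findInterval(D, dBreaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0, bins, bins)
  for (k in seq_along(iN)) h[iN[k], iD[k]] <- h[iN[k], iD[k]] + 1
  p <- h / sum(h)
  pot <- -log(p)
  pot[!is.finite(pot)] <- Inf
  pot <- pot - min(pot)
  attr(pot, "nBreaks") <- nBreaks
  attr(pot, "dBreaks") <- dBreaks
  pot
}

#' Count local minima of a (smoothed) pseudopotential
#'
#' Helper for basin counting: smooths the finite part of the landscape with a
#' 3 x 3 mean filter (treating empty bins as missing) and counts strict local
#' minima over 8-neighborhoods among finite bins.
#'
#' @param pot matrix from [pseudopotential()].
#' @return integer number of local minima.
#' @export
countBasins <- function(pot) {
  nr <- nrow(pot); nc <- ncol(pot)
  fin <- is.finite(pot)
  sm <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!fin[i, j]) next
      ii <- max(1L, i - 1L):min(nr, i + 1L)
      jj <- max(1L, j - 1L):min(nc, j + 1L)
      v <- pot[ii, jj]
      sm[i, j] <- mean(v[is.finite(v)])
    }
  }
  nMin <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(sm[i, j])) next
      ii <- max(1L, i - 1L):min(nr, i + 1L)
      jj <- max(1L, j - 1L):min(nc, j + 1L)
      v <- sm[ii, jj]
      v <- v[!is.na(v)]
      if (length(v) > 1L && sm[i, j] <= min(v) &&
          sum(v == min(v)) == 1L) nMin <- nMin + 1L
    }
  }
  nMin
}

# Shared engine: shielded rank-k hop-distance distributions over a set of
# focal cells (Tips, or Sprouts for sprout spacing). For every focal cell the
# other focal cells are ranked by hop distance with seeded random
# tie-breaking; pairs shielded by an intermediate focal cell are discarded
# from the histograms (rank assignment happens before shield filtering, as in
# the measurement protocol).
.shieldedDistanceDistribution <- function(graph, ids, maxRank, seed = NULL,
                                          shield = TRUE, radius = 0.5) {
  ids <- as.integer(ids)
  k <- length(ids)
  if (k < 2L) stop("at least two focal cells are required")
  if (k - 1L < maxRank) {
    warning(sprintf("only %d other focal cells; truncating ranks to %d",
                    k - 1L, k - 1L))
    maxRank <- k - 1L
  }
  if (!is.null(seed)) set.seed(seed)
  dm <- .hopDistanceMatrix(graph, ids, ids)
  recs <- vector("list", k)
  for (i in seq_len(k)) {
    d <- dm[i, -i]
    others <- ids[-i]
    ord <- order(d, runif(length(d)))           # random tie-breaking
    take <- ord[seq_len(maxRank)]
    keep <- rep(TRUE, maxRank)
    if (shield) {
      for (m in seq_len(maxRank)) {
        keep[m] <- !isShielded(graph, ids[i], others[take[m]], ids, radius)
      }
    }
    recs[[i]] <- data.frame(rank = seq_len(maxRank)[keep],
                            distance = d[take[keep]])
  }
  recs <- do.call(rbind, recs)
  out <- do.call(rbind, lapply(seq_len(maxRank), function(r) {
    dr <- recs$distance[recs$rank == r]
    if (length(dr) == 0L) {
      return(data.frame(rank = r, distance = NA_real_, count = 0L,
                        probability = NA_real_, nPairs = 0L))
    }
    tb <- table(dr)
    data.frame(rank = r, distance = as.numeric(names(tb)),
               count = as.integer(tb), probability = as.integer(tb) / sum(tb),
               nPairs = length(dr))
  }))
  rownames(out) <- NULL
  out
}

#' Shielded Tip-Tip hop-distance distributions by rank
#'
#' For every Tip cell, all other Tips are sorted by hop distance (random
#' tie-breaking: equidistant Tips are assigned their closest/second-closest
#' ranking at random), and the rank-1..`maxRank` distances are pooled over
#' Tips into per-rank histograms. A pair is discarded when an intermediate Tip
#' *shields* it (see [isShielded()]), matching the experimental measurement
#' protocol. In a perfect salt-and-pepper pattern the rank-1 distance is 1 for
#' every Tip; in the disordered regime adjacent Tips are frequent and the mean
#' rank-1 distance drops to about 0.5 cells.
#'
#' @param pattern a [PhenotypePattern-class].
#' @param maxRank deepest neighbor rank to report.
#' @param seed seed for the tie-breaking RNG (recorded; same seed, same
#'   histograms).
#' @param shield apply shield filtering (default `TRUE`).
#' @return data.frame with columns `rank, distance, count, probability,
#'   nPairs`; probabilities sum to 1 within each rank.
#' @export
tipDistanceDistribution <- function(pattern, maxRank = 3L, seed = NULL,
                                    shield = TRUE) {
  .shieldedDistanceDistribution(pattern@graph, tipCells(pattern),
                                as.integer(maxRank), seed, shield)
}

#' Mean distance at a given rank
#'
#' @param dist data.frame from [tipDistanceDistribution()] or
#'   [sproutSpacing()].
#' @param rank neighbor rank (default 1 = closest).
#' @return probability-weighted mean hop distance at that rank.
#' @export
meanRankDistance <- function(dist, rank = 1L) {
  d <- dist[dist$rank == rank & dist$count > 0L, ]
  if (nrow(d) == 0L) return(NA_real_)
  sum(d$distance * d$count) / sum(d$count)
}

#' Pool distance distributions across replicates
#'
#' Pools the per-rank counts of several distribution tables (e.g. one per
#' equilibrated replicate) into a single table, weighting every measured pair
#' equally.
#'
#' @param dists list of data.frames from [tipDistanceDistribution()].
#' @return pooled data.frame in the same format.
#' @export
poolDistanceDistributions <- function(dists) {
  all <- do.call(rbind, dists)
  all <- all[all$count > 0L, ]
  agg <- aggregate(count ~ rank + distance, data = all, FUN = sum)
  agg <- agg[order(agg$rank, agg$distance), ]
  nP <- tapply(agg$count, agg$rank, sum)
  agg$probability <- agg$count / as.numeric(nP[as.character(agg$rank)])
  agg$nPairs <- as.integer(nP[as.character(agg$rank)])
  rownames(agg) <- NULL
  agg[, c("rank", "distance", "count", "probability", "nPairs")]
}

#' Fit the order-disorder transition of a dose-response curve
#'
#' Takes a table of per-replicate Tip fractions across VEGF doses, averages
#' per dose, and on the log10-dose axis: (i) locates the transition zone as
#' the consecutive dose interval of maximal slope, (ii) fits straight lines
#' below, inside and above the zone, and (iii) reports the threshold as the
#' dose where the mean curve first crosses the midpoint between the low- and
#' high-dose plateaus (linear interpolation in log10 dose). A non-monotone
#' mean curve triggers a warning and the first crossing is used; a flat curve
#' (plateau separation below `minRise`) yields threshold `NA` with a warning.
#'
#' When comparing transitions across model-parameter values the midpoint of
#' each curve's *own* plateaus is not comparable (the plateau levels
#' themselves move with the parameter); pass a fixed `level` -- typically the
#' midpoint of a reference curve -- so that every curve's threshold is the
#' dose at which it crosses the same Tip fraction. [sweepParameter()] does
#' this automatically.
#'
#' @param doseFractionTable data.frame with columns `dose` and `tipFraction`
#'   (replicates as repeated dose rows), e.g. from [sweepVegf()].
#' @param minRise minimal plateau separation for a transition to be declared.
#' @param level optional fixed Tip-fraction level whose first crossing defines
#'   the threshold; default `NULL` uses the midpoint of the curve's plateaus.
#' @return a [TransitionFit-class].
#' @export
fitTransition <- function(doseFractionTable, minRise = 0.02, level = NULL) {
  tab <- doseFractionTable
  if (!all(c("dose", "tipFraction") %in% names(tab))) {
    stop("need columns dose and tipFraction")
  }
  mu <- aggregate(tipFraction ~ dose, data = tab, FUN = mean)
  mu <- mu[order(mu$dose), ]
  if (nrow(mu) < 4L) stop("need at least 4 dose points spanning both plateaus")
  if (any(mu$dose <= 0)) stop("doses must be positive (log10 axis)")
  lx <- log10(mu$dose)
  y <- mu$tipFraction
  lo <- y[1L]; hi <- y[length(y)]
  if (is.unsorted(y)) warning("mean dose-response curve is not monotone; using first midpoint crossing")
  if (abs(hi - lo) < minRise) {
    warning("no transition detected: dose-response curve is flat")
    return(new("TransitionFit", threshold = NA_real_, zone = c(NA_real_, NA_real_),
               plateaus = c(low = lo, high = hi),
               slopes = c(below = NA_real_, inside = NA_real_, above = NA_real_),
               residuals = c(below = NA_real_, inside = NA_real_, above = NA_real_)))
  }
  slopes <- diff(y) / diff(lx)
  zi <- which.max(abs(slopes))                  # maximal-slope interval
  zone <- c(mu$dose[zi], mu$dose[zi + 1L])
  mid <- if (is.null(level)) (lo + hi) / 2 else level
  cross <- which((y[-length(y)] - mid) * (y[-1L] - mid) <= 0 & y[-length(y)] != y[-1L])
  threshold <- if (length(cross) > 0L) {
    i <- cross[1L]
    10^(lx[i] + (mid - y[i]) * (lx[i + 1L] - lx[i]) / (y[i + 1L] - y[i]))
  } else NA_real_
  segFit <- function(idx) {
    if (length(idx) < 2L) return(c(NA_real_, NA_real_))
    f <- lm(y[idx] ~ lx[idx])
    c(coef(f)[2L], sqrt(mean(residuals(f)^2)))
  }
  below <- segFit(seq_len(zi))
  inside <- segFit(c(zi, zi + 1L))
  above <- segFit(seq(zi + 1L, length(y)))
  new("TransitionFit", threshold = threshold, zone = zone,
      plateaus = c(low = lo, high = hi),
      slopes = c(below = unname(below[1L]), inside = unname(inside[1L]),
                 above = unname(above[1L])),
      residuals = c(below = unname(below[2L]), inside = unname(inside[2L]),
                    above = unname(above[2L])))
}
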