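# Fibronectin neighborhood statistics: label-stratified intensity summaries
# and the seven-cell-group above-threshold ratio distributions that contrast
# the matrix environment around committed sprouts versus mini-sprouts.

#' Construct an IntensityMap
#'
#' @param graph a [CellGraph-class].
#' @param intensity per-cell mean fibronectin intensity, arbitrary units >= 0.
#' @param labels per-cell activity labels (`SproutLeading`, `SproutFollowing`,
#'   `MiniSprout`, `Quiescent`), character or factor.
#' @return an [IntensityMap-class].
#' @export
intensityMap <- function(graph, intensity, labels) {
  lv <- c("SproutLeading", "SproutFollowing", "MiniSprout", "Quiescent")
  labels <- factor(as.character(labels), levels = lv)
  new("IntensityMap", graph = graph, intensity = as.numeric(intensity),
      labels = labels)
}

#' Read an intensity map from a delimited table
#'
#' Expects columns `cell_id, x, y, intensity, label`; adjacency is built by
#' the caller-supplied function (default: none, an edgeless graph, sufficient
#' for [labelSummary()]).
#'
#' @param file path to a tab-separated table.
#' @param edges optional two-column matrix of adjacency pairs.
#' @return an [IntensityMap-class].
#' @export
readIntensityMap <- function(file, edges = matrix(integer(0), 0L, 2L)) {
  tab <- read.delim(file)
  tab <- tab[order(tab$cell_id), ]
  g <- cellGraph(cbind(tab$x, tab$y), edges)
  intensityMap(g, tab$intensity, tab$label)
}

#' Per-label fibronectin intensity summaries
#'
#' Box-and-whisker statistics (n, mean, median, quartiles, range) of the
#' per-cell intensity stratified by activity label. Classes that are requested
#' but empty are reported with `n = 0`, not dropped. No hypothesis testing is
#' performed.
#'
#' @param map an [IntensityMap-class].
#' @return data.frame with columns `label, n, mean, median, q1, q3, min, max`.
#' @export
labelSummary <- function(map) {
  out <- lapply(levels(map@labels), function(lv) {
    x <- map@intensity[map@labels == lv]
    if (length(x) == 0L) {
      return(data.frame(label = lv, n = 0L, mean = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                        max = NA_real_))
    }
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(label = lv, n = length(x), mean = mean(x), median = median(x),
               q1 = q[1L], q3 = q[2L], min = min(x), max = max(x))
  })
  do.call(rbind, out)
}

#' Build seven-cell neighborhood groups
#'
#' For every center (a sprout or mini-sprout cell), forms the group of `size`
#' cells consisting of the center plus its nearest cells by centroid distance,
#' searched among direct neighbors first and then neighbors-of-neighbors
#' (guaranteeing a connected neighborhood). The delineation is deterministic
#' given the map; supply a different `strategy` function
#' `(map, center, size) -> integer ids` to plug in another grouping rule.
#'
#' @param map an [IntensityMap-class].
#' @param centers integer ids of group centers.
#' @param size group size including the center (default 7).
#' @param strategy optional replacement grouping function.
#' @return list of groups, each `list(center =, members =)` with
#'   `length(members) == size`.
#' @export
buildGroups <- function(map, centers, size = 7L, strategy = NULL) {
  size <- as.integer(size)
  if (is.null(strategy)) strategy <- .nearestAdjacentGroup
  lapply(as.integer(centers), function(ct) {
    members <- strategy(map, ct, size)
    if (length(members) != size) {
      stop(sprintf("cell %d has an insufficient neighborhood for a group of %d",
                   ct, size))
    }
    list(center = ct, members = members)
  })
}

.nearestAdjacentGroup <- function(map, center, size) {
  g <- map@graph
  nb <- neighborList(g)
  ring1 <- nb[[center]]
  ring2 <- setdiff(unique(unlist(nb[ring1])), c(center, ring1))
  pool <- c(ring1, ring2)
  if (length(pool) < size - 1L) return(integer(0L))
  xy <- g@centroids
  d <- if (g@periodic) {
    dd <- sweep(xy[pool, , drop = FALSE], 2L, xy[center, ])
    dd <- cbind(.minImage(dd[, 1L], g@box[1L]), .minImage(dd[, 2L], g@box[2L]))
    sqrt(rowSums(dd^2))
  } else {
    sqrt((xy[pool, 1L] - xy[center, 1L])^2 + (xy[pool, 2L] - xy[center, 2L])^2)
  }
  # rings first (ring-1 cells listed before ring-2), distance within ring
  ringRank <- rep(c(1L, 2L), c(length(ring1), length(ring2)))
  ord <- order(ringRank, d, pool)
  c(center, pool[ord][seq_len(size - 1L)])
}

#' Fraction of group cells above an intensity threshold
#'
#' @param group one element of [buildGroups()] output.
#' @param map an [IntensityMap-class].
#' @param threshold intensity threshold (default 30, the minimum sprout
#'   intensity of the reference condition; see [fibronectinThreshold()]).
#' @return `count(intensity > threshold) / size`, in `[0, 1]`.
#' @export
ratioAboveThreshold <- function(group, map, threshold = 30) {
  mean(map@intensity[group$members] > threshold)
}

#' Derive the intensity threshold from the data
#'
#' `method = "fixed"` returns `value` (default 30). `method = "auto"` derives
#' the threshold as the minimum intensity among `SproutFollowing` cells, the
#' rule the default value comes from.
#'
#' @param map an [IntensityMap-class].
#' @param method `"fixed"` or `"auto"`.
#' @param value threshold used by the fixed method.
#' @return numeric threshold.
#' @export
fibronectinThreshold <- function(map, method = c("fixed", "auto"), value = 30) {
  method <- match.arg(method)
  if (method == "fixed") return(value)
  x <- map@intensity[map@labels == "SproutFollowing"]
  if (length(x) == 0L) stop("no SproutFollowing cells to derive the threshold from")
  min(x)
}

#' Above-threshold ratios for many groups
#'
#' Convenience wrapper: builds the groups and tabulates one ratio per center,
#' with the center's label attached so sprout-centered and mini-sprout-
#' centered distributions can be stratified or pooled (the pooled distribution
#' is the multiset union of the strata).
#'
#' @inheritParams buildGroups
#' @param threshold intensity threshold.
#' @return data.frame with columns `center, centerLabel, ratio`.
#' @export
groupRatios <- function(map, centers, threshold = 30, size = 7L) {
  groups <- buildGroups(map, centers, size)
  data.frame(
    center = vapply(groups, `[[`, integer(1L), "center"),
    centerLabel = as.character(map@labels[vapply(groups, `[[`, integer(1L), "center")]),
    ratio = vapply(groups, ratioAboveThreshold, numeric(1L), map = map,
                   threshold = threshold)
  )
}
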