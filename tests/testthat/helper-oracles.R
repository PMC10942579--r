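# Independent oracles used to validate the package's geometry primitives.
# These deliberately avoid igraph and the package's own vectorised code.

# plain breadth-first search over neighbor lists: edge-count distances from a
bfsDistanceOracle <- function(graph, a) {
  nb <- neighborList(graph)
  n <- nCells(graph)
  dist <- rep(NA_integer_, n)
  dist[a] <- 0L
  frontier <- a
  while (length(frontier) > 0L) {
    nxt <- integer(0L)
    for (v in frontier) {
      for (w in nb[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# dense point-sampling oracle for the shielding predicate: sample points along
# the (minimal-image) segment and test membership in any shield disk,
# considering 3x3 torus images of each shield when periodic
shieldSamplingOracle <- function(graph, a, b, tipSet, radius = 0.5,
                                 nSamples = 1e4) {
  xy <- centroids(graph)
  s0 <- xy[a, ]
  d <- xy[b, ] - s0
  if (graph@periodic) d <- d - round(d / graph@box) * graph@box
  tt <- seq(0, 1, length.out = nSamples)
  px <- s0[1L] + tt * d[1L]
  py <- s0[2L] + tt * d[2L]
  shields <- setdiff(tipSet, c(a, b))
  offs <- if (graph@periodic) {
    as.matrix(expand.grid(x = c(-1, 0, 1) * graph@box[1L],
                          y = c(-1, 0, 1) * graph@box[2L]))
  } else {
    matrix(0, 1L, 2L)
  }
  for (s in shields) {
    for (k in seq_len(nrow(offs))) {
      cx <- xy[s, 1L] + offs[k, 1L]
      cy <- xy[s, 2L] + offs[k, 2L]
      if (any((px - cx)^2 + (py - cy)^2 <= radius^2)) return(TRUE)
    }
  }
  FALSE
}

# a small Tip-Stalk pattern with a known number of Tips placed at given ids
patternWithTips <- function(graph, tipIds) {
  lab <- rep(FALSE, nCells(graph))
  lab[tipIds] <- TRUE
  phenotypePattern(graph, lab)
}
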