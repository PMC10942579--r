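# Hexagonal lattice and cell-graph geometry: adjacency, hop distances and the
# shielding (occlusion) predicate underlying all Tip-Tip spacing statistics.

.HEX_ROW_PITCH <- sqrt(3) / 2

#' Build a hexagonal cell lattice
#'
#' Constructs a `rows x cols` hexagonal lattice in the "odd-r" offset
#' convention (odd rows shifted right by half a cell), with unit
#' center-to-center spacing and deterministic row-major cell indexing
#' (`cell = (row - 1) * cols + col`). When `periodic`, opposite boundaries are
#' glued into a torus so that every cell has exactly six neighbors; this
#' requires an even number of rows for the hexagonal tiling to match across
#' the vertical seam.
#'
#' @param rows,cols lattice dimensions, both >= 2.
#' @param periodic wrap boundaries into a torus (default `TRUE`).
#' @return a [HexLattice-class].
#' @examples
#' lat <- buildHexLattice(4, 4)
#' nCells(lat)            # 16
#' nrow(cellEdges(lat))   # 48 = 3 * rows * cols
#' @export
buildHexLattice <- function(rows, cols, periodic = TRUE) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 2L || cols < 2L) {
    stop("rows and cols must both be >= 2")
  }
  if (periodic && rows %% 2L != 0L) {
    stop("periodic hex lattices require an even number of rows (seam mismatch)")
  }
  n <- rows * cols
  row0 <- rep(seq_len(rows) - 1L, each = cols)   # 0-based, row-major
  col0 <- rep(seq_len(cols) - 1L, times = rows)
  centroids <- cbind(
    x = col0 + 0.5 * (row0 %% 2L),
    y = row0 * .HEX_ROW_PITCH
  )

  # odd-r neighbor offsets depend on row parity
  offEven <- rbind(c(0L, -1L), c(0L, 1L), c(-1L, -1L), c(-1L, 0L), c(1L, -1L), c(1L, 0L))
  offOdd  <- rbind(c(0L, -1L), c(0L, 1L), c(-1L, 0L), c(-1L, 1L), c(1L, 0L), c(1L, 1L))

  edges <- vector("list", 6L)
  for (k in seq_len(6L)) {
    dr <- ifelse(row0 %% 2L == 0L, offEven[k, 1L], offOdd[k, 1L])
    dc <- ifelse(row0 %% 2L == 0L, offEven[k, 2L], offOdd[k, 2L])
    r2 <- row0 + dr
    c2 <- col0 + dc
    if (periodic) {
      r2 <- r2 %% rows
      c2 <- c2 %% cols
      keep <- rep(TRUE, n)
    } else {
      keep <- r2 >= 0L & r2 < rows & c2 >= 0L & c2 < cols
    }
    a <- which(keep)
    b <- (r2 * cols + c2 + 1L)[keep]
    edges[[k]] <- cbind(pmin(a, b), pmax(a, b))
  }
  edges <- unique(do.call(rbind, edges))
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]  # guards tiny periodic sizes
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  storage.mode(edges) <- "integer"

  new("HexLattice",
      centroids = centroids, edges = edges, periodic = periodic,
      box = if (periodic) c(cols, rows * .HEX_ROW_PITCH) else c(NA_real_, NA_real_),
      rows = rows, cols = cols, offset = "odd-r")
}

#' Construct a general cell-adjacency graph
#'
#' For irregular (experimentally derived) cell maps. Edges must reflect
#' positive shared-boundary contacts; corner (point) contacts are excluded by
#' convention and must not be passed in.
#'
#' @param centroids numeric n x 2 matrix of cell centers, in units of the mean
#'   neighbor center-to-center distance.
#' @param edges two-column matrix of undirected cell-id pairs (any order;
#'   duplicates and orientation are normalised).
#' @param periodic logical; set `TRUE` only with finite `box` periods.
#' @param box numeric torus periods `c(Lx, Ly)` when periodic.
#' @return a [CellGraph-class].
#' @export
cellGraph <- function(centroids, edges, periodic = FALSE, box = c(NA_real_, NA_real_)) {
  centroids <- as.matrix(centroids)
  colnames(centroids) <- c("x", "y")
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  new("CellGraph", centroids = centroids, edges = edges,
      periodic = periodic, box = as.numeric(box))
}

# igraph view of a CellGraph (torus is already encoded in the edge set)
.asIgraph <- function(graph) {
  g <- igraph::graph_from_edgelist(graph@edges, directed = FALSE)
  n <- nCells(graph)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Per-cell neighbor lists
#'
#' @param graph a [CellGraph-class].
#' @return list of integer neighbor-id vectors, one per cell.
#' @export
neighborList <- function(graph) {
  n <- nCells(graph)
  e <- graph@edges
  nb <- split(c(e[, 2L], e[, 1L]), factor(c(e[, 1L], e[, 2L]), levels = seq_len(n)))
  lapply(nb, as.integer)
}

#' Hop distance between two cells
#'
#' The hop distance is the number of *intermediate* cells on the shortest path
#' between two cells: adjacent cells are at hop distance 0, cells separated by
#' exactly one cell at hop distance 1, and so on (breadth-first shortest-path
#' edge count minus one). On periodic lattices the path may wrap around the
#' torus.
#'
#' @param graph a [CellGraph-class].
#' @param a,b distinct cell ids.
#' @return non-negative integer hop distance.
#' @examples
#' lat <- buildHexLattice(6, 6)
#' hopDistance(lat, 1, 2)  # adjacent: 0
#' @export
hopDistance <- function(graph, a, b) {
  n <- nCells(graph)
  a <- as.integer(a); b <- as.integer(b)
  if (is.na(a) || is.na(b) || a < 1L || a > n || b < 1L || b > n) {
    stop("cell id not found in graph")
  }
  if (a == b) stop("hop distance requires two distinct cells")
  d <- igraph::distances(.asIgraph(graph), v = a, to = b)[1L, 1L]
  if (!is.finite(d)) {
    stop(structure(
      class = c("angiopattern_disconnected", "error", "condition"),
      list(message = sprintf("cells %d and %d are not connected", a, b),
           call = sys.call(-1L))))
  }
  as.integer(d) - 1L
}

# Matrix of hop distances between two id sets (edge counts minus one);
# diagonal entries (same cell) are NA.
.hopDistanceMatrix <- function(graph, from, to = from) {
  d <- igraph::distances(.asIgraph(graph), v = from, to = to) - 1
  same <- outer(from, to, "==")
  d[same] <- NA_real_
  d
}

# displacement b - a under the minimal-image convention of a periodic box
.minImage <- function(d, box) {
  d - round(d / box) * box
}

# distances from points p (k x 2) to the segment s0 -> s1
.pointSegmentDistance <- function(p, s0, s1) {
  v <- s1 - s0
  vv <- sum(v * v)
  w <- cbind(p[, 1L] - s0[1L], p[, 2L] - s0[2L])
  tt <- if (vv > 0) pmin(1, pmax(0, (w[, 1L] * v[1L] + w[, 2L] * v[2L]) / vv)) else 0
  dx <- w[, 1L] - tt * v[1L]
  dy <- w[, 2L] - tt * v[2L]
  sqrt(dx * dx + dy * dy)
}

#' Shielding predicate for a Tip-Tip pair
#'
#' A pair of Tip cells is *shielded* when the straight segment between their
#' centroids intersects a disk of radius 0.5 (in center-to-center units)
#' centered on any other Tip cell: an intermediate Tip occludes the pair, and
#' the pair is then excluded from spacing statistics. The circular geometry
#' removes artifacts of the polygonal cell shape. Only Tip cells act as
#' shields. On periodic graphs the minimal-image segment is used and shield
#' candidates are checked over their 3 x 3 torus images.
#'
#' @param graph a [CellGraph-class].
#' @param a,b distinct cell ids, both in `tipSet`.
#' @param tipSet integer ids of all Tip cells (candidate shields).
#' @param radius shielding disk radius; default 0.5.
#' @return logical: `TRUE` if some other Tip shields the pair.
#' @export
isShielded <- function(graph, a, b, tipSet, radius = 0.5) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(a != b, a %in% tipSet, b %in% tipSet)
  shields <- setdiff(as.integer(tipSet), c(a, b))
  if (length(shields) == 0L) return(FALSE)
  xy <- graph@centroids
  s0 <- xy[a, ]
  if (graph@periodic) {
    s1 <- s0 + .minImage(xy[b, ] - s0, graph@box)
    off <- as.matrix(expand.grid(x = c(-1, 0, 1) * graph@box[1L],
                                 y = c(-1, 0, 1) * graph@box[2L]))
    p <- xy[shields, , drop = FALSE]
    p <- p[rep(seq_len(nrow(p)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = length(shields)), , drop = FALSE]
  } else {
    s1 <- xy[b, ]
    p <- xy[shields, , drop = FALSE]
  }
  any(.pointSegmentDistance(p, s0, s1) <= radius)
}

#' Write a CellGraph to two delimited text tables
#'
#' Serialises cells as `(id, x, y)` and edges as `(id_a, id_b)`, tab
#' separated. Coordinates are written with 17 significant digits so that
#' [readCellGraph()] round-trips exactly.
#'
#' @param graph a [CellGraph-class].
#' @param cellsFile,edgesFile output paths.
#' @return invisibly, the two paths.
#' @export
writeCellGraph <- function(graph, cellsFile, edgesFile) {
  cells <- data.frame(
    id = seq_len(nCells(graph)),
    x = sprintf("%.17g", graph@centroids[, 1L]),
    y = sprintf("%.17g", graph@centroids[, 2L])
  )
  write.table(cells, cellsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- data.frame(id_a = graph@edges[, 1L], id_b = graph@edges[, 2L])
  write.table(edges, edgesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cellsFile, edgesFile))
}

#' Read a CellGraph from two delimited text tables
#'
#' @param cellsFile,edgesFile paths written by [writeCellGraph()].
#' @param periodic,box torus metadata (not stored in the tables).
#' @return a [CellGraph-class].
#' @export
readCellGraph <- function(cellsFile, edgesFile, periodic = FALSE,
                          box = c(NA_real_, NA_real_)) {
  cells <- read.delim(cellsFile)
  cells <- cells[order(cells$id), ]
  edges <- read.delim(edgesFile)
  cellGraph(cbind(cells$x, cells$y), as.matrix(edges[, c("id_a", "id_b")]),
            periodic = periodic, box = box)
}
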