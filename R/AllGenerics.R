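#' Number of cells in a graph-backed object
#'
#' @param x a [CellGraph-class], [PhenotypePattern-class] or
#'   [IntensityMap-class].
#' @return integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell centroid coordinates
#'
#' @param x a graph-backed object.
#' @return numeric n x 2 matrix, in units of the mean neighbor
#'   center-to-center distance.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Undirected edge list
#'
#' @param x a graph-backed object.
#' @return integer m x 2 matrix, each edge once with `id_a < id_b`.
#' @export
setGeneric("cellEdges", function(x) standardGeneric("cellEdges"))

#' Per-cell phenotype labels
#'
#' @param x a [PhenotypePattern-class] or [IntensityMap-class].
#' @return a factor of per-cell labels.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' Ids of Tip cells in a pattern
#'
#' @param x a [PhenotypePattern-class].
#' @return integer vector of Tip cell ids.
#' @export
setGeneric("tipCells", function(x) standardGeneric("tipCells"))

#' Ids of cells selected as Sprouts
#'
#' @param x a [SproutSelection-class].
#' @return integer vector of sprout cell ids, in selection order.
#' @export
setGeneric("sproutIds", function(x) standardGeneric("sproutIds"))

#' @rdname nCells
#' @export
setMethod("nCells", "CellGraph", function(x) nrow(x@centroids))
#' @rdname nCells
#' @export
setMethod("nCells", "PhenotypePattern", function(x) nCells(x@graph))
#' @rdname nCells
#' @export
setMethod("nCells", "IntensityMap", function(x) nCells(x@graph))

#' @rdname centroids
#' @export
setMethod("centroids", "CellGraph", function(x) x@centroids)
#' @rdname centroids
#' @export
setMethod("centroids", "PhenotypePattern", function(x) x@graph@centroids)
#' @rdname centroids
#' @export
setMethod("centroids", "IntensityMap", function(x) x@graph@centroids)

#' @rdname cellEdges
#' @export
setMethod("cellEdges", "CellGraph", function(x) x@edges)
#' @rdname cellEdges
#' @export
setMethod("cellEdges", "PhenotypePattern", function(x) x@graph@edges)
#' @rdname cellEdges
#' @export
setMethod("cellEdges", "IntensityMap", function(x) x@graph@edges)

#' @rdname cellLabels
#' @export
setMethod("cellLabels", "PhenotypePattern", function(x) x@labels)
#' @rdname cellLabels
#' @export
setMethod("cellLabels", "IntensityMap", function(x) x@labels)

#' @rdname tipCells
#' @export
setMethod("tipCells", "PhenotypePattern", function(x) which(x@labels == "Tip"))

#' @rdname sproutIds
#' @export
setMethod("sproutIds", "SproutSelection", function(x) x@sproutIds)

#' Extract the underlying CellGraph
#'
#' @param x a [PhenotypePattern-class] or [IntensityMap-class].
#' @return the [CellGraph-class] the object is defined on.
#' @export
setGeneric("cellGraphOf", function(x) standardGeneric("cellGraphOf"))
#' @rdname cellGraphOf
#' @export
setMethod("cellGraphOf", "PhenotypePattern", function(x) x@graph)
#' @rdname cellGraphOf
#' @export
setMethod("cellGraphOf", "IntensityMap", function(x) x@graph)

setMethod("show", "CellGraph", function(object) {
  cat("CellGraph with", nCells(object), "cells and", nrow(object@edges), "edges;",
      if (object@periodic) "periodic (torus)" else "planar", "\n")
})

setMethod("show", "HexLattice", function(object) {
  cat(sprintf("HexLattice %d x %d (%s offset), %s, %d cells, %d edges\n",
              object@rows, object@cols, object@offset,
              if (object@periodic) "periodic" else "open boundary",
              nCells(object), nrow(object@edges)))
})

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (VEGF/NOTCH lattice circuit)\n")
  cat("  production  :", paste(names(object@production), object@production,
                               sep = "=", collapse = ", "), "molecules/hr\n")
  cat("  degradation :", paste(names(object@degradation), object@degradation,
                               sep = "=", collapse = ", "), "1/hr\n")
  cat("  binding     :", paste(names(object@binding),
                               format(object@binding, digits = 3),
                               sep = "=", collapse = ", "), "1/(molecule hr)\n")
  cat("  thresholds  :", paste(names(object@thresholds), object@thresholds,
                               sep = "=", collapse = ", "), "molecules\n")
  cat("  fold-change :", paste(names(object@foldChange), object@foldChange,
                               sep = "=", collapse = ", "), "\n")
  cat("  Hill coef   :", paste(names(object@hillCoef), object@hillCoef,
                               sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: VEGF %g ng/ml (x%g molecules), pre %g hr, max %g hr, tol %g molecules/hr, %d replicate(s), seed %d\n",
    object@vExt, object@vegfScale, object@tPre, object@tMax,
    object@convergenceTol, object@nReplicates, object@seed))
})

setMethod("show", "PhenotypePattern", function(object) {
  nt <- length(tipCells(object))
  cat(sprintf("PhenotypePattern: %d cells, %d Tips (fraction %.3f)\n",
              nCells(object), nt, nt / nCells(object)))
})

setMethod("show", "SproutSelection", function(object) {
  cat(sprintf("SproutSelection [%s]: %d sprouts (seed %d)\n",
              object@model, length(object@sproutIds), object@seed))
})

setMethod("show", "FateSeries", function(object) {
  cat(sprintf("FateSeries: %d cells over %d time points (%s hr)\n",
              nrow(object@states), length(object@timePoints),
              paste(object@timePoints, collapse = ", ")))
})

setMethod("show", "IntensityMap", function(object) {
  cat(sprintf("IntensityMap: %d cells, intensity range [%.1f, %.1f]\n",
              nCells(object), min(object@intensity), max(object@intensity)))
  print(table(object@labels))
})

setMethod("show", "TransitionFit", function(object) {
  cat(sprintf("TransitionFit: threshold %.3g ng/ml, zone [%.3g, %.3g], plateaus (%.3f, %.3f)\n",
              object@threshold, object@zone[1L], object@zone[2L],
              object@plateaus[1L], object@plateaus[2L]))
})
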