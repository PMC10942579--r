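#' @import methods
#' @importFrom stats runif setNames quantile median aggregate lm coef residuals approx
#' @importFrom utils head read.delim write.table
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CellGraph: cell adjacency and centroid geometry
#'
#' A `CellGraph` stores the planar (or toroidal) geometry of a sheet of cells:
#' one centroid per cell, in units of the mean neighbor center-to-center
#' distance, and an undirected adjacency relation. Hexagonal lattices are the
#' model's case ([HexLattice-class]); irregular graphs arise from segmented
#' experimental cell maps (see [jitteredGraph()] for a synthetic stand-in).
#' Corner (point) contacts are never edges: builders must apply a positive
#' shared-boundary criterion.
#'
#' @slot centroids numeric matrix (n x 2) of cell center coordinates.
#' @slot edges integer matrix (m x 2); each undirected edge stored once with
#'   `edges[, 1] < edges[, 2]`; no self-loops.
#' @slot periodic logical; `TRUE` if the geometry lives on a torus.
#' @slot box numeric length-2 torus periods `c(Lx, Ly)`; `NA` when aperiodic.
#'
#' @seealso [buildHexLattice()], [cellGraph()], [hopDistance()], [isShielded()]
#' @exportClass CellGraph
setClass("CellGraph",
  representation(
    centroids = "matrix",
    edges = "matrix",
    periodic = "logical",
    box = "numeric"
  )
)

setValidity("CellGraph", function(object) {
  n <- nrow(object@centroids)
  e <- object@edges
  if (ncol(object@centroids) != 2L) return("centroids must be an n x 2 matrix")
  if (ncol(e) != 2L) return("edges must be an m x 2 matrix")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) return("edge endpoint outside cell id range")
    if (any(e[, 1L] == e[, 2L])) return("self-loop edges are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edges must be stored with id_a < id_b")
    if (anyDuplicated(e)) return("duplicated edges")
  }
  if (object@periodic && any(!is.finite(object@box))) {
    return("periodic graphs need finite box periods")
  }
  TRUE
})

#' HexLattice: periodic hexagonal cell lattice
#'
#' A hexagonal lattice of `rows x cols` cells in "odd-r" offset convention
#' (odd rows shifted right by half a cell), with unit center-to-center spacing
#' and row pitch sqrt(3)/2. When periodic, every cell has exactly six
#' neighbors and the graph has `3 * rows * cols` edges.
#'
#' @slot rows,cols integer lattice dimensions.
#' @slot offset offset convention; always `"odd-r"`.
#' @seealso [buildHexLattice()]
#' @exportClass HexLattice
setClass("HexLattice",
  contains = "CellGraph",
  representation(rows = "integer", cols = "integer", offset = "character")
)

setValidity("HexLattice", function(object) {
  if (object@rows < 2L || object@cols < 2L) return("rows and cols must be >= 2")
  if (object@periodic && object@rows %% 2L != 0L) {
    return("periodic hex lattices need an even number of rows (seam mismatch)")
  }
  if (!identical(object@offset, "odd-r")) return("only the odd-r convention is supported")
  TRUE
})

#' ModelParameters: kinetic parameters of the VEGF/NOTCH lattice model
#'
#' Holds every rate constant, threshold, fold-change and Hill coefficient of
#' the five-species (NOTCH, Delta, Jagged, NICD, VEGFR) per-cell circuit.
#' Defaults are the published simulation values; see [modelParameters()].
#'
#' @slot production named numeric: basal production rates `N0, D0, J0, VR0`
#'   (molecules/hr).
#' @slot degradation named numeric: `gamma` (N, D, J, VR) and `gammaI` (NICD),
#'   1/hr.
#' @slot binding named numeric: trans NOTCH-ligand (`kT`), cis (`kC`) and
#'   VEGF-VEGFR (`kTV`) binding rate constants, 1/(molecule hr). The published
#'   parameter table prints a single trans constant; `kTV` defaults to the
#'   same value but is kept separate so that varying the NOTCH-Delta binding
#'   rate does not implicitly rescale the VEGF input arm.
#' @slot thresholds named numeric: NICD Hill threshold `I0` and activated-VEGFR
#'   Hill threshold `V0` (molecules).
#' @slot foldChange named numeric: shifted-Hill fold-changes
#'   `c(N, D, VR, J, V)` for NICD on NOTCH/Delta/VEGFR/Jagged and activated
#'   VEGFR on Delta. Values > 1 activate, < 1 inhibit.
#' @slot hillCoef named numeric: matching Hill coefficients.
#' @seealso [modelParameters()], [cellDerivatives()]
#' @exportClass ModelParameters
setClass("ModelParameters",
  representation(
    production = "numeric",
    degradation = "numeric",
    binding = "numeric",
    thresholds = "numeric",
    foldChange = "numeric",
    hillCoef = "numeric"
  )
)

setValidity("ModelParameters", function(object) {
  need <- function(x, nm) identical(sort(names(x)), sort(nm)) && all(is.finite(x))
  if (!need(object@production, c("N0", "D0", "J0", "VR0"))) {
    return("production must be named c(N0, D0, J0, VR0)")
  }
  if (!need(object@degradation, c("gamma", "gammaI"))) {
    return("degradation must be named c(gamma, gammaI)")
  }
  if (!need(object@binding, c("kT", "kC", "kTV"))) {
    return("binding must be named c(kT, kC, kTV)")
  }
  if (!need(object@thresholds, c("I0", "V0"))) return("thresholds must be named c(I0, V0)")
  if (!need(object@foldChange, c("N", "D", "VR", "J", "V"))) {
    return("foldChange must be named c(N, D, VR, J, V)")
  }
  if (!need(object@hillCoef, c("N", "D", "VR", "J", "V"))) {
    return("hillCoef must be named c(N, D, VR, J, V)")
  }
  if (any(object@production <= 0) || any(object@degradation <= 0) ||
      any(object@thresholds <= 0)) {
    return("rates and thresholds must be > 0")
  }
  if (any(object@binding < 0)) return("binding rates must be >= 0")
  if (any(object@foldChange < 0)) return("fold-changes must be >= 0")
  if (any(object@hillCoef < 1)) return("Hill coefficients must be >= 1")
  TRUE
})

#' SimulationConfig: integration and ensemble settings
#'
#' @slot vExt external VEGF level on the ng/ml scale.
#' @slot vegfScale molecules per (ng/ml) conversion factor applied to `vExt`
#'   inside the equations; the published axis absorbs units, so the default
#'   is 1.
#' @slot tPre pre-equilibration duration without VEGF (hr).
#' @slot tMax maximum integration time with VEGF after the pre-phase (hr).
#' @slot convergenceTol steady-state residual bound, molecules/hr.
#' @slot initRanges 2 x 5 matrix of uniform initial-condition bounds
#'   (rows lo/hi, columns N, D, J, I, VR), molecules.
#' @slot seed base RNG seed; replicate r uses `seed + r - 1`.
#' @slot nReplicates independent runs per condition.
#' @seealso [simulationConfig()], [equilibrate()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    vExt = "numeric",
    vegfScale = "numeric",
    tPre = "numeric",
    tMax = "numeric",
    convergenceTol = "numeric",
    initRanges = "matrix",
    seed = "integer",
    nReplicates = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@vExt < 0) return("vExt must be >= 0")
  if (object@tPre <= 0 || object@tMax <= 0) return("tPre and tMax must be > 0")
  if (object@convergenceTol <= 0) return("convergenceTol must be > 0")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  r <- object@initRanges
  if (!identical(dim(r), c(2L, 5L))) return("initRanges must be a 2 x 5 matrix")
  if (any(r[1L, ] > r[2L, ])) return("initRanges lower bounds exceed upper bounds")
  if (any(r < 0)) return("initRanges must be non-negative")
  TRUE
})

#' PhenotypePattern: per-cell Tip/Stalk labels over a CellGraph
#'
#' @slot graph the underlying [CellGraph-class].
#' @slot labels factor of length `nCells(graph)` with levels
#'   `c("Stalk", "Tip")`.
#' @seealso [classifyTips()], [tipFraction()], [disorderIndex()]
#' @exportClass PhenotypePattern
setClass("PhenotypePattern",
  representation(graph = "CellGraph", labels = "factor")
)

setValidity("PhenotypePattern", function(object) {
  if (length(object@labels) != nrow(object@graph@centroids)) {
    return("labels length must equal the number of cells")
  }
  if (!identical(levels(object@labels), c("Stalk", "Tip"))) {
    return('labels must be a factor with levels c("Stalk", "Tip")')
  }
  if (anyNA(object@labels)) return("every cell must be labeled")
  TRUE
})

#' SproutSelection: Tips promoted to Sprouts by a phenomenological model
#'
#' @slot model one of `"cell_autonomous"`, `"repulsion"`, `"random_uniform"`.
#' @slot sproutIds ordered integer ids of the selected Tip cells.
#' @slot targetCount requested number of sprouts.
#' @slot seed RNG seed used for the selection.
#' @seealso [selectCellAutonomous()], [selectRepulsion()],
#'   [selectRandomUniform()], [sproutSpacing()]
#' @exportClass SproutSelection
setClass("SproutSelection",
  representation(
    model = "character",
    sproutIds = "integer",
    targetCount = "integer",
    seed = "integer"
  )
)

setValidity("SproutSelection", function(object) {
  if (!object@model %in% c("cell_autonomous", "repulsion", "random_uniform")) {
    return("unknown selection model")
  }
  if (anyDuplicated(object@sproutIds)) return("duplicate sprout ids")
  if (length(object@sproutIds) != object@targetCount) {
    return("number of sprouts differs from the target count")
  }
  TRUE
})

#' FateSeries: per-cell fate-label trajectories over ordered time points
#'
#' States are `"Stalk"`, `"MiniSprout"` or `"Sprout"`; the Sprout state is
#' absorbing (a committed sprout never reverts) and the tracked cohort is, by
#' definition, the set of cells observed in the MiniSprout state at least
#' once. The state before the first observation is Stalk for every cell.
#'
#' @slot cellIds character cell identifiers.
#' @slot timePoints numeric observation times in hours (possibly non-uniform).
#' @slot states character matrix, cells x time points.
#' @seealso [fateSeries()], [validateSeries()], [intervalTransitions()],
#'   [cohortSummary()]
#' @exportClass FateSeries
setClass("FateSeries",
  representation(cellIds = "character", timePoints = "numeric", states = "matrix")
)

setValidity("FateSeries", function(object) {
  st <- object@states
  if (nrow(st) != length(object@cellIds)) return("one row of states per cell required")
  if (ncol(st) != length(object@timePoints)) return("one column of states per time point required")
  if (is.unsorted(object@timePoints, strictly = TRUE)) {
    return("time points must be strictly increasing")
  }
  ok <- st %in% c("Stalk", "MiniSprout", "Sprout")
  if (!all(ok)) return("states must be Stalk, MiniSprout or Sprout")
  TRUE
})

#' IntensityMap: per-cell fibronectin intensities with activity labels
#'
#' @slot graph the underlying [CellGraph-class].
#' @slot intensity numeric per-cell mean fibronectin intensity (a.u., >= 0).
#' @slot labels factor with levels `c("SproutLeading", "SproutFollowing",
#'   "MiniSprout", "Quiescent")`.
#' @seealso [intensityMap()], [labelSummary()], [buildGroups()],
#'   [ratioAboveThreshold()]
#' @exportClass IntensityMap
setClass("IntensityMap",
  representation(graph = "CellGraph", intensity = "numeric", labels = "factor")
)

setValidity("IntensityMap", function(object) {
  n <- nrow(object@graph@centroids)
  if (length(object@intensity) != n || length(object@labels) != n) {
    return("intensity and labels must have one entry per cell")
  }
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0)) {
    return("intensities must be finite and >= 0")
  }
  lv <- c("SproutLeading", "SproutFollowing", "MiniSprout", "Quiescent")
  if (!identical(levels(object@labels), lv)) {
    return("labels must use levels SproutLeading/SproutFollowing/MiniSprout/Quiescent")
  }
  TRUE
})

#' TransitionFit: order-disorder transition summary of a dose-response curve
#'
#' @slot threshold VEGF dose (ng/ml) where the mean Tip fraction crosses the
#'   midpoint between the low and high plateaus.
#' @slot zone dose interval `c(lo, hi)` of maximal slope on the log10-dose
#'   axis (the transition zone).
#' @slot plateaus mean Tip fraction at the lowest and highest dose.
#' @slot slopes named slopes (per log10 dose) of linear fits below, inside and
#'   above the zone (`NA` where fewer than two points are available).
#' @slot residuals residual standard errors of the same fits.
#' @seealso [fitTransition()]
#' @exportClass TransitionFit
setClass("TransitionFit",
  representation(
    threshold = "numeric",
    zone = "numeric",
    plateaus = "numeric",
    slopes = "numeric",
    residuals = "numeric"
  )
)
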