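# Mini-sprout / sprout fate-transition tracking across ordered observation
# times, with the absorbing Sprout rule: once a cell leads a lumenized sprout
# it is permanently committed. The tracked cohort is the set of cells that
# displayed the MiniSprout phenotype at least once; the state before the
# first observation is Stalk for every cell (newly formed vessels start as
# non-invading endothelium).

.FATE_STATES <- c("Stalk", "MiniSprout", "Sprout")

#' Construct a FateSeries
#'
#' @param states character matrix (cells x time points) of
#'   `"Stalk"`/`"MiniSprout"`/`"Sprout"` labels, or a data.frame whose first
#'   column is `cell_id` and remaining columns are per-time states.
#' @param timePoints numeric observation times in hours (default the 1, 3, 7,
#'   28 hr imaging schedule).
#' @param cellIds cell identifiers; defaults to row numbers.
#' @return a [FateSeries-class] (structural checks only; see
#'   [validateSeries()] for the scientific invariants).
#' @export
fateSeries <- function(states, timePoints = c(1, 3, 7, 28), cellIds = NULL) {
  if (is.data.frame(states)) {
    if (names(states)[1L] == "cell_id") {
      cellIds <- as.character(states$cell_id)
      states <- as.matrix(states[, -1L])
    } else {
      states <- as.matrix(states)
    }
  }
  storage.mode(states) <- "character"
  dimnames(states) <- NULL
  if (is.null(cellIds)) cellIds <- as.character(seq_len(nrow(states)))
  new("FateSeries", cellIds = cellIds, timePoints = as.numeric(timePoints),
      states = states)
}

#' Validate the scientific invariants of a FateSeries
#'
#' Checks (i) the absorbing-sprout rule: no cell ever leaves the Sprout state
#' (a Sprout followed by MiniSprout or Stalk is an error naming the cell and
#' interval), and (ii) cohort membership: every tracked cell is in the
#' MiniSprout state at least once.
#'
#' @param series a [FateSeries-class].
#' @return the validated series, invisibly usable downstream.
#' @export
validateSeries <- function(series) {
  st <- series@states
  nT <- ncol(st)
  for (j in seq_len(nT - 1L)) {
    bad <- which(st[, j] == "Sprout" & st[, j + 1L] != "Sprout")
    if (length(bad) > 0L) {
      stop(sprintf(
        "absorbing-sprout violation: cell %s reverts from Sprout between time points %d and %d",
        series@cellIds[bad[1L]], j, j + 1L))
    }
  }
  everMini <- rowSums(st == "MiniSprout") > 0L
  if (!all(everMini)) {
    stop(sprintf(
      "cohort violation: cell %s is never observed in the MiniSprout state",
      series@cellIds[which(!everMini)[1L]]))
  }
  series
}

# states with the implicit all-Stalk observation prepended at t = 0
.withInitialStalk <- function(series) {
  cbind(rep("Stalk", nrow(series@states)), series@states)
}

#' Per-interval transitions out of the MiniSprout state
#'
#' For every pair of consecutive time points, counts the three outcomes among
#' cells that are MiniSprout at the interval start: maintain the MiniSprout
#' state, become a Sprout, or retract to the Stalk state. Also counts how many
#' of the conversions come from *newly formed* mini-sprouts (Stalk two
#' observations before conversion, MiniSprout one observation before; the
#' state before the first observation counts as Stalk).
#'
#' @param series a validated [FateSeries-class] with >= 2 time points.
#' @return data.frame with one row per interval: `interval, tFrom, tTo, nMini,
#'   maintain, toSprout, retract, fracMaintain, fracSprout, fracRetract,
#'   newlyFormedConversions`. The three fractions sum to 1 on every interval
#'   with `nMini > 0`.
#' @export
intervalTransitions <- function(series) {
  series <- validateSeries(series)
  st <- series@states
  if (ncol(st) < 2L) stop("at least two time points are required")
  ext <- .withInitialStalk(series)      # column j+1 of ext == column j of st
  nInt <- ncol(st) - 1L
  rows <- lapply(seq_len(nInt), function(j) {
    from <- st[, j]
    to <- st[, j + 1L]
    mini <- from == "MiniSprout"
    nM <- sum(mini)
    toS <- sum(mini & to == "Sprout")
    mnt <- sum(mini & to == "MiniSprout")
    ret <- sum(mini & to == "Stalk")
    newly <- sum(mini & to == "Sprout" & ext[, j] == "Stalk")
    data.frame(interval = j,
               tFrom = series@timePoints[j], tTo = series@timePoints[j + 1L],
               nMini = nM, maintain = mnt, toSprout = toS, retract = ret,
               fracMaintain = if (nM) mnt / nM else NA_real_,
               fracSprout = if (nM) toS / nM else NA_real_,
               fracRetract = if (nM) ret / nM else NA_real_,
               newlyFormedConversions = newly)
  })
  do.call(rbind, rows)
}

#' Endpoint summary of a tracked mini-sprout cohort
#'
#' Summarises the cohort at the final observation: the fractions of cells that
#' retracted back to the Stalk state, are still mini-sprouts, or lead a
#' committed sprout; the fraction of sprouts that emerged from newly formed
#' mini-sprouts (Stalk, then MiniSprout, in the two observations preceding
#' commitment -- direct Stalk-to-Sprout transitions are counted as sprouts not
#' from mini-sprouts); and the dwell time spent in the immediately preceding
#' state before sprout commitment. Dwell is the number of consecutive
#' observations in that state directly before commitment (a retraction resets
#' the clock); in hours it is the commitment time minus the time of the first
#' of those observations (state entry between observations is not
#' resolvable, so this is the observable lower bound).
#'
#' @param series a validated [FateSeries-class].
#' @return list with `cohortSize`, `finalCounts` and `finalFractions` (named
#'   `retracted, mini_sprout, sprout`), `sproutsFromNewlyFormed`,
#'   `fracSproutsFromNewlyFormed`, and a `dwell` data.frame (`cell, state,
#'   nObservations, hours`) for cells that committed.
#' @export
cohortSummary <- function(series) {
  series <- validateSeries(series)
  st <- series@states
  nT <- ncol(st)
  if (nrow(st) == 0L) stop("empty cohort")
  final <- st[, nT]
  counts <- c(retracted = sum(final == "Stalk"),
              mini_sprout = sum(final == "MiniSprout"),
              sprout = sum(final == "Sprout"))
  ext <- .withInitialStalk(series)      # ext column j+1 == observation j
  tExt <- c(0, series@timePoints)
  committed <- which(final == "Sprout")
  dwell <- lapply(committed, function(i) {
    jC <- match("Sprout", st[i, ])      # first committed observation
    jExt <- jC + 1L                     # index into ext
    prevState <- ext[i, jExt - 1L]
    k <- 0L
    while (jExt - 1L - k >= 1L && ext[i, jExt - 1L - k] == prevState) k <- k + 1L
    hours <- tExt[jExt] - tExt[jExt - k]
    data.frame(cell = series@cellIds[i], state = prevState,
               nObservations = k, hours = hours,
               newlyFormed = prevState == "MiniSprout" && k == 1L)
  })
  dwell <- if (length(dwell)) do.call(rbind, dwell) else
    data.frame(cell = character(0), state = character(0),
               nObservations = integer(0), hours = numeric(0),
               newlyFormed = logical(0))
  nNew <- sum(dwell$newlyFormed)
  list(cohortSize = nrow(st),
       finalCounts = counts,
       finalFractions = counts / nrow(st),
       sproutsFromNewlyFormed = nNew,
       fracSproutsFromNewlyFormed = if (length(committed)) nNew / length(committed) else NA_real_,
       dwell = dwell[, c("cell", "state", "nObservations", "hours")])
}

#' Sankey link table of state transitions
#'
#' Counts every (source state, target state) transition per interval,
#' including the implicit all-Stalk state before the first observation.
#'
#' @param series a validated [FateSeries-class].
#' @param includeInitial prepend the implicit Stalk state at t = 0.
#' @return data.frame with columns `interval, source, target, count`.
#' @export
sankeyLinks <- function(series, includeInitial = TRUE) {
  series <- validateSeries(series)
  st <- if (includeInitial) .withInitialStalk(series) else series@states
  rows <- lapply(seq_len(ncol(st) - 1L), function(j) {
    tb <- table(factor(st[, j], .FATE_STATES), factor(st[, j + 1L], .FATE_STATES))
    df <- as.data.frame(tb, stringsAsFactors = FALSE)
    names(df) <- c("source", "target", "count")
    df$interval <- j
    df[df$count > 0L, c("interval", "source", "target", "count")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write fate-series state tables
#'
#' Delimited text format: one row per cell, columns `cell_id` then one state
#' column per time point (named `t<hours>`).
#'
#' @param series a [FateSeries-class].
#' @param file path.
#' @return `writeFateSeries()` returns `file` invisibly; `readFateSeries()`
#'   returns a [FateSeries-class].
#' @export
writeFateSeries <- function(series, file) {
  tab <- data.frame(cell_id = series@cellIds, series@states)
  names(tab) <- c("cell_id", paste0("t", series@timePoints))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFateSeries
#' @export
readFateSeries <- function(file) {
  tab <- read.delim(file, colClasses = "character")
  tp <- as.numeric(sub("^t", "", names(tab)[-1L]))
  fateSeries(as.matrix(tab[, -1L]), timePoints = tp, cellIds = tab$cell_id)
}
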