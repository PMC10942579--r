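test_that("cell-autonomous selection is uniform over Tips and Tip-restricted", {
  set.seed(1)
  pat <- disorderedPattern(8, 8, 0.3, adjacencyBias = 0, seed = 2)
  tips <- tipCells(pat)
  sel <- selectCellAutonomous(pat, length(tips), seed = 1)
  expect_setequal(sproutIds(sel), tips)
  expect_error(selectCellAutonomous(pat, length(tips) + 1L, seed = 1), "exceeds")
  # single-sprout draws are uniform over the Tip set
  draws <- vapply(1:4000, function(s) sproutIds(selectCellAutonomous(pat, 1L, seed = s)),
                  integer(1L))
  freq <- table(factor(draws, levels = tips)) / 4000
  expect_true(all(freq > 0))
  expect_lt(max(abs(freq - 1 / length(tips))), 3 * sqrt((1 / length(tips)) / 4000) + 0.01)
  # adjacent sprout pairs occur at an appreciable rate (the model's failure mode)
  touching <- vapply(1:200, function(s) {
    ids <- sproutIds(selectCellAutonomous(pat, 8L, seed = s))
    e <- cellEdges(pat)
    any(e[, 1L] %in% ids & e[, 2L] %in% ids)
  }, logical(1L))
  expect_gt(mean(touching), 0.2)
})

test_that("repulsion selections never contain adjacent sprouts", {
  pats <- lapply(1:5, function(s) disorderedPattern(8, 8, 0.3, 0, seed = s))
  for (run in 1:1000) {
    pat <- pats[[(run - 1L) %% 5L + 1L]]
    sel <- selectRepulsion(pat, 5L, seed = run)
    ids <- sproutIds(sel)
    e <- cellEdges(pat)
    expect_false(any(e[, 1L] %in% ids & e[, 2L] %in% ids))
  }
})

test_that("repulsion reports infeasible targets instead of looping", {
  lat <- buildHexLattice(4, 4)
  allTip <- phenotypePattern(lat, rep(TRUE, 16))
  # a 4x4 torus has no independent set anywhere near 10 of 16 cells
  expect_error(selectRepulsion(allTip, 10L, seed = 1), "infeasible")
})

test_that("maximal-dispersion selection picks chain endpoints and is locally optimal", {
  # 1D chain of Tips: the second sprout is the endpoint farthest from the start
  n <- 9L
  chain <- cellGraph(cbind(seq_len(n), 0), cbind(seq_len(n - 1L), 2:n))
  pat <- phenotypePattern(chain, rep(TRUE, n))
  for (s in 1:10) {
    ids <- sproutIds(selectRandomUniform(pat, 2L, seed = s))
    expect_true(ids[2L] %in% c(1L, n))
    expect_equal(abs(ids[2L] - ids[1L]), max(ids[1L] - 1L, n - ids[1L]))
  }
  # greedy audit: no unselected Tip is farther from the earlier sprouts than
  # the one actually added last
  set.seed(5)
  pat2 <- disorderedPattern(8, 8, 0.3, 0, seed = 7)
  tips <- tipCells(pat2)
  sel <- selectRandomUniform(pat2, 5L, seed = 3)
  ids <- sproutIds(sel)
  dm <- angiopattern:::.hopDistanceMatrix(pat2@graph, tips, tips)
  dm[is.na(dm)] <- 0
  idx <- match(ids, tips)
  prev <- idx[-length(idx)]
  base <- min(dm[idx[length(idx)], prev])
  for (alt in setdiff(seq_along(tips), idx)) {
    expect_lte(min(dm[alt, prev]), base)
  }
})

test_that("all three models coincide at full and single selection", {
  set.seed(2)
  pat <- disorderedPattern(8, 8, 0.25, 0, seed = 11)
  tips <- tipCells(pat)
  nT <- length(tips)
  for (model in c("cell_autonomous", "repulsion", "random_uniform")) {
    if (model == "repulsion") next   # full Tip set is not an independent set
    expect_setequal(sproutIds(selectSprouts(pat, nT, model, seed = 1)), tips)
  }
  # single sprout: repulsion is distributionally identical to cell-autonomous
  a <- vapply(1:500, function(s) sproutIds(selectCellAutonomous(pat, 1L, seed = s)), integer(1L))
  b <- vapply(1:500, function(s) sproutIds(selectRepulsion(pat, 1L, seed = s)), integer(1L))
  expect_identical(a, b)
})

test_that("sprout spacing distributions reflect the selection rule", {
  lat <- buildHexLattice(8, 8)
  pat <- phenotypePattern(lat, rep(TRUE, 64))
  adjacentPair <- .newSel <- new("SproutSelection", model = "cell_autonomous",
                                 sproutIds = c(1L, neighborList(lat)[[1L]][1L]),
                                 targetCount = 2L, seed = 1L)
  sp <- sproutSpacing(adjacentPair, pat)
  expect_equal(sp$distance[sp$count > 0L], 0)
  expect_error(sproutSpacing(selectCellAutonomous(pat, 1L, seed = 1), pat), "two sprouts")
  # repulsion outputs put zero mass at distance 0
  set.seed(3)
  pat2 <- disorderedPattern(8, 8, 0.35, 0, seed = 4)
  for (s in 1:25) {
    sel <- selectRepulsion(pat2, 6L, seed = s)
    sp <- sproutSpacing(sel, pat2, seed = s)
    expect_false(any(sp$distance[sp$count > 0L] == 0))
  }
})

test_that("mean closest-sprout distance decreases with sprout fraction", {
  pats <- lapply(1:3, function(s) disorderedPattern(10, 10, 0.35, 0, seed = s))
  for (model in c("cell_autonomous", "random_uniform")) {
    curve <- spacingVsFractionCurve(pats, model, fractions = c(0.05, 0.15, 0.3),
                                    seeds = 1:8)
    expect_true(all(diff(curve$meanDistance) <= 1e-9),
                info = paste("monotone spacing for", model))
  }
  # saturation: selecting every Tip drives the closest distance to its minimum
  allTip <- phenotypePattern(buildHexLattice(6, 6), rep(TRUE, 36))
  sel <- selectCellAutonomous(allTip, 36L, seed = 1)
  expect_equal(meanRankDistance(sproutSpacing(sel, allTip), 1L), 0)
})

test_that("model spacing is ordered random_uniform >= repulsion >= cell_autonomous", {
  set.seed(20)
  pats <- lapply(1:3, function(s) disorderedPattern(12, 12, 0.32, 0.5, seed = s))
  nS <- round(0.06 * 144)
  means <- sapply(c("cell_autonomous", "repulsion", "random_uniform"), function(model) {
    d <- c()
    for (pat in pats) {
      for (s in 1:17) {
        sel <- selectSprouts(pat, nS, model, seed = s)
        d <- c(d, meanRankDistance(sproutSpacing(sel, pat, seed = s), 1L))
      }
    }
    mean(d)
  })
  expect_gte(means[["random_uniform"]], means[["repulsion"]])
  expect_gte(means[["repulsion"]], means[["cell_autonomous"]])
})
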