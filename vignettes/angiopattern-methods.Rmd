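---
title: "Models and methods behind angiopattern"
author: "angiopattern authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind angiopattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(angiopattern)
```

`angiopattern` analyses how VEGF input reshapes Delta–NOTCH lateral
inhibition in an endothelial sheet: from the ordered salt-and-pepper
Tip–Stalk arrangement at low VEGF to disordered patterns with excess,
frequently adjacent Tip cells at high VEGF, and onward to which Tips commit
to leading sprouts. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic generators do and do
not emulate.

## The multicellular VEGF/NOTCH circuit

Each cell carries five species, in molecules: NOTCH receptor $N$, Delta
ligand $D$, Jagged ligand $J$, the NOTCH intracellular domain (NICD) $I$,
and VEGF receptor $V_R$. Production of $N$, $D$, $J$ and $V_R$ is basal
($N_0, D_0, J_0, V_{R0}$, molecules/hr) and transcriptionally modulated by
NICD through shifted Hill factors

$$H(X; X_0, n, \lambda) \;=\; \frac{1 + \lambda\,(X/X_0)^n}{1 + (X/X_0)^n},$$

which run from 1 at zero signal to $\lambda$ at saturation: NICD activates
NOTCH and Jagged ($\lambda = 2$) and completely shuts down Delta and VEGFR
($\lambda = 0$), the core of lateral inhibition. Trans binding of NOTCH with
neighbor ligands (rate constant $k_T$) releases NICD; the neighbor signal
$X_{ext}$ is the arithmetic mean over the six hexagonal neighbors. Cis
binding within a cell ($k_C$) degrades receptor–ligand pairs without
signaling. External VEGF acts through the activated receptor complex: its
dynamics are not modeled explicitly, so the Hill argument on Delta production
is the quasi-steady complex level $A = k_{TV} V_R V_{EXT}/\gamma$ (formation
balanced against first-order turnover). With the default parameters and
$V_R$ near its carrying capacity of $10^4$ molecules, $A$ crosses its
threshold $V_0 = 80$ molecules between doses 10 and 100 ng/ml, which brackets
the order–disorder transition.

Defaults (see `modelParameters()`): $N_0, D_0, J_0, V_{R0} =
1200, 1000, 800, 1000$ molecules/hr; $\gamma = 0.1$/hr, $\gamma_I = 0.5$/hr;
$k_T = 2.5\times10^{-5}$, $k_C = 5\times10^{-4}$ per molecule per hour;
$I_0 = 200$, $V_0 = 80$ molecules; fold-changes $(2, 0, 0, 2, 2)$ and Hill
coefficients $(2, 2, 2, 5, 2)$ for the NOTCH/Delta/VEGFR/Jagged/VEGF arms.
Jagged production is kept low so NOTCH–Jagged signaling does not interfere
with the Delta-driven bistability; hybrid NOTCH–Jagged phenotypes are out of
scope.

Two parameters deserve comment:

* **`kTV` (VEGF–VEGFR binding).** The published parameter table prints a
  single trans binding constant. Inside the equations that constant plays two
  unrelated roles: NOTCH–ligand binding and VEGF–receptor binding. The
  package keeps them as separate slots (`kT`, `kTV`), both defaulting to the
  printed value, so that sweeping the NOTCH–Delta binding rate does not
  silently rescale the VEGF input arm (which would invert the direction of
  the transition shift).
* **`vegfScale` (molecules per ng/ml).** The dose axis is calibrated, not
  absolute: the VEGF arm is known only up to the unit conversion between the
  experimental dose and the molecular signal. `calibrateVegfScale()`
  reproduces the calibration step on which the parameter set rests: it
  bisects the scale until a small ensemble's mean Tip fraction at the
  100 ng/ml condition matches the experimentally measured anchor of 0.32.
  The Tip fraction is monotone in the effective dose, so the bisection is
  well posed. Without calibration (`vegfScale = 1`) the same condition gives
  a mean Tip fraction near 0.37.

## Simulation protocol and numerics

A simulation starts from independent uniform initial conditions per cell and
species. The uniform ranges are not prescribed anywhere authoritative; the
package default is $[0,\, X_0/\gamma]$ per species (the isolated-cell
carrying capacity, e.g. $[0, 12000]$ for NOTCH) and $[0, 0]$ for NICD, and
the ranges are configurable. The measured Tip fraction at the operating point
is insensitive to this choice (halving the upper bounds moves it by less
than one replicate standard deviation).

The lattice first relaxes for `tPre = 100` hr without VEGF (emulating cell
seeding), then integrates at the configured dose until the maximum absolute
derivative over all cells and species falls below `convergenceTol = 1e-3`
molecules/hr or `tMax = 1000` hr elapse. Convergence is checked every 100 hr.
The stacked $5 \times n$ system is integrated with `deSolve`'s adaptive
Adams method at `rtol = 1e-6`, `atol = 1e-5`: the system is not stiff (all
time scales sit between roughly 1 and 10 hr; the switching integrator never
leaves its non-stiff mode) and the Adams path avoids reserving a full
Jacobian workspace for thousands of states, which makes it about an order of
magnitude faster here. `equilibrate(method = "lsoda")` selects the
stiff-capable switching integrator and produces the same trajectories.
Occasional replicates carry metastable cells whose residual stays slightly
above tolerance at `tMax`; these are flagged `converged = FALSE` with a
warning and are still analyzed, since the Tip classification stabilises long
before the strict residual bound is met.

Ensembles use a deterministic seed ladder (`seed + replicate - 1`), and
every stochastic analysis step (distance-rank tie-breaking, sprout
selection) takes its own recorded seed, so all results are bit-reproducible.

## Pattern statistics

Equilibrated Delta levels are bimodal at every dose, with a wide empty
valley, so Tips are classified by the fixed threshold $D > 10^3$ molecules.
The disorder index is the fraction of Tip cells with at least one adjacent
Tip (0 for the perfect pattern, 1 for an all-Tip sheet); the exact
supplementary definition used alongside the original figures is not
reproduced in the available text, so this default is declared, not
attributed, and `disorderIndex(metric =)` accepts a replacement.

Tip–Tip spacing uses hop distances — the number of intermediate cells on the
shortest path, adjacent cells at distance 0 — computed by breadth-first
search on the adjacency graph (`igraph`). A printed closed-form offset-grid
distance rule exists but is internally inconsistent as written, so BFS is
authoritative and the test suite validates it against an independent
hand-rolled BFS oracle. For each Tip, the other Tips are ranked by distance
with seeded random tie-breaking; a pair is excluded when a third Tip
*shields* it, i.e. the straight minimal-image segment between the centroids
intersects a closed disk of radius 0.5 (in units of the mean neighbor
spacing) centered on the shield. Shield candidates are Tips only, and on the
torus their $3\times3$ images are checked. Note a structural consequence of
this protocol: an adjacent Tip pair can never be shielded (any third cell's
center lies at least $\sqrt{3}/2 > 0.5$ from the unit segment), so the
probability that a Tip's closest Tip is at distance 0 equals the probability
of having an adjacent Tip, which ties the mean rank-1 distance tightly to the
adjacency probability.

`fitTransition()` summarises a dose–response table on the log10-dose axis:
transition zone = the consecutive dose interval of maximal slope, linear fits
below/inside/above the zone, and threshold = the first crossing of the
midpoint between the low- and high-dose plateau. When comparing thresholds
*across parameter values* (`sweepParameter()`), each curve is instead crossed
against a common reference level — the default-parameter curve's plateau
midpoint — because the plateau levels themselves move with the parameter
(e.g. stronger NOTCH–Delta binding lowers the absolute Delta level of the Tip
state under the fixed classification threshold), and the per-curve midpoint
would confound plateau shifts with transition shifts.

## Sprout selection

All three models act on the Tip set of an equilibrated pattern and are
normalised to a requested sprout count:

* **cell-autonomous** — a uniform random Tip subset; permits adjacent
  sprouts, its characteristic failure mode;
* **repulsion** — iterative rejection sampling in which a drawn Tip is
  promoted only if not adjacent to an existing sprout (retry budget
  `100 * nSprouts`; exhaustion raises an explicit infeasibility error);
* **random-uniform (maximal dispersion)** — greedy farthest-point sampling:
  a random first sprout, then the farthest Tip, then repeatedly the Tip
  maximising the *minimum* hop distance to the selected sprouts, ties broken
  by the larger total distance and then by the seeded RNG. Maximising the
  minimum separation is the operational meaning of "maximal spread": the raw
  sum of pairwise distances is degenerate on a torus (two antipodal clumps of
  mutually adjacent sprouts maximise it) and contradicts the model's defining
  behavior of never placing sprouts in contact.

Distances inside the selection objective are plain hop distances; shielding
applies only to the reported spacing statistics, mirroring the measurement
protocol. At matched sprout fractions the mean closest-sprout distance is
ordered random-uniform ≥ repulsion ≥ cell-autonomous, and it is
non-increasing in the sprout fraction for every model.

## Fate dynamics

`FateSeries` objects hold per-cell state labels (Stalk, MiniSprout, Sprout)
over ordered observation times, by default the 1, 3, 7, 28 hr imaging
schedule. Two rules are enforced by `validateSeries()`: the Sprout state is
absorbing, and the tracked cohort consists of cells observed as MiniSprout at
least once. The state before the first observation is Stalk for every cell,
so a mini-sprout at the first time point counts as *newly formed* (Stalk two
observations before a conversion, MiniSprout one before). Cells first seen as
Sprout without a preceding MiniSprout observation are direct Stalk-to-Sprout
transitions. Dwell before commitment counts consecutive observations in the
immediately preceding state — a retraction resets the clock, and a
re-extended mini-sprout starts a fresh dwell — and is also reported in hours
as commitment time minus the first of those observations (entry between
observations is unobservable, so this is the observable lower bound).

`syntheticTrackingCohort()` ships a deterministic synthetic 118-cell table
whose counting statistics emulate tracked VEGF-stimulated vessels:
per-interval mini-sprout-to-sprout conversion of 9/66 (13.6%), 1/34 (2.9%)
and 3/40 (7.5%); final fractions 54/118 retracted, 49/118 mini-sprout,
15/118 sprout (45.8/41.5/12.7%); and 13 of 15 sprouts (86.7%) from newly
formed mini-sprouts, the other two direct from Stalk. It is a synthetic
stand-in — individual trajectories are exchangeable within their summary
classes — used so the counting code can be exercised without measured data.

## Fibronectin neighborhoods

`IntensityMap` objects attach per-cell mean fibronectin intensities and
activity labels (sprout-leading, sprout-following, mini-sprout, quiescent) to
a cell graph. `labelSummary()` reports box-and-whisker statistics per label
with no hypothesis testing. `buildGroups()` delineates seven-cell
neighborhoods as the center plus its six nearest cells by centroid distance,
searched among direct neighbors first and then neighbors-of-neighbors (the
delineation used alongside the original images is not specified; the strategy
is pluggable). `ratioAboveThreshold()` counts the fraction of group members
above an intensity threshold, default 30 (derived as the minimum
sprout-following intensity; `fibronectinThreshold(method = "auto")` recomputes
that rule from the data). The pooled ratio distribution is exactly the
multiset union of the sprout-centered and mini-sprout-centered strata.

## Synthetic generators

* `perfectSaltPepper()` tiles Tips on the even-row/even-column sublattice:
  Tip fraction exactly 1/4, zero Tip contacts, rank-1 Tip distance exactly 1.
* `disorderedPattern()` samples patterns with a fixed Tip count (so the
  realised fraction is within one cell of the target) by Metropolis swap
  moves with energy `adjacencyBias` times the number of Tip–Tip edges,
  annealed linearly from zero. Bias 0 gives i.i.d. placement, for which
  $P(\ge 1\text{ Tip neighbor}) = 1 - (1-f)^6$; large biases approach the
  ordered limit.
* `simulateFateSeries()` runs an absorbing Markov chain per cell
  (Stalk→MiniSprout with `pExtend`; MiniSprout→{maintain, Sprout, Stalk}
  with the given simplex) and returns the mini-sprout cohort.
* `simulateIntensityMap()` draws mean-preserving lognormal intensities with
  label-dependent location (zero SD returns the label means exactly).
* `jitteredGraph()` perturbs hexagonal centroids by uniform jitter and builds
  adjacency as the Gabriel graph (an edge survives if no third centroid lies
  in the circle having the edge as diameter) — a Delaunay-like proximity rule
  that restores the exact hexagonal adjacency at zero jitter, excludes
  corner/point contacts, and is always connected because it contains the
  Euclidean minimum spanning tree. It stands in for segmented experimental
  cell maps.

What the generators do *not* emulate: measurement noise in cell segmentation,
the irregular vessel-surface topology of real endothelium, spatial
correlations between fate transitions of neighboring cells, and any coupling
between fibronectin intensity and the fate dynamics. Tests passing on
generated data therefore validate the estimators and their statistical
calibration, not the biology of real vessels.

## Problem sizes and reproducibility

The default study condition is the 30×30 periodic lattice with 50 randomized
replicates; that is what `scripts/acceptance.R` runs. The test suite exercises
the same code paths at the sizes a unit test needs: full 30×30×50 for the
calibrated-ensemble checks, 16×16 with 3 replicates and a 6-point log-spaced
dose grid (1–1024 ng/ml) for the parameter sweeps, 8×8–12×12 patterns for
selection and spacing properties, and $10^4$ cells for fate-rate recovery.
Every stochastic step is seeded and recorded; rerunning any function with the
same seed reproduces its output exactly.

## Known limitations

* The model is deterministic; molecular noise (Langevin/Gillespie dynamics)
  is out of scope, and the fixed Delta threshold classification relies on
  the clean bimodality that determinism produces.
* The VEGF arm is phenomenological: the activated complex is a quasi-steady
  approximation and the dose axis is meaningful only after calibration
  against a measured Tip fraction.
* At matched Tip fraction the equilibrated patterns show fewer multi-Tip
  clusters (two or three adjacent Tips per Tip) than the experimentally
  reported adjacency probabilities; the shielded mean closest-Tip distance
  is correspondingly below one half cell. Within this model family the mean
  rank-1 distance and the adjacency probability cannot be varied
  independently (see the shielding note above).
* Repulsion selection uses rejection sampling, not exact uniform sampling
  over independent sets; for feasible targets far from the packing limit the
  difference is negligible, and infeasible targets fail loudly.
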