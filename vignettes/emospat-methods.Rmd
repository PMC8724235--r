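---
title: "Methods: spatiotemporal analysis of urban emotion on hexagonal grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of urban emotion on hexagonal grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emospat)
```

## The problem and the unit of observation

The observational unit is a geotagged, timestamped short-text message carrying
exactly one label from the closed six-emotion set
`{happy, angry, sad, fear, surprise, neutral}` and a pre-tokenized word list.
Individual messages are too noisy and too unevenly distributed to analyze
pointwise, so the study area (a bounding box in geographic degrees) is
tessellated into regular hexagons and all statistics are computed on per-cell
emotion *proportions*. Hexagons are used because they give uniform first-order
contiguity (every interior cell has exactly six edge-sharing neighbors at
equal center distance) and the tightest packing of any regular tile.

Three analytic layers sit on top of the grid:

* **ESDA** — where does each emotion concentrate? (global Moran's *I*, local
  Moran's *I* / LISA, Getis–Ord Gi\*);
* **ESTDA** — how does that spatial structure move between time regimes?
  (LISA time paths, transition taxonomy, flow/cohesion);
* **word shifts** — which words drive the lexical difference between emotion
  strata? (Shannon-entropy decomposition).

## Gridding choices

`hex_grid()` keeps whole hexagons whose center falls inside the bounding box;
nothing is clipped, and cells are addressed by integer axial coordinates
(q, r) with deterministic row-major ids, so two runs over the same box give
byte-identical grids. Coordinates stay in geographic degrees with Euclidean
center distances. At city scale (tenths of a degree) the longitude/latitude
anisotropy (about cos(latitude), ~12% at 29° N) distorts hexagons slightly but
identically everywhere, which leaves contiguity — the only geometric input to
every downstream statistic — unchanged; users needing metric cells can
project their coordinates before gridding. `cell_size` is the circumradius
in degrees; neither a canonical size nor an orientation is claimed, both are
parameters (`0.02`° and pointy-top in the examples, giving ~250 cells over a
0.5° box).

Point-in-hexagon assignment is by nearest center (for a hexagonal lattice the
Voronoi diagram of the centers *is* the tessellation), realized by axial cube
rounding plus an explicit nearest-center check over the rounded cell and its
six lattice neighbors. Boundary points equidistant from several centers go to
the lowest cell id — an arbitrary but deterministic rule for a
measure-zero event. Points outside every retained hexagon receive an `NA`
sentinel and are excluded, never errored.

**Minimum-count filter.** Cells with fewer than 20 messages overall are
removed before any statistic is computed (`filter_min_count`, `min_n = 20`,
configurable): proportions estimated from a handful of messages are too
unreliable to classify. The retained-cell count is the *n* in every formula
below.

## Time regimes

Two regime partitions are analyzed: day (06:00–18:00 local, configurable)
vs. night, and weekday vs. weekend (Saturday–Sunday). The synthetic
generator realizes regimes through its timestamps — a uniform date in a
four-full-week window and a uniform second in the day — so the downstream
partition operates on timestamps alone, exactly as it would on real data.

## Spatial statistics

Weights are first-order edge contiguity on the retained cells:
row-standardized (`style = "W"`) for Moran/LISA, binary with self included
for Gi\* — the defaults of the GIS tools practitioners use for these
statistics. Cells that lose all neighbors to the filter are islands: their
spatial lag is 0 and they are flagged.

* **Global Moran's I**: the standard cross-product statistic with
  `E[I] = -1/(n-1)`; inference by random relabeling (999 permutations,
  seeded), reported as a pseudo p-value `(extreme + 1)/(n_perm + 1)`.
* **LISA**: `z_i` standardized with the *population* sd (divide by n), lag
  `= Σ_j w_ij z_j`, `I_i = z_i · lag_i`. With row-standardized weights this
  scaling makes the global–local identity exact:
  `Σ_i I_i = S0 · I` (and `S0 = n` on island-free lattices). Quadrants
  HH/HL/LH/LL come from the signs of `(z_i, lag_i)`; inference is
  conditional permutation (the cell's own value held fixed, neighbors
  redrawn from the rest).
* **Gi\***: the self-inclusive z-score form with analytic mean and variance.
  `hot` / `cold` labels use a two-sided 0.05 level by default, with no
  multiple-testing correction (exposed as `alpha`). Degenerate case: if a
  cell's self-included neighborhood spans the entire study area the
  numerator and variance are both exactly zero and the statistic is defined
  as 0.

## Dynamics: LISA time paths and transitions

Each regime slice re-standardizes the proportion *within the slice*, so a
cell's Moran-scatter position is always relative to the slice mean — the
scatter plot is defined on standardized values, and this keeps the two
slices comparable even when the city-wide emotion mix shifts wholesale
between them. Cell–regime strata with zero messages get the slice mean
imputed (z = 0, the neutral scatter position) rather than erroring; with the
20-message filter this affects only a small minority of cells.

The relative time-path length is

$$T_i = \frac{n \sum_{t=1}^{T-1} d(L_{i,t}, L_{i,t+1})}
             {\sum_{i=1}^{n}\sum_{t=1}^{T-1} d(L_{i,t}, L_{i,t+1})}$$

with `d` the Euclidean distance in the (z, lag) plane — the conventional
choice in the exploratory space-time literature; the defining text of the
statistic leaves `d` unspecified. The mean of `T_i` over cells is exactly 1
(an algebraic identity the tests assert to 1e-9), `T_i = 0` for motionless
cells, and the statistic is invariant to reversing the slice order. Both
regime pairs are two-slice paths (T = 2); the implementation accepts any
T ≥ 2.

Quadrant transitions between the two slices are classified into five types
(I: no change; II: own letter changes; III: neighborhood letter changes;
IV(a): concordant double flip HH↔LL; IV(b): discordant double flip HL↔LH).
The 16 ordered quadrant pairs partition 4/4/4/2/2 across the types — a total
function the tests assert exhaustively. *All* retained cells are classified,
not only significant LISA cells: the summary shares must sum to 1 over the
cells, which pins down this reading. Flow `F = (S_II + S_III)/m` and cohesion
`C = (S_I + S_IV(a))/m` then satisfy `F + C + S_IV(b)/m = 1`; high C means a
locked, path-dependent spatial pattern.

**Volatility hot spots** apply Gi\* to the per-cell *sum* of the six
per-emotion `T_i` values, locating regions where the local spatial structure
of emotion as a whole is most dynamic.

## Word shifts

Strata vocabularies are compared through Shannon entropy in bits,
`H(P) = Σ_τ p_τ log2(1/p_τ)`, on raw relative frequencies with no smoothing:
the convention `p log2(1/p) = 0` at `p = 0` handles out-of-support words and
keeps the decomposition
`Σ_τ δH_τ = H_2 − H_1` with
`δH_τ = p_τ^{(2)} log2(1/p_τ^{(2)}) − p_τ^{(1)} log2(1/p_τ^{(1)})`
*exact* (smoothing would break it). Ranking is by |δH_τ| with a
lexicographic tie-break so output is reproducible. The simpler proportion
shift `p_τ^{(2)} − p_τ^{(1)}` is provided as a companion diagnostic. No
stopword list is applied in the core; `pipeline_config(stoplist = ...)`
filters tokens before the shift. The reference stratum is always named
explicitly by the caller (the pipeline default contrasts every emotion
against `neutral`).

## Classifier evaluation

The evaluation layer is classifier-agnostic: a confusion matrix over the six
labels, one-vs-rest per-class precision/recall/F1 (`F = 2PR/(P+R)`, defined
as 0 when `P + R = 0`, with a warning when a class has no predicted or no
true positives), and multiclass accuracy = trace/total. One published
formulation writes accuracy with true negatives in numerator and denominator;
under one-vs-rest reduction in a multiclass task the standard trace/total is
the quantity whose diagonal consistency per-class recall must match, so that
is what is reported. The shipped `lexicon_classifier()` (majority vote of
keyword matches, `neutral` fallback, fixed-label-order tie-break) exists so
the pipeline runs end to end at desk scale; it is a baseline, not a
contribution — a fine-tuned neural classifier would slot into the same
interface.

## The synthetic generator: what it emulates, and what it does not

`sim_config()`/`generate_messages()` produce corpora with exactly the
structure the analysis assumes:

* **Spatial clustering** — hotspot points are isotropic Gaussians
  rejection-sampled inside the bounding box (share of all points and sd in
  degrees per hotspot), over a uniform background.
* **Emotion mixtures** — a background probability vector (default: the
  marginal proportions of a large urban microblog corpus, happy 31%,
  sad 26%, neutral 20%, angry 18%, surprise 4%, fear 1%); inside a hotspot
  the mixture is convexly pulled toward the target emotion with weight
  `boost`.
* **Regime structure** — optional per-regime mixture multipliers, and
  volatile *regions*: disks whose dominant emotion flips between the two
  slices of one regime pair (planting is spatial because cells only exist
  after gridding).
* **Vocabularies** — per-emotion Zipf-weighted disjoint core tokens (60% of
  mass) plus shared uniform stopwords (40%), giving word shifts and the
  lexicon baseline a known signed structure.

All randomness flows from a single config seed via an isolated RNG scope, so
identical configs give byte-identical tables and the caller's RNG state is
never touched.

What the generator does **not** emulate: road-network and land-use geometry,
temporally bursty posting (events), label noise from an imperfect upstream
classifier, spatially varying vocabulary within a stratum, and message-length
/ user-activity heterogeneity. Passing recovery tests therefore shows the
*statistics* behave correctly when their assumptions hold — not that any
particular real city exhibits the planted patterns.

## Numerical and scale choices

* Standardization uses the population sd throughout (exactness of the
  global–local identity); zero-variance slices are errors, not silent zeros.
* Quadrant boundaries: `z > 0` is "H", `z ≤ 0` is "L" — exact zeros are
  measure-zero after standardization.
* Permutation p-values use the `(extreme + 1)/(n_perm + 1)` convention; 999
  permutations by default, seeded and reproducible.
* The worked examples and the acceptance script use 20,000 messages on a
  0.5° × 0.5° box with 0.02° cells (~245 retained cells at the 20-message
  filter) — large enough that planted hotspots span ~11 cells and recovery
  is stable across seeds, small enough to run in seconds. Unit and property
  tests use 4,000–6,000 messages on coarser grids.
* Tests compare every spatial statistic against independent brute-force
  double-loop oracles on lattices of ≤ 20 cells (tolerance 1e-9), and
  global Moran's I additionally against `ape::Moran.I`.

## Known limitations

* Degree-space geometry: no metric CRS hook is built in; project first if
  hexagon regularity in meters matters.
* Two-slice dynamics: with T = 2 the time path is a single segment, so path
  *shape* statistics (tortuosity, direction) are meaningless and are not
  computed — only relative length and transitions.
* No multiple-testing correction on hot/cold labels; with ~250 cells at
  α = 0.05 about 12 false positives are expected under the null, which is
  why recovery claims are about planted regions, not individual cells.
* The per-cell analysis variable is the emotion *proportion* (activity-
  controlled), not the raw count; analyses that want raw-count hot spots can
  pass counts to `getis_ord_gistar()` directly.
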