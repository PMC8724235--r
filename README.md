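# emospat

Spatiotemporal pattern mining of geotagged emotion data on hexagonal grids.

## What this is for

City-scale studies of population affect increasingly rely on geotagged,
emotion-labeled short-text messages (microblog check-ins). Researchers want to
know *where* each emotion concentrates, *how stable* those spatial patterns
are across time regimes (day vs. night, weekday vs. weekend), and *which
words* distinguish the language of one emotion stratum from another. `emospat`
packages that entire workflow for R users working in spatial epidemiology,
urban analytics and computational social science:

1. **Hexagonal aggregation** — messages are binned into a regular hexagonal
   tessellation (uniform 6-neighbor contiguity, tight packing); cells with
   fewer than 20 messages are excluded as unreliable.
2. **Spatial structure (ESDA)** — per-cell emotion proportions are analyzed
   with global Moran's *I* (permutation inference), local Moran's *I* (LISA,
   with HH/HL/LH/LL Moran-scatter quadrants and conditional-permutation
   pseudo p-values) and the Getis–Ord Gi\* hot/cold-spot statistic.
3. **Spatiotemporal dynamics (ESTDA)** — each cell's LISA coordinate
   L(i,t) = (z_i, lag_i) is tracked between regime slices. The relative
   time-path length

       T_i = n * sum_t d(L(i,t), L(i,t+1)) / sum_i sum_t d(L(i,t), L(i,t+1))

   (Euclidean d, mean exactly 1 over cells) measures local volatility.
   Quadrant transitions are classified into five types — I (no change),
   II (own letter changes), III (neighborhood letter changes), IV(a) (both
   flip concordantly: HH↔LL), IV(b) (both flip discordantly: HL↔LH) — and
   summarized by the spatiotemporal flow `F = (S_II + S_III)/m` and cohesion
   `C = (S_I + S_IV(a))/m`.
4. **Word shifts** — the Shannon entropy `H(P) = Σ p_τ log2(1/p_τ)` of each
   stratum's word distribution is compared between strata; each word's
   contribution `δH_τ = p_τ⁽²⁾log2(1/p_τ⁽²⁾) − p_τ⁽¹⁾log2(1/p_τ⁽¹⁾)` sums
   exactly to `H2 − H1`.
5. **Classifier evaluation** — confusion matrix, accuracy and one-vs-rest
   precision/recall/F1 over the closed six-emotion label set
   {happy, angry, sad, fear, surprise, neutral}, plus a keyword-lexicon
   baseline classifier so the pipeline runs end to end; any model that emits
   one of the six labels per message plugs into the same evaluation.

Because real check-in corpora are typically not redistributable, the package
ships a first-class **synthetic generator**: spatially clustered points with
planted emotion hotspots (truncated Gaussians), regime-dependent mixture
shifts, volatile regions whose dominant emotion flips between regimes, and
disjoint-core per-emotion vocabularies — every downstream stage is testable
with known ground truth.

## Worked example

```r
library(emospat)

cfg   <- planted_demo_config(n_messages = 20000, seed = 1)  # 1 happy hotspot + 1 sad/fear volatile region
msg   <- generate_messages(cfg)
grid  <- hex_grid(cfg$bbox, cell_size = 0.02)               # circumradius in degrees
panel <- filter_min_count(aggregate_panel(assign_points(grid, msg)), min_n = 20)
cells <- sort(unique(panel$cell_id))
w     <- contiguity_weights(grid, cells)                    # row-standardized, <= 6 neighbors

x  <- panel$proportion[panel$regime == "all" & panel$emotion == "happy"]
gm <- global_morans_i(x, w, n_perm = 999, seed = 1)
gs <- getis_ord_gistar(x, w)
```

which prints (seed 1):

```
hex_grid: 247 cells, circumradius 0.02 deg, pointy-top, bbox [115.7, 116.2] x [28.4, 28.9]
spatial_weights: 245 cells, style W, 0 island(s), avg 5.49 neighbors
global Moran I = 0.696 (E[I] = -0.0041, pseudo p = 0.001)
           cold             hot not_significant
             16              28             201
```

The happy proportion is strongly spatially autocorrelated (I = 0.70 against
an expectation of −0.004), and Gi\* flags 28 hot cells — including every cell
of the planted hotspot. Dynamics between day and night:

```r
transition_table(panel, "day_night", w)[, c("emotion", "SF", "SC")]
vol <- volatility_hotspots(panel, "day_night", w)   # Gi* on the summed T_i of all six emotions
```

gives flow/cohesion per emotion (e.g. happy: SF = 0.44, SC = 0.48) and 17
volatility hot cells concentrated on the planted volatile region, whose mean
T_i is ~2.3× the stable background. Finally, the vocabulary contrast:

```r
sh <- entropy_shift(unlist(msg$tokens[msg$emotion == "neutral"]),
                    unlist(msg$tokens[msg$emotion == "happy"]))
print(sh, k = 4)
```

```
word_shift: H1 = 4.2978 bits, H2 = 4.3030 bits, delta = +0.0052 bits
  1 neutral_core01       -0.44362 -====================
  2 happy_core01         +0.44336 +====================
  3 neutral_core02       -0.31880 -==============
  4 happy_core02         +0.31626 +==============
```

The top contributors are exactly the planted core words of each stratum:
neutral-specific words lose entropy mass, happy-specific words gain it.

`run_pipeline(pipeline_config(...), outdir)` chains all stages and writes
the full bundle (messages CSV, panel CSV, six per-emotion GeoJSON hot-spot
layers, two transition tables, volatility layers, word-shift TSVs, and a
JSON run log with seed and parameters).

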