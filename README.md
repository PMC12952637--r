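# boulderreef

Geomorphometry and macroalgal vegetation analysis for man-made boulder
reefs mapped by underwater photogrammetry.

Artificial boulder reefs — natural rock boulders of ~1 m diameter installed
on the seafloor — are used to seed macroalgal beds (kelps, *Sargassum*) on
coasts where they have declined. Whether an individual boulder develops
rich vegetation depends on its substrate (bare sand vs natural
cobble/boulder bottom) and on its local geomorphic setting. `boulderreef`
is for benthic ecologists and restoration practitioners who have (or want
to simulate) a photogrammetric mesh of such a reef plus per-boulder species
observations, and who want the full quantitative chain from mesh to
stratified statistics.

## What it computes

Per boulder, at the summit vertex (highest point inside the annotated
footprint), with edge exclusion near the survey boundary:

* **Relative height** `RH(v) = z(v) − min{ z(u) : ‖u − v‖ ≤ 1.5 m }` —
  height above the deepest vertex in a 1.5 m neighbourhood (m).
* **Surface complexity** — box-counting occupancy: a 3.0 m cube centred on
  the vertex is split into 6³ = 216 half-open 0.5 m cells, and
  `SC(v) = (# cells containing ≥ 1 mesh vertex) / 216`. A 2D mode (6² = 36
  cells) reproduces the planar schematic of the same procedure.

Per reef:

* a rule-based classification of five-species presence/absence into seven
  community types with ordinal **vegetation scores** 0–6 (bare rock …
  perennial *Sargassum* + *U. pinnatifida*), as a priority cascade;
* species prevalence and community tables, overall and by bottom type;
* Welch's t-test of scores between bottom types
  (`t = (x̄₁ − x̄₂)/√(s₁²/n₁ + s₂²/n₂)`, Welch–Satterthwaite df);
* Pearson correlations of score vs each indicator, overall and per
  stratum, with two-sided p from `t = r√((n−2)/(1−r²))`;
* rich (score ≥ 3) vs poor (score ≤ 2) indicator comparisons per stratum.

A deterministic simulator generates the whole study scene — sloping sandy
seafloor, cobble ridges, isolated and piled boulders, bottom-type-dependent
Bernoulli species presence — so everything above runs without field data.

## Worked example

```r
library(boulderreef)

cfg <- terrain_config(extent = c(40, 12), depth_range = c(5, 7.8),
                      ridge_count = 2, n_boulders = 150, mesh_spacing = 0.2,
                      seed = 42)
tr   <- generate_terrain(cfg)
pres <- generate_presence(tr$annotations, presence_model(), seed = 42)
ind  <- boulder_indicators(tr$mesh, tr$annotations)

rec <- pres
i <- match(rec$boulder_id, ind$boulder_id)
rec$relative_height    <- ind$relative_height_m[i]
rec$surface_complexity <- ind$surface_complexity[i]
rec$valid              <- ind$valid[i]

analysis <- run_full_analysis(rec)
print(analysis)
```

```
Boulder-reef vegetation analysis: 150 boulders (86 sand, 64 cobble)

Species prevalence (n, % of stratum):
  U. pinnatifida                 total   51 ( 34.0%)  sand   49 ( 57.0%)  cobble    2 (  3.1%)
  Perennial Sargassum spp.       total   33 ( 22.0%)  sand   31 ( 36.0%)  cobble    2 (  3.1%)
  ...

Mean vegetation score: sand 3.5 (n=86), cobble 1.0 (n=64)
  Welch's t-test sand vs cobble: t = 10.395, df = 128.5, p = <2e-16

Score vs geomorphic indicators (150 boulders with valid indicators):
  relative_height.overall          r = -0.001, p = 0.991 (n = 150)
  ...
```

Reading the output: most canopy-forming species establish on the sandy
stratum, *C. sinuosa* is ubiquitous, and the mean vegetation score is far
higher on sand (3.5) than on cobble (1.0) — the bottom-type contrast the
analysis is built to quantify. The correlations are near zero here because
the default presence model is covariate-free: species presence depends only
on bottom type, so score–geomorphology correlations are null by
construction (planted indicator effects are available through
`presence_model(beta_rh = ...)`).

File-based orchestration (`simulate_survey()`, `compute_indicators()`,
`analyze_survey()`, `render_vegetation_map()`) reads and writes PLY/OBJ
meshes, annotation/indicator CSVs, presence tables, JSON reports and a
GeoJSON vegetation map, each run accompanied by a manifest with seed,
configuration and output checksums. A thin command-line front end is
installed at `inst/scripts/reef-pipeline.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/reef-pipeline.R", package="boulderreef"))') \
    all --out-dir reef_out --seed 4 --n-boulders 60
```

See the vignette (`vignettes/boulder-reef-analysis.Rmd`) for the models,
conventions and simulator calibration.

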