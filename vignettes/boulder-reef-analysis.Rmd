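---
title: "Geomorphic indicators and macroalgal vegetation on man-made boulder reefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geomorphic indicators and macroalgal vegetation on man-made boulder reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boulderreef)
```

## The problem

Man-made boulder reefs — natural rock boulders of roughly 1 m diameter
installed on the seafloor — are a standard intervention to seed macroalgal
beds (kelps, *Sargassum*) on coasts where they have declined. Whether a
given boulder develops rich vegetation depends not only on the substrate it
sits on (bare sand versus natural cobble/boulder bottom) but on its local
geomorphic setting: how far it stands above its surroundings, and how
rugged its immediate neighbourhood is. Underwater photogrammetry makes both
measurable: a diver-collected image survey yields a georeferenced
triangulated mesh of the reef at centimetre resolution, and every installed
boulder can be annotated and scored for its vegetation.

`boulderreef` implements that analysis chain: mesh input and
georeferencing, two per-boulder geomorphic indicators, a rule-based
vegetation classification, and the stratified statistical battery linking
the two — plus a synthetic generator so the whole pipeline runs and is
tested without any field data.

## Georeferencing

A photogrammetric model comes out of reconstruction in an arbitrary local
frame: unknown uniform scale, orientation and offset. `georeference()` fits
a 7-parameter similarity transform from (i) one known inter-point distance
between two reference markers, which fixes the scale exactly, and (ii) at
least three non-collinear reference points of known depth, which fix the
tilt and the vertical offset. With exactly three references the depth
constraints are met exactly; with more they are met in least squares and
the per-reference residuals and their RMS are attached to the result rather
than discarded.

Two degrees of freedom are genuinely unobservable from depths alone:
rotation about the vertical axis (yaw) and horizontal translation. The
fitted transform therefore uses the *minimal* rotation taking the recovered
up-direction to +z and leaves the horizontal origin untouched: the output
mesh is metrically correct (scale, tilt, depth) and its horizontal frame
stays as close to the model frame as possible. Supplying no known distance
is an error by design — depth references cannot fix scale, and silently
assuming unit scale would corrupt every downstream indicator.

Coordinates follow one convention throughout: z is elevation in metres,
negative below the sea-surface datum, so depth = −z and "the deepest point"
is simply the minimum of z.

## Geomorphic indicators

Both indicators are evaluated at each boulder's **summit** — the
highest-elevation mesh vertex inside the annotated circular footprint, with
ties broken deterministically by the lowest vertex index. Boulder
annotation (centre, footprint radius, bottom type) is an input; the package
deliberately does no automatic boulder segmentation.

**Relative height** of a vertex is its height above the deepest vertex
within a 1.5 m neighbourhood. The neighbourhood is a 3D Euclidean radius
query on the vertex cloud; at 1.5 m radius over sub-metre relief the
difference from a purely horizontal query is negligible, and the choice is
isolated inside `relative_height()` with the radius exposed in
`indicator_config()`. The value is always ≥ 0 and is 0 exactly when the
vertex is co-deepest in its own neighbourhood.

**Surface complexity** is a box-counting occupancy fraction: an
axis-aligned cube of side 3.0 m centred on the target vertex is divided
into 6³ = 216 cubic cells of 0.5 m side, and the fraction of cells
containing at least one mesh vertex is returned. Occupancy is *vertex*
based — a cell crossed by a triangle but containing no vertex does not
count — which ties the measure to the sampling the mesh actually provides.
A planar variant (`dims = 2`, 6² = 36 cells) reproduces the
two-dimensional schematic version of the procedure: nine occupied cells of
36 give 0.25.

Numerical conventions that matter for reproducibility:

* Cells are half-open `[a, a + cell)` on each axis, anchored at the
  window's minimum corner, so boundary vertices are assigned
  deterministically. Cell membership is computed with `findInterval()`
  against the explicit cell edges, which keeps floating-point behaviour
  identical to testing `p >= a && p < a + cell` directly; the test suite
  holds the implementation to *exact* agreement with an unoptimised
  cell-by-cell enumeration.
* The target vertex occupies its own cell, so valid values lie in
  [1/216, 1] with the defaults.
* Box counting is monotone under vertex insertion, and both indicators are
  invariant under rigid vertical translation; both properties are tested.

**Edge exclusion.** Near the rim of the mapped area the analysis window
extends past the surveyed surface and indicator values would be biased low.
A vertex is valid if and only if its full horizontal 3.0 m window lies
inside the mesh's horizontal footprint, taken as the 2D convex hull of the
projected vertices. Only the larger of the two supports is tested: the
3.0 m window contains the 1.5 m disc, so a window-valid vertex is valid for
both indicators. Boulders whose summit fails the test keep their row in the
output with `valid = FALSE` and no indicator values — no silent drops.

## Vegetation classification

Five taxa are scored as present/absent on each boulder: *Undaria
pinnatifida*, perennial *Sargassum* spp., *Sargassum horneri*, *Colpomenia
sinuosa* and geniculate coralline red algae. `classify_vegetation()` maps
the 32 possible combinations onto seven community types with ordinal scores
0–6, reflecting persistence, canopy size and structural complexity:

| Score | Community | Rule (first match wins) |
|---|---|---|
| 6 | *Sargassum* & *U. pinnatifida* | perennial *Sargassum* and *U. pinnatifida* |
| 5 | *Sargassum* | perennial *Sargassum* |
| 4 | *S. horneri* | *S. horneri* |
| 3 | *U. pinnatifida* | *U. pinnatifida* |
| 2 | Coralline red algae | coralline algae |
| 1 | *C. sinuosa* | *C. sinuosa* |
| 0 | Bare rock | nothing present |

The priority cascade is the unique total function consistent with the
published scoresheet's wildcard ("+/−") patterns; the test suite checks all
32 combinations against an independent expansion of those patterns.

The **rich/poor dichotomy** binarises the score for group comparisons. The
source description ("greater than 3 … less than 2") read literally leaves
scores 2 and 3 unassigned while the analyses that use the dichotomy treat
it as exhaustive; `richness_dichotomy()` therefore uses score ≥ 3 = rich,
≤ 2 = poor, placing the boundary between the crustose/ephemeral communities
and the canopy-forming ones. This is flagged here deliberately: it is the
one classification choice not forced by the published rules.

Presence tables are read and written in a fixed CSV schema (one column per
taxon with `+`/`−` tokens, a bottom-type column, optional community and
indicator columns). The reader accepts the Unicode minus, en dash and ASCII
hyphen; the writer always emits ASCII and says so in a comment line. A
`boulder_id` column is carried so indicator tables join unambiguously.

## Statistics

The battery in `run_full_analysis()` mirrors the study design:

* per-species prevalence and per-community counts, overall and stratified
  by bottom type (percentages half-up rounded to one decimal, matching the
  reporting style);
* mean vegetation score per bottom type, compared with **Welch's t-test**
  (unequal variances, Welch–Satterthwaite df, two-sided p);
* **Pearson correlations** between score and each indicator, overall and
  within each bottom type;
* Welch comparisons of each indicator between rich and poor boulders
  within each bottom type.

Scores are treated as numeric 0–6 in the tests and correlations, exactly
as in the study being reproduced; no multiple-testing correction is
applied (none was used there either) and the report labels all p-values as
raw. The Welch and Pearson computations are delegated to
`stats::t.test()` and `stats::cor.test()`; the test suite independently
recomputes both from the closed-form formulas to 10⁻¹⁰ and checks the
Welch test's type-I error over 2,000 null replicates at a fixed seed, where
the rejection rate at α = 0.05 must land in [0.04, 0.06]. Degenerate
inputs (both samples zero-variance, constant correlates) raise explicit
errors rather than NaNs.

## The synthetic generator

`generate_terrain()` and `generate_presence()` exist so every stage of the
pipeline — including edge exclusion and the stratified statistics — can be
exercised end to end, deterministically, with no survey data. The scene
they emulate follows the study conditions wherever those are stated, and
fills the gaps with fixed, documented choices:

* **Stated conditions:** an 80 × 20 m site sloping from 4.5 m to 9.2 m
  depth; artificial boulders of 1 m diameter, isolated or piled; a default
  mesh spacing of 0.08 m (matching a 7.9 cm mean vertex resolution); and
  per-bottom-type species prevalences taken from the surveyed reef (e.g.
  *C. sinuosa* 0.793 on sand, 0.797 on cobble; *U. pinnatifida* 0.584 on
  sand but 0.057 on cobble).
* **Simulator choices:** terrain noise as a sum of eight smooth random
  cosines (sd 0.1 m, wavelengths 5–20 m); five cobble ridges of Gaussian
  cross-section (height 0.4 m, σ = 2.0 m) crossing the slope, roughened
  with 0.2–0.5 m cobble-sized caps — ridge coverage is set so that roughly
  half the installed boulders sit on cobble, matching the surveyed
  550/561 sand/cobble split; boulders as spherical caps with height =
  radius, piles as 2–4 overlapping caps with a raised centre, which
  suffices to produce the qualitative contrasts the indicators must detect
  (piles → higher surface complexity, isolated boulders → cap-height
  relative height).
* **Placement** uses a jittered grid of slots rather than rejection
  sampling: installed reefs are laid out deliberately, and a planned
  layout is the only way to reach the real density (~0.7 boulders/m²)
  without overlap pathologies. Requests exceeding the placeable area are
  refused with an error.
* **Determinism:** one integer seed governs a run; each stage (noise,
  ridges, placement, presence draws) derives its own sub-seed from it, so
  identical configuration reproduces byte-identical files.

The presence model is covariate-free by default — bottom type is the only
driver, which is exactly what the published prevalences can calibrate.
Logit-scale effects of the indicators (`beta_rh`, `beta_sc`) are opt-in
and are used by the power test: with a +2.0 per-metre relative-height
effect on perennial *Sargassum*, the cobble-stratum score–height
correlation must be recovered (positive, p < 0.05) in at least 80% of 50
seeded replicates at the surveyed sample sizes.

What the generator does **not** emulate: real boulder shapes and scanned
micro-relief, spatial autocorrelation of species occurrence, grazing,
succession, or any hydrodynamics. Passing tests therefore demonstrate that
the software computes its quantities correctly and recovers effects it
plants — not that the ecological conclusions transfer to any particular
real reef.

## Problem sizes and tolerances

The test suite runs on deliberately small scenes: oracle-equivalence
meshes of ≤ 2,000 vertices (where both indicators must match exhaustive
brute-force recomputation exactly), a miniature 16 × 8 m end-to-end scene
at 0.25 m spacing, and a 0.5 m-spacing full-density scene for the
1,111-boulder bookkeeping check. Mesh I/O stores ascii PLY/OBJ coordinates
as full-precision doubles and binary PLY as float32 (the conventional PLY
vertex type), so one binary round trip quantises once and is bit-stable
thereafter. Georeferencing recovery is asserted to 10⁻⁶ m RMS on exact
references, and idempotence to 10⁻⁹ m.

## Known limitations

* The horizontal-area summary sums horizontally projected triangle areas,
  which equals the footprint area for non-overhanging (heightfield-like)
  surfaces — all this pipeline consumes — but would double-count true
  overhangs.
* Edge exclusion uses the convex hull of the footprint; a strongly concave
  survey boundary would be treated as if filled.
* Yaw and horizontal offset of a georeferenced mesh are conventions, not
  measurements (see above); downstream indicators are invariant to both.
* The classifier is exactly the published scoresheet; it cannot express
  partial cover or abundance, only presence/absence.
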