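---
title: "Methods: multimodal service-area accessibility and facility point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal service-area accessibility and facility point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`medaccess` measures the spatial accessibility of medical facilities with
the *service-area method*: from the facilities of a class, compute the set
of locations reachable within a travel-time threshold along a multimodal
transport network, and report per district the fraction of area (`SAR =
sa/ta`) and of population (`SPR = sp/tp`) that the service area covers.
This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices, so that results can be interpreted —
and challenged — precisely.

## The multimodal travel-time graph

Three modes coexist in one directed graph with symmetric costs (seconds):

* **walk edges** — every road centreline segment, traversable both ways at
  `v_walk` (default 1.2 m/s, a conservative urban walking speed that also
  absorbs slope effects in hilly terrain);
* **access edges** — each station contributes one *platform node per line*;
  a platform connects to the nearest walk node by an access edge whose cost
  is the straight-line snap distance walked at `v_walk`. Reaching a vehicle
  therefore always costs walking time; boarding itself is free;
* **ride edges** — between consecutive stations of a line, at the mode
  speed (`v_bus` 40 km/h, `v_rail` 70 km/h defaults, reflecting mountainous
  urban operation) **plus one dwell** (`dwell_s`, default 30 s).

Dwell placement is a modelling decision: the stop time is embedded in every
ride edge, so boarding at the first station incurs no dwell and each
traversed stop incurs exactly one. Alternative placements (dwell at
boarding, dwell at termini) would shift every transit path by a constant
and do not change ranking between modes. No waiting or headway time is
modelled; travel times are therefore lower bounds for passengers who just
miss a vehicle.

Stations (and facilities) snap to the nearest walk *node*, not to an
interior point of an edge. On grid-like networks the induced error is at
most half a block; the `snap_tolerance` (default 500 m) turns silent
mis-snapping into an explicit error. Transfers between lines happen by
walking through the shared anchor node, so a transfer costs the sum of the
two access walks.

Where a line's geometry matters, an alignment polyline can be supplied to
`add_ride_edges()`; inter-station distances are then measured along the
polyline (stations are projected onto it), otherwise they are Euclidean.
An alignment shorter than the straight-line station distance is rejected.

## Isochrones and the accessibility ratios

`multi_source_reach()` runs one Dijkstra expansion from a virtual
super-source connected to every snapped facility of a class (the source's
initial cost is its snap-distance walking time). This is equivalent to the
union of per-facility service areas but computed in one pass. For a time
budget `b`:

* a node is *reached* if its minimal cost is at most `b`;
* a walk or access edge is covered from each end by the fraction of its
  cost that the remaining budget affords (full coverage when the fractions
  sum to at least one);
* ride edges are all-or-nothing — passengers cannot alight mid-segment.

Because node costs do not depend on the budget, the covered fractions are
monotone in `b`; reach sets, isochrones and the ratios built from them nest
across thresholds *by construction*, not as a numerical accident.

The *service area* is the union of round-capped buffers of half-width
`buffer_width` around the covered walking portions. In-vehicle (ride)
segments contribute reachability but no geometry: a rail line passing over
a neighbourhood without a station does not serve it. The region is kept
implicit — a point belongs to the service area iff it lies within
`buffer_width` of a covered portion — which makes membership exact and
nesting preserved; discretised outline polygons are only a display/export
format (`coverage_outline()`).

All areas and populations are evaluated with one **cell-centre rule** on
one analysis grid (the population raster): `ta`/`tp` count the cells whose
centres fall in the district, `sa`/`sp` the subset whose centres also fall
in the service area. Using the same rule for numerator and denominator
makes the ratios exact at the extremes (a region containing the district
gives `SAR = 1`) and keeps `SAR` and `SPR` mutually consistent. A district
with no populated cell reports `SPR = NA`, not 0.

`buffer_width` must be commensurate with the spacing of the walking
network: buffers narrower than half the typical street spacing leave holes
between streets that the cell-centre rule then samples, deflating `SAR`.
For the synthetic 500 m street grid the run-configuration default is 250 m
(service polygons fill each reached block); for dense real road networks a
narrower buffer (the 50 m function default) is appropriate. The width is
recorded in every output, so ratios are only compared across runs with
equal widths.

## Point-pattern statistics

**Nearest-neighbour ratio.** `R = r1bar/rebar` with
`rebar = 0.5 * sqrt(A/n)`. The plain (uncorrected) form is used: points
near the boundary have artificially distant neighbours, which biases `R`
upward by roughly `0.05 * P / (n * sqrt(A/n))` for perimeter `P`; at the
sizes analysed here (hundreds of points) the bias is about 2 % and is
absorbed by the tolerances of the regime checks. Classification uses a
band of half-width `tolerance` (default 0.01) around 1: `aggregation`
below, `uniform` above, `random` inside — strict equality with 1 is not
testable on data. Observed distances come from a uniform-grid spatial
index with expanding ring search; the test suite verifies it against an
O(n²) scan.

**Quartic kernel density.** The surface is the sum over points of
`3 (1 - (d/r)^2)^2 / (pi r^2)` for `d < r`, evaluated at cell centres
(no partial-cell weighting). Each point's kernel integrates to one over
its disc, so the surface has units points · m⁻² and total mass `n` for
interior patterns; the kernel's pointwise definition leaves the
normalisation of the *sum* open, and this summed (per-point) convention is
the one adopted. A radius not larger than the cell size triggers an
undersampling warning. No bandwidth selection is attempted: `r` is a
reporting choice, not an estimate.

**Mean centre and standard deviational ellipse.** The ellipse uses the
population covariance (`1/n`; the sample `1/(n-1)` form is available as
`ddof = 1`). Axes are the square roots of the eigenvalues — one standard
deviation, with no cartographic scaling constant (some GIS renderings
multiply by √2; comparisons should check this). Rotation is the angle of
the dominant eigenvector, reported in `[0, pi)`; a perfectly isotropic
pattern has no defined axis and reports 0, a collinear pattern returns
`sigma_minor = 0` with a `degenerate` flag rather than an error. Rotation
equivariance and trace invariance are asserted in the tests.

## The synthetic city

The generator produces study regions with the statistical structure the
analysis assumes, so every stage is testable without proprietary map data:

* a `grid_nx × grid_ny` street lattice (default 25 × 25 intersections,
  500 m blocks → a 12 × 12 km extent), connected by construction;
* **districts** as the Voronoi partition of uniformly drawn seeds (default
  9), clipped to the extent — irregular convex districts that exercise the
  area-intersection code the way real administrative boundaries do;
* a **population raster** (250 m cells) as a sum of Gaussian centres
  normalised within the extent so mass is conserved exactly; the default
  three centres totalling one million residents make the city polycentric;
* **facility point patterns** per class: `uniform` (binomial process),
  `thomas` (uniform parents, Gaussian offspring; offspring falling outside
  the extent are *resampled*, not clipped, so each class has exactly its
  requested `n`) and `lattice` (regular grid, the dispersed extreme).
  Default class counts (8 tertiary-A … 300 pharmacies) and cluster scales
  (700–1800 m) are free parameters chosen to span the observed range from
  rare, strongly clustered flagship hospitals to dense retail pharmacies;
  published sources report totals, not per-class counts, so these are
  plausibility choices, not calibrated values;
* **transit** on grid corridors: two rail lines crossing mid-city
  (1500 m station spacing) and four bus lines on the quarter corridors
  (500 m spacing), stations ordered along the corridor
  (`floor(L/spacing) + 1` per line).

A `city_params()` object plus its seed determines the city bit for bit
(`withr::with_seed` scopes the RNG), which the determinism tests rely on.

The generator deliberately does **not** emulate: real road topology
(one-ways, grade separation, dead ends), terrain, timetable variation,
demand behaviour (facility choice, capacity), or population displacement
between census and raster vintages. Passing tests therefore demonstrate
the correctness of the algorithms and the qualitative regimes (clustered
classes score `R < 1`, accessibility grows with threshold, transit helps),
not the numeric accessibility of any real city.

## Numerical choices

* Voronoi cells are computed exactly by half-plane clipping of the extent
  rectangle against all perpendicular bisectors; areas are shoelace sums,
  and the cells tile the extent to relative 1e-9.
* District membership on shared boundaries goes to the first matching
  polygon (deterministic); points lost to floating-point grazing fall back
  to the nearest district seed.
* Walk-edge endpoints are merged when within 0.01 m; zero or negative
  length edges are rejected with their ids reported.
* Quadrature: region areas use cell-centre counting at a stated cell size
  (stadium-shaped buffers reproduce their closed-form area to 1 % at a
  cell of buffer/10 or finer); the accessibility ratios use the population
  raster's own grid.
* Degenerate inputs: coincident points contribute zero nearest-neighbour
  distance with a warning; an all-coincident pattern short-circuits to
  zero distances; `tp = 0` districts yield `NA` ratios; empty reaches give
  empty coverages with zero area.

## Sizes used by the tests and acceptance script

Chosen as the package's own verification design: reach is compared against
exhaustive simple-path enumeration on 50 random graphs of 6–12 nodes;
the nearest-neighbour regimes use a 10 × 10 lattice (`R = 2` exactly, up to
edge effects within ±0.05), 200 CSR replicates of `n = 500` (mean `R`
within [0.95, 1.05] of the Clark–Evans expectation), and a 400-point
Thomas pattern (`R < 1`); the kernel mass check uses a cell of `r/20`;
the full accessibility run uses the default 625-intersection city with 118
stations; byte-level determinism is checked on an 8 × 8 city run twice.

## Known limitations

* No edge-corrected nearest-neighbour statistics (Donnelly/guard area) —
  the uncorrected form is the one commonly reported with GIS tooling and
  keeps `R` comparable with published tables.
* Service-area polygonisation is a buffer union, not a proprietary GIS
  service-area polygon; absolute `SAR` values depend on `buffer_width`.
* Ratios are evaluated at the population raster's resolution; districts
  much smaller than a few cells will be noisy.
* One-way streets, turn penalties, timetables/headways and facility
  capacity are out of scope.
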