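---
title: "A center-based model of epidermal homeostasis on structured substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A center-based model of epidermal homeostasis on structured substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epidermsim` simulates interfollicular epidermis as a three-dimensional
center-based (off-lattice) system. Each keratinocyte is a particle with a
position, an axisymmetric ellipsoid shape `(a, a, c)`, and a lifecycle state.
Stem cells sit anchored on a basement membrane of configurable geometry;
their daughters are pushed upward by continued proliferation, differentiate
on the way, flatten into corneocytes that pack into a stratum-corneum sheet,
and are shed from the free surface. Homeostasis — a stationary cell count
with balanced production and shedding — is an emergent property of the
coupled mechanics and lifecycle rules, not an imposed constraint.

The scientific question the package addresses is how the *geometry of the
substrate* (the basement membrane, or a textile scaffold standing in for
the dermal papillary undulation) controls the thickness of the living layer
and the stratum corneum. The packaged experiments compare a flat membrane
against sinusoidal undulations and against a panel of textile fiber
geometries, using histology-like readouts.

### Mechanics

Cells move by overdamped dynamics: `dx/dt = F / gamma + noise`. Forces are

* **Pairwise contact**: linear repulsion `k_rep (R - d)` below contact and
  linear adhesion up to `adh_range_um` beyond contact, along the center
  line. The contact distance `R` is the sum of direction-dependent
  ellipsoid radii `r(u) = a c / sqrt(c^2 sin^2(theta) + a^2 cos^2(theta))`
  (theta measured from the vertical), a cheap anisotropic approximation
  that lets flattened corneocytes present a thin profile vertically and a
  wide one laterally, so they stack into sheets without a full
  ellipsoid-ellipsoid contact solver.
* **Membrane contact**: cells whose vertical clearance above the membrane
  surface is less than their vertical semi-axis are pushed out along the
  surface normal with stiffness `k_mem`.
* **Stem anchoring**: stem cells are *attached* to the membrane. They feel
  a linear spring toward their on-surface anchor point and are exempt from
  the membrane contact repulsion. The exemption is deliberate: an anchored
  stem resting at zero clearance would otherwise feel a constant outward
  push and equilibrate well above its anchor, which contradicts the
  intended picture of basal cells held on the membrane (hemidesmosome-like
  attachment). With the exemption, an undisturbed stem rests exactly at
  its anchor.

Thermal noise acts only on proliferative, spinous and granular cells:
corneocytes are dead and mechanically passive (they are pushed from below),
and stems are anchored.

Integration is explicit Euler-Maruyama with `dt_h = 0.02` h. A runtime
guard limits any single-step displacement to half a cell radius. Rare force
spikes (for instance two daughters placed almost coincidentally by
neighbouring stems) are handled by adaptive halving of the timestep for the
affected step, down to `dt/16`, with forces recomputed at every sub-step;
if even that overflows, the run aborts with a diagnostic naming the cell.
Lateral boundaries are periodic (minimum-image convention); the vertical
direction is open. Neighbour search uses a uniform spatial hash grid whose
bin size covers the largest possible interaction distance
(`2 a_max + adh_range_um`), and grid-accelerated force sums are verified
against an all-pairs oracle in the test suite.

### Membrane geometries

Heights are always evaluated on laterally wrapped coordinates, so every
membrane is periodic with the domain by construction.

* **flat** — the zero surface.
* **sinusoidal** — the separable product
  `h(x, y) = (A/2) sin(2 pi x / lambda) sin(2 pi y / lambda)`, an isotropic
  in-plane undulation whose peak-to-trough excursion equals the amplitude
  `A`. A one-dimensional groove variant (`grooves = TRUE`) is available for
  sensitivity checks. The product form was chosen over grooves as the
  default because dermal papillae are dome-like rather than ridge-like.
  When the wavelength does not divide the domain, drivers snap the domain
  per condition: the nearest multiple of `lambda` at or below twice the
  target for `lambda <= target`, and `lambda/2` above it (the product
  sinusoid tiles continuously, with a slope kink, at half periods).
* **fiber_grid** — a textile scaffold modeled as two orthogonal families of
  cylinders of diameter `fiber_thickness_um` resting on the base plane,
  axes spaced `fiber_thickness_um + fiber_interval_um` apart; the surface
  is the upper envelope. Weave over/under structure is ignored because the
  substrates are characterised only by fiber thickness and inter-fiber
  interval. The packaged preset table carries the ten textile geometries
  plus a `"papillary"` preset (51 um ridge height, 105 um interval) with
  the measured human papillary-layer geometry.

Stem cells are seeded on a jittered hexagonal lattice in the plane
(projected onto the surface), not by a Poisson process, to avoid
initialization artifacts from random clumping; density is set by the
spacing (default 10 um, one cell diameter).

### Lifecycle

The per-cell state machine is `STEM -> (spawns PROLIF) -> SPINOUS ->
GRANULAR -> CORNEOCYTE -> shed`, with no skips and no reversals; stems
never transition and are never removed.

* **Division** is an exponential clock with mean `division_period_h = 12`
  h, suppressed entirely while more than `crowding_cap` neighbours lie
  within one cell diameter of the stem. Daughters are placed
  `daughter_offset_um = 5` um away in a uniformly random upward-hemisphere
  direction.
* **Differentiation** is positional: a proliferative cell becomes spinous
  once its vertical clearance above the membrane exceeds
  `diff_height_um = 12` um (about one cell diameter above the basal
  layer), standing in for loss of membrane contact.
* **Spinous and granular residence** are exponential clocks with means
  24 h each.
* **Flattening**: on cornification the aspect ratio `q = c/a` relaxes
  exponentially toward `target_aspect = 0.2` with time constant 6 h, with
  the semi-axes recomputed from `q` so the volume `a^2 c = r0^3` is exact
  at every step (no numerical drift by construction).
* **Desquamation**: corneocytes carry an exponential clock (mean
  `desquam_dur_h`) whose events are honoured only when the cell is
  *surface-exposed* — no other cell center within a 45-degree upward cone
  of height `3 r0`. Interior corneocytes are therefore never removed and
  the stratum corneum is shed coherently from the top.

An optional per-cell calcium proxy (disabled by default) relaxes toward a
height-dependent target — zero at the membrane, one above the
differentiation height plus one cell diameter — with a 1 h time constant,
and scales the spinous-to-granular rate. It is a deliberately minimal
scalar stand-in for intracellular calcium dynamics, provided as a feature
flag so that runs without it are bitwise identical to a build that lacks
the field.

### Choosing the homeostasis-critical defaults

The division, residence and shedding laws above are conventional
center-based reconstructions; the package's defaults were completed from
the model's own balance requirements, and two of them deserve explanation
because naive choices fail qualitatively:

* **`crowding_cap = 5`.** In dense tissue a stem's neighbour count within
  one cell diameter is distributed over 2-9 with mean about 6. A cap well
  above that range never binds, so division runs at full rate (about 10
  cells/h from 120 stems on the 100 x 100 um domain) against a
  surface-limited shedding capacity of order 1 cell/h, and the tissue
  grows without bound. A cap of 5 sits on the steep flank of the measured
  neighbour-count distribution: when the basal region densifies, most
  stems exceed the cap and division throttles; when shedding thins the
  tissue, stems drop below it and production resumes. That steepness is
  what makes influx track removal.
* **`desquam_dur_h = 16`.** Shedding capacity is (number of exposed
  corneocytes) / (surface residence time). The residence time also sets
  the horizon over which the stratum-corneum standing stock builds to its
  stationary level: at 72 h the capacity (about 1 cell/h) is below even
  the fully throttled division flux and the stratum corneum grows
  indefinitely; at 24 h the count becomes stationary only after about
  700 h; at 16 h the tissue is stationary from roughly 350 h — within the
  500 h study window used throughout — while still carrying a thick
  standing stratum corneum (several hundred corneocytes).

### Why undulation thickens the tissue in this model

On a curved membrane, stems seeded at fixed *planar* density are farther
apart in three dimensions (their separation is stretched by the surface
slope), so fewer of a stem's neighbours fall inside the crowding radius and
division is suppressed less often than on a flat membrane; the valleys also
provide extra volume below the mean surface that the tissue fills. Both
effects scale with surface steepness, i.e. they grow with amplitude and
shrink with wavelength — which is exactly the regime relationship the
sweep experiment quantifies with rank correlations.

## Analysis readouts

* `count_layers()` partitions a snapshot into cornified cells (stratum
  corneum) and living keratinocytes; the counts always sum to the total.
* `section_areas()` mimics the histological quantification: cells
  intersecting a 10 um slab are rasterised as their `(a, c)` ellipse
  cross-sections onto an (x, z) pixel grid (default 0.25 um pixels),
  pixels at or below the membrane/fiber profile are masked out (the
  analogue of removing fiber cross-sections from stained-section images),
  and areas are reported in um^2 per 100 um of section length. Where a
  corneocyte and a living cell contest a pixel, the corneocyte wins,
  mirroring scoring of compacted stratum corneum overlying living layers.
  Units are um^2 per 100 um of section; the rasterisation is verified
  against a fine-grid oracle (0.05 um pixels) to 1%.
* `thickness_profiles()` bins the domain laterally; per tile, living
  thickness is the highest living-cell top minus the membrane height, and
  stratum-corneum thickness is the highest corneocyte top minus the living
  top. Interface roughness is the population standard deviation of the
  interface height over tiles (population, not sample, so constructed
  fixtures with +/- d offsets give exactly d). Empty tiles contribute zero
  thickness, so callers should choose bins coarse enough to contain cells;
  the experiment drivers use 10 bins per axis on 100 um domains.
* `render_section()` draws sections with the conventional color code —
  membrane green, living cells purple, cornified cells red.
* `compare_conditions()` applies one-way ANOVA with Tukey HSD at
  alpha = 0.05, the standard multi-condition morphometry analysis.

## Experiments and reproducibility

All experiment drivers use a *paired-seed* design: replicate `r` of every
condition uses seed `base_seed + r - 1`, so condition contrasts are paired
and Monte-Carlo variance cancels in the comparison. Every run is bitwise
reproducible from its arguments and seed: all randomness flows through R's
RNG, cells are processed in id order, and two runs with the same seed give
identical snapshots.

The default experiment scale is a 100 x 100 um domain (one-ninth the area
of the full 300 x 300 um region of interest rendered in full-scale runs)
for 500 simulated hours with snapshots every 25 h — long enough for about
40 stem division periods and several complete stratum-corneum turnovers.
The flat-vs-sinusoidal driver defaults to amplitude 50 um and wavelength
100 um, matching the measured human papillary geometry (51 um ridge
height, 105 um interval, rounded) and the best-performing textile preset
(60 um fibers, 101 um interval); `full_roi = TRUE` runs the full 300 um
extent. The sweep driver uses amplitudes {10, 30, 50} um and wavelengths
{60, 100, 200} um with per-condition domain snapping as described above,
and reports Spearman rank correlations of mean living thickness with
amplitude and with wavelength. The reduced problem sizes used by the test
suite and the acceptance script (one to five replicates; 200-500 h for
the study-scale checks, shorter for structural ones) are
the package's choice of desk-scale defaults; the drivers record the domain
and scale used in every report.

The textile panel runs the fiber-grid presets against a flat control and
reports means, a thickness ranking and Tukey flags versus control. It
deliberately makes no claim about which textile ranks first: the
lifecycle and force constants are reconstructions, not fitted parameters,
so only ordering- and regime-level statements are meaningful.

## What the simulations do and do not show

The synthetic tissue emulates: stem-driven stratified growth, positional
differentiation, corneocyte flattening into a coherent sheet, surface
shedding, and the geometric coupling between substrate undulation and
tissue thickness. It does not emulate: transit-amplifying divisions,
apoptosis, lateral lineage competition, real calcium reaction dynamics,
substrate deformation, melanocytes or immune cells, or any molecular
marker. Passing tests therefore demonstrate internal consistency and the
geometry-thickness mechanism under the model's assumptions — not
quantitative agreement with any particular wet-lab measurement.

## Numerical notes

* Volume conservation under flattening is exact by construction (semi-axes
  are derived from the aspect ratio each step); the suite still asserts
  drift below 1e-8 over 1e4 steps.
* Coincident cell centers (distance < 1e-6 um) are resolved by a
  deterministic hash-seeded direction, antisymmetric in the pair, never
  NaN.
* The contact-energy surrogate (sum of squared overlaps plus squared
  membrane penetrations) is non-increasing under noise-free, adhesion-free
  relaxation; with adhesion enabled the statement does not hold from
  spread-out initial conditions (adhesion deliberately creates contacts),
  so the test disables adhesion.
* The displacement guard, sub-stepping and the grid/oracle equivalence are
  exercised directly by the test suite.
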