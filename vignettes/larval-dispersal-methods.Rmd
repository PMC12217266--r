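---
title: "Methods: Lagrangian larval dispersal and reef connectivity"
author: "reefdrift"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`reefdrift` estimates physical connectivity between coral reef complexes by
tracking virtual larvae as passive Lagrangian particles in gridded surface
ocean currents. The model has three layers.

**Transport.** A particle at position $\mathbf{x}$ moves by

$$\mathbf{x}_{t+\Delta t} = \mathbf{x}_t + \Delta t\,
\mathbf{u}\!\left(\mathbf{x}_t + \tfrac{\Delta t}{2}\mathbf{u}(\mathbf{x}_t, t),\;
t + \tfrac{\Delta t}{2}\right) + \boldsymbol{\eta}_t ,$$

the explicit-midpoint (second-order Runge–Kutta) scheme, with
$\boldsymbol{\eta}_t$ an isotropic Gaussian random-walk increment of per-axis
standard deviation $\sqrt{2K\Delta t}$ metres. Displacements are computed in
local metres and converted to degrees at the midpoint latitude
($\mathrm{d}\lambda = \mathrm{d}x / (R\cos\varphi)$,
$\mathrm{d}\varphi = \mathrm{d}y / R$, $R = 6\,371$ km). Diffusion is applied
after advection within a step (standard operator splitting for random-walk
models); the kernel is Gaussian because $K$ is a Fickian diffusivity.
Transport is surface-only: the larvae modelled here are positively buoyant
gamete-bundle products that stay in the surface layer, so no vertical
velocities enter.

**Coastline interaction.** A tentative position on land (nearest grid node
masked as land) strands the particle: it keeps its last ocean position but
its biological clock keeps running, and it is retried every step, so a flow
reversal refloats it. A tentative position outside the grid hull freezes the
particle as having left the domain. The status machine is
ACTIVE ↔ STRANDED with absorbing INACTIVE (aged out) and LEFT_DOMAIN states;
particles are never deleted, only re-flagged, so ensembles are conserved.

**Biology.** Each larva drifts for a pelagic larval duration (PLD) of
`max_age_days` = 10 days. The first `precompetency_days` = 4 days are a
developmental period during which reef contact does not count; the remaining
6 days are the settlement window. A connectivity event is the first record
at which a competent, ACTIVE larva lies inside a reef polygon, recorded once
per (larva, destination reef) pair; larvae continue after an event and may
connect to several reefs. Travel time is the larva's age at the event.
Mortality, swimming, competency decay and post-settlement survival are
deliberately outside the model: the package measures *physical* connectivity.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dt` | 1800 | s | internal tracker step; resolves km-scale flow features at ≤ 2 m/s |
| `diffusivity` K | 933 | m²/s | sub-grid variability of a daily 1/12° current product; well below the ~2000 m²/s eddy diffusivity of typical ocean models, so it never dominates |
| `max_age_days` (PLD) | 10 | d | short-PLD broadcast-spawning *Acropora*-type larva |
| `precompetency_days` | 4 | d | laboratory competency onset for such larvae |
| seeding density | 200 | larvae/km² | applied to polygons whose plan area exceeds 1 km² |
| seeding floor | 200 | larvae | polygons at or below 1 km² (threshold is a strict "exceeding") |
| release schedule | every 2 d, Feb–Mar, 00:00 UTC | — | peak spawning season; midnight releases mimic observed spawning |

All are arguments of `tracker_config()`, `biology_config()` and
`run_config()`; the defaults reproduce the reference parameterisation, so an
empty YAML override (`read_run_config()`) runs the canonical configuration.

# The synthetic ocean

No current reanalysis or reef survey data are bundled. The generator exists
to exercise the pipeline under controlled, dynamically sensible conditions.

**Streamfunction construction.** Every scenario is a sum of analytic
streamfunction components — uniform drift, Rankine vortices (solid-body core,
$1/r$ exterior; the core ψ-drop is $V_{\max}R_{core}/2$), and jets with an
error-function ψ-profile across a waypoint path (Gaussian speed profile) —
each with optional piecewise-linear amplitude modulation in time (eddy
arrival and decay without solving dynamics). Velocities on the grid are
central differences of ψ in the spherical metric
($u = -\partial\psi/\partial y$,
$v\cos\varphi = \partial\psi/\partial x_{eq}$). Because the same discrete
operators appear in the discrete spherical divergence, generated fields are
non-divergent to machine precision at interior ocean nodes — particles
cannot spuriously accumulate, and ψ-conservation along K = 0 trajectories is
a free oracle for the tracker. Jet paths are extended past the grid edges so
the end caps of the truncated ψ-profile (where the return flow concentrates)
fall outside the domain.

**Coastline.** An idealised meridional coast (land to the west) with a
smooth eastward headland (cosine bell of configurable half-width and
indentation depth). The headland's concave flanks form the bight in whose
lee cyclonic eddies sit; setting the indentation to zero gives a straight
coast. The landmask is the coastline curve rasterised at grid nodes.

**Scenarios.** Three regimes spanning the mechanism space:
*A* — a slow (0.3 m/s) jet following the coast around the headland:
neighbouring reef bands connect in ~8–9 days, distant bands would need
~26 days and never connect. The 0.3 m/s is a modelling choice (the regime is
defined by "slower than the bight-bypassing streams") and is configurable.
*B* — a fast (1 m/s) jet from the headland directly to the southern reefs,
bypassing the bight, plus a Southern-Hemisphere cyclone (clockwise Rankine
vortex, amplitude ramping over 4 days) in the lee: bight-released larvae are
recirculated and pressed coastward and effectively cannot reach the southern
band within the PLD, while headland larvae ride the jet south in ~6 days.
*C* — the A-type coastal jet strengthened to 1.4 m/s and fed by the western
flank of a large offshore anticyclone, locally exceeding 1.5 m/s: even the
most distant bands connect in ~5–7 days, inside the settlement window.

**Synthetic reefs.** Small convex polygons (elliptical octagons, ~0.25–3 km²)
placed just offshore in four latitude bands (complexes BA, INHM, INHC, MRC
north→south), every vertex verified against the coastline curve.

**What this does and does not show.** The generator reproduces the
*kinematic* structure of the regimes (speeds, length scales, eddy trapping,
divergence-free flow) but not ocean dynamics: no time-evolving eddy fields
from instabilities, no tides, no bathymetry beyond the binary landmask, no
inter-annual variability. Tests passing on these fields validate the
numerics and the biology logic, not any claim about a specific ocean state;
runs on real reanalysis currents (read through the same
`read_currents()` interface) inherit the validated machinery but their
realism is bounded by the input data.

# Numerical choices

* **Space–time interpolation** is bilinear in space and linear in time
  between daily snapshots (the cheapest defensible choice; reanalysis-scale
  products do not justify higher order). Near the coast, land corner nodes
  contribute zero velocity and their bilinear weight is renormalised over
  the ocean corners — this avoids the spurious onshore drift that
  zero-filled land values would induce, while keeping the sampler
  deterministic and continuous.
* **Ocean/land queries** use the nearest-node landmask; the synthetic
  coastline is grid-resolved, so a vector coastline would add cost without
  information.
* **Containment** is tested at discrete records (every `dt`), not by
  segment–polygon intersection: at a 30-minute step and ≤ 2 m/s a particle
  moves ≤ 3.6 km per step, comparable to reef size, so fast crossings of
  very small reefs can be missed. This is a known undercount risk, and
  `detect_events()` warns when trajectories are coarser than the 30-minute
  contract.
* **Ageing boundary.** A particle is frozen INACTIVE strictly *after* its
  age exceeds the PLD, so the record at exactly the PLD is still active and
  an arrival at exactly the PLD counts — consistent with the inclusive
  settlement window precompetency ≤ travel time ≤ PLD.
* **Seed counts** round to the nearest integer, half away from zero
  (fractional counts have no exact-integer contract). Travel-time spreads
  use the *population* standard deviation: the simulated larvae are the full
  population, not a sample.
* **Overlapping reef polygons** resolve to the first reef in north→south
  order (deterministic tie-break). Release points are uniform over the
  polygon by bounding-box rejection; placement within a polygon is not
  specified by the biology, and uniform is the assumption-free choice.
  Degenerate rings (collinear vertices, zero area) and pathologically thin
  polygons raise errors rather than silently returning nonsense.
* **Leap years.** The release schedule is anchored at 1 February with a
  fixed 48-hour stride while the date stays in February–March — the simplest
  reading of "every 2 days" (30 releases in both leap and non-leap years).
* **Reproducibility.** One master seed drives every random stage. Inside the
  tracker a single master-seeded stream draws a fixed-size Gaussian block
  for the full ensemble at every step (draws for frozen particles are
  discarded), so trajectories do not depend on the statuses of other
  particles or on iteration order; per-year tracker seeds are derived
  deterministically from the master seed. Identical configuration and seed
  give byte-identical artefacts, and the run manifest (config hash, seed,
  versions) suffices to reproduce a run.

# Validation strategy and problem sizes

The test suite checks the implementation against independent oracles rather
than against itself: a winding-number point-in-polygon scan against the
indexed even-odd locator (10⁵ points); a nested-loop interpolation reference
(agreement to 10⁻¹²); closed-form RK2 displacements and second-order
convergence on solid-body rotation (error ratio ≈ 4 when the step halves;
the rotation period is chosen at 2 days so truncation error dominates the
metre/degree metric distortion); the Fickian law for the random walk
(per-axis sd within 1% at 10⁵ particles, ensemble variance linear in time,
R² > 0.999 over 100 steps); ψ-conservation within 1% of the core ψ-scale
over 10 simulated days of K = 0 tracking in a gridded Rankine vortex; and
transit-time gating in a uniform stream linking two reefs 300 km apart —
no connections at 1.5 m/s (transit inside precompetency), > 50% connecting
with mean travel time within 10% of $d/U$ at 0.5 m/s, none at 0.3 m/s
(transit beyond the PLD). The scenario contrasts are asserted as
inequalities (A connects neighbours but not distant bands; B yields fewer
bight-to-south connections than A with a longer PLD-censored mean travel
time; C connects the most distant bands), using 3 reefs per complex and 300
larvae per reef on the default 4° × 8.5°, 1/24° domain — sizes chosen so a
full suite run completes in about a minute while keeping the regime
contrasts far from sampling noise (the censoring convention makes the B–A
travel-time comparison well defined even when B yields zero connections).

# Limitations

Physical connectivity only: no mortality, no behaviour, no settlement
ecology, so absolute counts are upper bounds on demographic exchange.
Discrete-record containment undercounts very small reefs under very fast
flow. The synthetic regimes are steady or piecewise-linearly modulated
kinematic fields, not dynamic ocean states. Shapefile reef input is not
supported (GeoJSON only). Travel-time statistics are conditional on
connection; the censored summaries used in the regime comparisons should be
preferred when regimes differ in how often they connect at all.
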