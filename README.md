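# reefdrift

Biophysical simulation of coral-larval dispersal and reef connectivity in
strong western-boundary-current systems.

Coral metapopulations persist through larval exchange: broadcast-spawning
corals release buoyant gamete bundles that fertilise at the sea surface, and
the resulting larvae drift with surface currents for days before they can
settle on another reef. For short-lived larvae, whether two reef complexes
are connected is decided almost entirely by regional flow features — coastal
jets, mesoscale eddies and boundary streams — interacting with the coastline.
`reefdrift` simulates this process end to end for ecologists and physical
oceanographers who want to quantify source–sink structure among reef systems:

* **Lagrangian tracker** — virtual larvae are advected through gridded
  surface currents with an explicit-midpoint (second-order Runge–Kutta)
  scheme at a 30-minute internal step, plus a constant-diffusivity random
  walk with per-axis displacement `sd = sqrt(2 K dt)` (default
  `K = 933 m²/s`, representing sub-grid variability unresolved by a daily
  1/12° reanalysis). Transport is surface-only. Larvae pushed ashore
  accumulate on the shoreline but stay biologically active and can refloat
  when the flow changes.
* **Larval biology** — each larva drifts for a 10-day pelagic larval
  duration (PLD); the first 4 days are a precompetency period during which
  no settlement occurs, leaving a 6-day settlement window. A connectivity
  event is the intersection of a competent, active larva with a reef
  polygon; one event is recorded per (larva, destination reef) pair and a
  larva may connect to several reefs.
* **Seeding rule** — reef polygons above 1 km² receive 200 larvae/km²;
  smaller polygons receive 200 larvae. Releases occur at midnight every
  2 days through the February–March spawning season.
* **Analytics** — source-by-destination connectivity matrices (diagonal =
  self-recruitment, axes ordered north→south), mean and population-standard-
  deviation travel-time matrices, complex-level block sums and per-year /
  per-release contribution tables for a destination complex (intra-complex
  exchange excluded).
* **Synthetic ocean** — a streamfunction-based generator
  (`velocity_field()`, `scenario_library()`) produces exactly non-divergent
  current fields on an idealised coastline with a bight-forming headland,
  with three canonical regimes: **A** a slow (~0.3 m/s) alongshore stream
  hugging the bight, **B** a fast (~1 m/s) direct jet bypassing the bight
  plus a cyclonic lee eddy that traps larvae released inside it, and **C** a
  broad boundary stream exceeding 1.5 m/s fed by a large offshore
  anticyclone. `generate_reefs()` creates reef polygon sets in alongshore
  bands (complexes). Currents are read/written as CF-style NetCDF
  (`read_currents()` / `write_currents()`), reefs as GeoJSON.

The package ships no observational data; the synthetic generator exists so
the full pipeline is testable at desk scale against closed-form oracles
(streamfunction conservation, Fickian diffusion, transit-time gating).

## Worked example

A compact run: scenario C (boundary stream), two reef complexes ~670 km
apart, one season with two release days, 1/12° synthetic currents.

```r
library(reefdrift)
cfg <- run_config(out_dir = "run_demo", scenario = "C", grid_resolution = 1/12,
                  years = 2010, months = 2, interval_days = 16,
                  n_per_complex = 2, complexes = c("BA", "MRC"),
                  band_lats = c(-21.3, -27.3), seed = 3,
                  tracker = tracker_config(seed = 3))
run <- run_pipeline(cfg)
print(run)
#> dispersal_run: 2606 larvae released, 10 connectivity events, 4 reefs
#> artefacts in run_demo
print(summarize_run(run))
#> dispersal_report
#>   total connectivity events: 10
#>   self-recruitment: 0 events (0.0%)
#>   mean travel time within complexes:  n/a (no connections)
#>   mean travel time between complexes: 158.1 h
#>   complex-level totals (source rows, destination columns):
#>     BA MRC
#> BA   0  10
#> MRC  0   0
```

Ten larvae released in the northern band (BA) reached the southern band
(MRC), carried ~670 km by the fast boundary stream in a mean 158 h (6.6
days) — inside the 4–10-day settlement window, which is why this regime
connects the distant complexes. Under scenario A (slow alongshore stream)
the same transit needs ~26 days, far beyond the PLD, and the BA→MRC block
is empty; only neighbouring bands connect. The run directory contains
`events.csv`, reef- and complex-level connectivity matrices (TSV),
travel-time mean/sd matrices, `temporal_contributions.csv`, the reef
GeoJSON and a `manifest.json` (seed, config hash, versions) that makes the
run reproducible bit for bit.

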