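# dctraj — drift-corrected velocities and trajectories for tracked marine animals

Satellite tracks of marine animals confound two motions: the animal's own
swimming and the drift imposed by currents, wind and waves. For small
oceanic-stage animals such as juvenile loggerhead turtles the two are of
similar size, so raw trajectories cannot be read behaviorally. `dctraj` is
an R package for movement ecologists that separates them using gridded
ocean reanalysis fields:

- **velocity over ground** `V_g` from daily positions (midnight-interpolated
  centered differences, local-plane metric),
- a **drift model** `V_d = V_co + γ · V_sto` — surface Eulerian current plus
  a leeway fraction γ of the surface Stokes drift — with γ estimated by a
  stacked 2-D least-squares regression on passive-drifter (or animal)
  tracks,
- the **drift-corrected velocity** `V_DC = V_g − V_d`, an estimate of the
  swimming velocity, and its time integral the **DC-trajectory** in a local
  plane,
- downstream behavioral analyses: two-segment breakpoint detection with a
  drifting / homing / unreliable taxonomy, annual-sine fits of meridional
  DC-trajectories with circular phase statistics, von Bertalanffy size
  imputation, the size-conditional homing probability `F_H(SCL)`, Rayleigh
  seasonality tests, and 5°×5° drifter noise maps,
- a **seedable synthetic world** (analytic current/Stokes fields, passive
  drifters, behaviorally programmed turtles with truth tables) so the whole
  chain is testable without restricted tracking data.

Reference leeway fractions from the North Pacific study system are 0.88 for
undrogued surface buoys and 0.28 for juvenile loggerheads; the drifting vs
homing split uses a mean zonal DC-velocity threshold of −6.5 cm/s with
90-day / 0.25 m/s reliability guards.

## Worked example

```r
library(dctraj)

cfg      <- synth_config(seed = 1, n_drifters = 200, n_days = 300)
fields   <- gen_fields(cfg)
drifters <- gen_drifters(cfg, fields)

tracks <- velocity_over_ground(drifters$tracks)
tracks <- match_fields(tracks, fields)
fit    <- fit_leeway(tracks, domain = "buoys")
fit
#> Leeway model  V_d = V_co + gamma * V_sto   [buoys]
#>   gamma = 0.8804 (se 0.0078), n = 59600 days
#>   intercepts mu = (0.0002, -0.0002) m/s   residual std = (0.0362, 0.0363) m/s
```

The regression recovers the planted leeway fraction 0.88 within one
standard error from 200 drifters × 300 days; the near-zero intercepts mean
the drift model is unbiased in this world. The same functions applied to a
programmed turtle population recover the planted behavior — e.g. with
`n_turtles = 80, n_days = 500` the pipeline prints a mean annual migration
amplitude of 439 km (planted: 440) with circular mean phase on day 264
(planted: Sept 21), and `estimate_f_h()` reaches 50% at 42 cm SCL
(planted trigger: Normal(42, 4)).

A thin command-line wrapper over the same functions lives at
`inst/cli/dctraj.R`:

```sh
Rscript inst/cli/dctraj.R simulate --out work --seed 1
Rscript inst/cli/dctraj.R match --tracks work/drifters.csv --fields work/fields.csv --out work
Rscript inst/cli/dctraj.R fit-leeway --tracks work/matched.csv --out work
```

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic world from a seed and runs
the complete pipeline — field generation, drifter and turtle simulation,
field matching, leeway regression, DC-velocities and trajectories,
segmentation/classification, seasonal sine fits and circular phase, size
imputation and `F_H`, breakpoint seasonality — writing its JSON report to
the path given:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/track-store.R` — track I/O, midnight interpolation, velocity over ground
- `R/fields.R` — gridded field container, bilinear sampling, matching, box statistics
- `R/leeway.R` — the leeway regression (`fit_leeway`) and drift prediction
- `R/dc.R` — DC-velocities, DC-trajectories, ensemble statistics, noise maps
- `R/segment.R` — breakpoint detection and the D/H/U taxonomy
- `R/seasonal.R` — annual sine fits, circular phases, binned meridional means
- `R/growth.R` — von Bertalanffy imputation, `F_H(SCL)`, Rayleigh seasonality
- `R/synthetic.R` — the seedable synthetic ocean, drifters and turtles
- `R/cli.R`, `inst/cli/dctraj.R` — command-line interface
- `vignettes/drift-corrected-trajectories.Rmd` — methods and assumptions
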