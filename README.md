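# avmsim

Reduced-order haemodynamic simulation for planning **embolo-sclerotherapy of
peripheral arteriovenous malformations (pAVMs)**.

A pAVM shunts arterial blood directly into veins through a tangle of
pathological vessels (the *nidus*). Treatment injects sclerosants into the
nidus in stages, progressively raising its hydraulic resistance until the
shunt carries almost no flow. `avmsim` turns the printed parameters of such
an intervention — vessel calibres, digital subtraction angiography (DSA)
flow estimates, boundary conditions — into a calibrated lumped hydraulic
network that predicts, stage by stage, how flow and pressure redistribute
as the nidus occludes. It is aimed at modellers and interventional teams
prototyping treatment-planning pipelines, and at anyone who needs a fast,
fully testable surrogate for 3D CFD of staged AVM embolisation.

## Model

- **Network haemodynamics** — the lesion is a resistive graph: pressure
  inlet `P_in`, a resistance outlet boundary condition `P_art = Q_art·R_art`
  on the arterial branch, zero-pressure venous outlets, and linear edges
  `ΔP = R·Q` solved by sparse nodal analysis (laminar regime, inlet
  Re ≈ 150).
- **Darcy nidus** — the nidus is an isotropic porous medium
  (`S = −(μ/K)·u`); lumped, `R_nidus = μ·α/K` with a shape factor α
  calibrated at the baseline `(K, R)` pair. Sclerotherapy is a fall in
  permeability `K`.
- **Calibration** — with `P_in` and `R_art` fixed, three lumped path
  resistances are fitted to the baseline flow split and the completion
  inlet flow (bracketed root finding; residuals ≤ 1e-10); per-stage `K` is
  fitted to each DSA inlet-flow estimate, and an undocumented stage is
  interpolated quadratically in `(stage index, log10 K)`.
- **Contrast transport & virtual angiography** — a 1D advection–diffusion
  solve of a unit square bolus (1.5 s wide, 5 s horizon, Δt = 0.01 s) over
  the steady flow field, rendered to boolean DSA-like frames at 2 frames/s.
- **Swept-volume flow estimation** — flow from frame series as (newly
  dye-filled volume)/(elapsed time), with repeated-window mean ± SD.
- **Stokes–Brinkman verification** — a 2D staggered-grid solver of the
  distributed momentum-sink formulation verifies the lumped Darcy closure
  against `ΔP = μLU/K`.

## Worked example

```r
library(avmsim)

fit <- avm_model(make_reference_case())
print(fit)
#> Reduced-order AVM embolo-sclerotherapy model
#>
#> AVM network calibration
#>   R_feed = 1.023, R_AO = 16.02, R_ven = 16.07 mmHg.s/ml
#>   nidus shape factor alpha = 220 1/m
#>   target residual 3.91e-15 (6 iterations)
#>
#> Stage haemodynamics:
#>        stage R_nidus Q_inlet  Q_nidus  Q_art nidus_fraction success
#>     baseline    0.33   1.645 1.168000 0.4770          71.0%   FALSE
#>    Post AE I   22.17   1.011 0.517840 0.4932          51.2%   FALSE
#>  Post AE III 3970.00   0.511 0.005096 0.5059           1.0%    TRUE
```

Reading: at baseline the nidus steals 71% of the 1.645 ml/s inlet flow; by
completion (`R_nidus` = 3970 mmHg·s/ml) the nidus carries 0.005 ml/s — 1%
of a reduced 0.511 ml/s inlet flow — and the arterial branch flow has risen
to 0.506 ml/s: the shunt is defeated and perfusion re-routes to the normal
arterial bed (`success = TRUE` marks the ≤ 1% embolisation endpoint).

```r
coef(fit)       # fitted lumped resistances and nidus shape factor
residuals(fit)  # model − DSA inlet flows; completion residual +0.28 ml/s
                # reflects post-intervention vascular adaptation the fixed
                # boundary conditions cannot capture
plot(fit)       # staged flows with DSA measurements overlaid

# virtual angiogram of the baseline stage, 2 frames/s
frames <- simulate(fit, stage = "baseline")[[1]]

# and flow back-estimated from frames by the swept-volume method
d <- synthesize_dsa_frames(make_synthetic_avm(7), "baseline")
estimate_inlet_flow(d$geometry, d$series)
#> $mean
#> [1] 1.480067   # ground truth: 1.480842
```

A command-line front end is installed at
`system.file("cli", "avmsim", package = "avmsim")` with subcommands
`simulate`, `calibrate`, `angiogram`, `estimate-flow`, `synth` and
`brinkman`; case files are JSON (or YAML) per
`inst/extdata/case.schema.json`, with the reference case shipped at
`inst/extdata/reference_case.json`.

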