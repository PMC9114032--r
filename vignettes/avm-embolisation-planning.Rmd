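---
title: "Reduced-order planning of AVM embolo-sclerotherapy: models and methods"
author: "avmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order planning of AVM embolo-sclerotherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmsim)
```

## The clinical problem

A peripheral arteriovenous malformation (pAVM) short-circuits arterial blood
into the venous system through a tangle of pathological vessels, the *nidus*.
Embolo-sclerotherapy occludes the nidus in stages: each sclerosant injection
(sodium tetradecyl sulfate foam, then absolute ethanol) raises the nidus's
hydraulic resistance until almost no flow passes through it, at which point
the shunt is defeated and flow re-routes through the normal arterial branch.
Interventionists monitor progress with digital subtraction angiography (DSA),
which yields flow estimates but no pressures and no forecast of how the next
injection will redistribute flow. `avmsim` provides that forecast at desk
scale: a lumped hydraulic network whose only nonstandard element — the nidus
— is a Darcy porous medium with a stage-dependent permeability.

## Network model

The lesion is reduced to a directed resistive network:

```
inlet --R_feed--> junction --R_AO--> arterial outlet --R_art--> (0 mmHg)
                     |
                  R_nidus
                     v
              venous confluence --{R_ven split}--> venous outlets (0 mmHg)
```

Each edge obeys `dP = R * Q`. The inlet carries a prescribed pressure `P_in`
(the action of the heart); the venous outlets are held at zero gauge
pressure; the arterial outlet is closed by a *resistance boundary condition*
`P_art = Q_art * R_art`, representing the downstream capillary bed that the
imaged geometry does not include. Flow conservation at the free nodes gives
a small sparse linear system (`solve_flow()`), exact to machine precision.
Convective losses are neglected: the baseline inlet Reynolds number is about
150, firmly laminar, and the solved flows enter the transport model as a
steady field because DSA's 2 frames/s cannot resolve pulsatility anyway.

Two venous outlets share the calibrated venous lump as parallel resistances
apportioned by the fourth power of their diameters (the Poiseuille weight);
their individual split is reported but nothing downstream depends on it.

### The nidus as a porous medium

Sclerosant action is modelled as a permeability change. With an isotropic
Darcy momentum sink `S = -(mu/K) u`, lumping over an effective
length-to-area ratio `alpha` gives

```
R_nidus = mu * alpha / K .
```

`alpha` is *calibrated*, not geometric: evaluating the inverse map at the
baseline pair (K = 2e-8 m^2, R = 0.330 mmHg.s/ml) gives `alpha` of about
220 1/m, whereas the bounding-box ratio `L/(W*H)` of the 16 x 12 x 9 mm
nidus is only about 148 1/m. The difference is the tortuosity of the real
flow path, and it is why the package anchors `alpha` at the baseline pair
rather than deriving it from the box. The completion pair (1.5e-12 m^2,
3970 mmHg.s/ml) implies `alpha` of about 198 1/m — a deviation of roughly
10% from constant `alpha`, a three-dimensional geometry effect. Stages may
therefore prescribe `R_nidus` directly, overriding the `alpha` map; the
reference case does exactly that for its two anchored stages.

One transcription wrinkle in the source material: the baseline permeability
appears once with a positive exponent (2e+8 m^2). A permeability of 2e+8
m^2 would make the nidus five orders of magnitude more conductive than open
space; the value consistent with the quoted resistances and with the results
is 2e-8 m^2, which is what `make_reference_case()` emits. The discrepancy is
flagged here rather than silently corrected.

## Calibration

The study geometry supplies segment diameters but no centerline lengths, so
the three viscous path resistances (`R_feed`, `R_AO`, `R_ven`) cannot be
computed from Poiseuille's law; they are fitted. With `P_in` = 20.837 mmHg
and `R_art` = 24.138 mmHg.s/ml fixed at their known values, three flow
conditions determine the three lumps:

1. baseline inlet flow 1.645 ml/s,
2. baseline nidus flow 1.168 ml/s,
3. completion inlet flow 0.511 ml/s.

Conditions 1-2 are linear in the lumps once `R_feed` is fixed, so
`calibrate_reference_resistances()` eliminates `R_AO` and `R_ven`
analytically and runs bracketed root finding on `R_feed` alone
(`uniroot`, tolerance 1e-14 on the bracket), then re-verifies all three
targets through the full network solver. The fit gives `R_feed` = 1.023,
`R_AO` = 16.016 and `R_ven` = 16.068 mmHg.s/ml, with target residuals below
1e-10. Infeasible target sets (e.g. a nidus flow exceeding the inlet flow)
raise errors naming the violated constraint rather than returning a
least-squares compromise.

Per-stage permeability is then found by `calibrate_stage_permeability()`:
inlet flow is strictly increasing in `K`, so bracketed root finding on
`log10 K` converges unconditionally, stopping when the solved inlet flow is
within 1e-6 ml/s of the DSA target. The bracket default spans `K` from
1e-16 to 1e-2 m^2 and the result is invariant to any bracket containing the
root.

A stage without usable DSA data is interpolated: the unique quadratic
through three documented `(stage index, log10 K)` knots, evaluated at the
missing index (`interpolate_missing_stage()`). Interpolation is done on
`log10 K` because permeability spans more than four decades over a full
intervention; a quadratic in linear `K` would be dominated entirely by the
largest knot. The source material does not state its interpolation scale;
the logarithmic choice is this package's, made once and kept.

## Contrast transport and virtual angiography

The de-coupled transport step solves, per network edge,

```
dc/dt + v dc/ds = D d2c/ds2 ,    v = Q / A ,
```

with flow-weighted instantaneous mixing at junctions (no junction volume —
nothing in the data constrains one), zero-flux walls, and a unit square
inlet bolus (amplitude 1 kg/m^3, width 1.5 s, horizon 5 s, reporting step
0.01 s). The nidus edge uses the superficial velocity `Q/(W*H)`; porosity
is not modelled because no porosity is specified for transport. The contrast
diffusivity is 2.2e-10 m^2/s, giving a Peclet number of order 1e6: transport
is advection-dominated and the physical diffusion term is negligible
against numerical diffusion.

The discretisation is first-order upwind finite volume with explicit time
stepping, sub-divided automatically to satisfy `dt <= 0.9 / (v/ds +
2D/ds^2)`. This scheme is conservative (the flow-weighted junction average
makes inter-edge fluxes telescope exactly) and monotone, so the discrete
maximum principle holds by construction; the test suite verifies mass
closure to well under 0.5% and bounds `0 <= c <= amplitude`. The price of
monotonicity is front smearing by numerical diffusion. Consequently all
quantitative use of the transport field is through *front arrival* (a level
crossing), which is first-order accurate and stable under refinement
(halving `ds` moves arrival times by under 2%), never through front
sharpness.

`render_angiogram_frames()` thresholds the field at a fraction of the bolus
amplitude (default 0.1) and samples at the DSA frame rate (2 frames/s),
producing boolean occupancy per centerline sample — the package's canonical
angiogram representation. A rendering caveat discovered during
verification: immediately downstream of a junction the first cell of a
nearly-blocked branch equilibrates with the junction concentration at rate
`v/ds`, so even at completion the first nidus cell reaches a few percent of
the bolus amplitude. "The nidus is bypassed" is therefore asserted on the
volume-averaged nidus concentration (< 1% of amplitude at completion) and
on occupancy (no nidus sample crosses the 0.1 threshold), not on a
sample-wise maximum, which no finite upwind grid would satisfy.

Model-to-phantom similarity uses the Peclet number `Pe = D v / diffusivity`:
at 2:1 geometric scale with doubled flow and a dye diffusivity of 2e-10
m^2/s, the computational and phantom values come out near 2.5e6 and 2.8e6.

## Swept-volume flow estimation

DSA-derived flow is the volume newly filled by contrast between two frames
divided by the elapsed time. `swept_volume()` sums `A * ds` over centerline
samples newly occupied in the later frame; `estimate_inlet_flow()` repeats
the measurement over several windows and reports mean, (n-1) standard
deviation, and n (SD is absent when only one window is usable, mirroring
real runs with too few analysable frames). How a partially filled cross
section should count is not specified anywhere authoritative; the package's
convention is boolean per centerline sample, documented here.

Three robustness rules, each motivated by a concrete failure mode observed
on synthetic data:

- **Monotone closure**: each sample is latched once occupied. The raw
  occupied band has finite length (the bolus washes out behind the front),
  so differencing raw frames measures bolus length, not swept volume.
- **Despeckle**: a sample counts only if occupied in two consecutive
  frames. Isolated flipped-bit noise otherwise survives the closure and
  biases the estimate upward by several percent per percent of noise.
- **Field-of-view truncation**: windows end one frame before dye reaches
  the far end of any imaged branch, where the swept volume would saturate.

With these rules the estimator recovers ground-truth flows from synthetic
frame series to well under 5% across 0.2-2.0 ml/s (noiseless) and under
10% with 1% of occupancy bits flipped.

## Stokes-Brinkman verification solver

The lumped Darcy element is justified against a distributed solver:
`solve_stokes_brinkman()` discretises the Stokes equations with the
momentum sink `-(mu/K) u` on a staggered (MAC) grid — uniform inflow,
zero-pressure outflow, no-slip walls — and solves the saddle-point system
with a direct sparse factorisation. Convective terms are dropped: the
verification target (the Darcy closed form `dP = mu L U / K`) is a creeping
-flow limit, and nothing the package validates exercises inertia. The
end-to-end pressure drop is read from a linear fit of the streamwise
pressure profile over the downstream three quarters of the channel, which
is exact for Darcy-dominated (linear) profiles and skips the entrance
region in the clear-fluid limit.

On a uniform porous block the solver matches `mu L U / K` to well under 2%
on all tested grids (up to 128 x 32) and matches plane Poiseuille
(`12 mu L U / h^2`) within 5% when `K` is effectively infinite; the lumped
element with geometric `alpha = L/A` agrees with the distributed `dP/Q`
within 5%, which is the package's justification for the network closure.
One verification subtlety: under refinement the discrete solution converges
to the *Brinkman* drop, which sits a fraction of a percent above the Darcy
form because of the no-slip wall layer (thickness of order `sqrt(K)`), so
the error measured against the Darcy form is not monotone in grid size —
the self-convergence test therefore measures distance to the finest-grid
value, and the Darcy comparison is a tolerance check.

## Synthetic data: what it does and does not emulate

`make_synthetic_avm()` samples lesions from the same parametric family as
the reference case (diameters 1-5 mm, lumps 0.5-30 mmHg.s/ml, permeability
ladders spanning at least three decades over five stages) and computes
ground-truth flows with the network solver itself; `synthesize_dsa_frames()`
runs the real transport solver over a straight measurement vessel at the
ground-truth flow and renders frames at 2 frames/s, optionally flipping a
seeded fraction of bits. All randomness in the package is confined to this
module and every test pins its seed.

Because the generator draws from the model family, recovery tests certify
the *inverse problems* (calibration, permeability fitting, flow estimation)
— they cannot certify the lumped closure against real three-dimensional
haemodynamics. What passing tests show: the solvers are correct on their
own equations, the calibration recovers generating parameters to 0.5%, and
the estimation chain closes to 1% on exact targets. What they do not show:
wall compliance, pulsatility, non-Newtonian rheology, vascular adaptation
after occlusion — all absent from the model, and visibly so: the calibrated
model over-predicts the completion inlet flow (0.511 ml/s simulated vs
0.231 ml/s measured), a residual the package reports rather than hides
(`residuals()` on the fitted model).

The measurement vessel in `synthesize_dsa_frames()` is 0.35 m long — far
longer than any real feeding artery — so that the dye front stays inside
the imaged geometry for several frames at clinical flows; it is a
measurement fixture (the analogue of choosing analysable DSA windows), not
an anatomical claim. Its frames are rendered at threshold 0.5, the
mid-level of a symmetric smeared front, which travels at the mean velocity
and so supports unbiased recovery; the clinical default for virtual
angiograms stays at 0.1.

## Numerical choices and degenerate inputs

- Internal computation is SI throughout; the user surface speaks mmHg,
  ml/s, mmHg.s/ml, with 1 mmHg = 133.322 Pa exactly, so unit round trips
  are lossless.
- Segment lengths absent from a case default to 15 mm for transport
  geometry only; hydraulics never uses them (lumps are calibrated).
- Zero-resistance edges are rejected (merge the nodes instead); negative
  resistances, non-positive diameters/permeabilities, empty stage lists,
  duplicated stage names and targets outside attainable ranges all raise
  errors that name the offending quantity.
- Flow-direction reversal in transport is handled by upwinding, not an
  error; a directed cycle in the solved flow field is an error.
- Root-finding tolerances: 1e-6 ml/s on stage flows (about 0.1% of the
  smallest stage target), bracket tolerance 1e-14 on calibration.

## Problem sizes

The default study runs solve networks of six edges and three free nodes;
transport integrates about 80 centerline cells over 500 reporting steps;
the Brinkman verification uses grids up to 128 x 32 (about 12,000
unknowns); property tests sweep 100 random networks (up to 50 edges) and
50 synthetic lesions. These sizes were chosen so the entire verification
suite, including every cross-check oracle, runs in well under a minute on
one core, which keeps the full calibrate-simulate-verify loop interactive.

## Worked example

```{r example}
fit <- avm_model(make_reference_case())
summary(fit)
```

```{r example-predict}
# sweep candidate endpoints: how much resistance must sclerotherapy add?
sweep <- predict(fit, R_nidus = c(0.33, 3, 30, 300, 3970))
sweep[, c("R_nidus", "Q_inlet", "Q_nidus", "nidus_fraction", "success")]
```

```{r example-plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Known limitations

- Steady flow only; DSA temporal resolution motivates this, but systolic
  transients are invisible to the model.
- The lumped closure compresses all distributed viscous loss into three
  fitted resistances; pressures at interior points other than the junction
  and confluence are not predicted.
- The quadratic log-K interpolation of an undocumented stage is a smooth
  guess, not physiology; its output is marked as interpolated wherever
  reported.
- Virtual angiograms are occupancy maps on centerlines, not X-ray
  projections; no attenuation physics, no injection-catheter model.
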