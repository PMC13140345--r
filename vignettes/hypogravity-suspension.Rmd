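---
title: "Modelling head-up-tilt suspension: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling head-up-tilt suspension: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hutsim)
```

## The suspension model and its assumptions

A body suspended by ropes and tilted head-up by an angle $\theta$ from
horizontal experiences an axial gravitational component
$a_{axial} = g\sin\theta$ while its weight transverse to the body axis is
carried by counterbalanced ropes. Everything in this package follows from
that law plus three assumptions:

1. **Rigidity.** The body moves as a rigid link, so one axial displacement
   $s$ is shared by every rope attachment. Flexion between segments,
   lateral sway and rotation are outside the model.
2. **Perpendicular equilibrium.** At rest each rope is perpendicular to the
   body axis and the foot plate perpendicular to the body, i.e. inclined at
   $90-\theta$ from horizontal. Uphill/downhill work that breaks plate
   perpendicularity is representable by overriding the plate angle, but the
   perpendicular default is assumed by the pendulum equations.
3. **Point-mass rope groups.** Each rope group (ankle, knee, pelvis,
   thorax) is treated as a point mass at its attachment; group masses and
   attachment heights come from a segment-fraction table.

Under horizontal suspension ($\theta = 0$, all ropes equal length $L$) the
system is a simple pendulum: displacement $s$ swings the ropes to
$\theta_{rope} = \arcsin(s/L)$ and the restoring axial acceleration is
$g \sin\theta_{rope}\cos\theta_{rope}$. Under tilt the ropes are unequal
($L_i = L_{ankle} - d_{axial,i}\tan\theta$), so each group is modelled
separately and combined as a mass-weighted sum.

### The tilted-pendulum acceleration

For a rope swung to $\theta_{rope,i} = \arcsin(s/L_i) + \theta$, we compute
the segment's axial acceleration as

$$a_{axial,i} = g\,\sin\theta_{rope,i}\,\cos(\theta_{rope,i}-\theta).$$

This expression was a genuine design choice. An alternative form,
$g\sin\theta\cos(\theta_{rope,i}-\theta)$, superficially analogous, is
*decreasing* in rope swing — it can only fall below the equilibrium value
$g\sin\theta$, i.e. it has no restoring excess and cannot describe the
pendulum error that accelerates a displaced body back toward the plate. The
form we use satisfies all three boundary conditions a restoring model must
meet: it equals $g\sin\theta$ at equilibrium, reduces exactly to the
horizontal model at $\theta = 0$, and its excess over equilibrium is
non-negative and increasing in displacement. The non-restoring variant is
kept behind `axial_accel_hut(..., printed_form = TRUE)` purely for
comparison; nothing else calls it.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `theta_deg` | degrees | — | 9.5 simulates lunar, 22.3 Martian gravity; plate range 0–30 |
| `l_ankle_m` | m | — | Longer ropes shrink the pendulum error roughly as $1/L$ |
| `height_m`, `mass_kg` | m, kg | — | Accepted in (1.0, 2.3) m and (30, 125) kg, the rig's envelope and safe working load |
| segment table | fractions | see below | Drives masses, attachment heights, counterbalance loads |
| `plate_mass_kg` | kg | 0 | A 16.4 kg cradle adds $16.4\sin\theta \approx 2.7$ kg axial-equivalent at lunar tilt |
| filter cutoff/order | Hz, — | none | 20 Hz order 2 (quasi-static standing) or 50 Hz order 4 (dynamic trials) |
| `window_s` | s | required | Published standing windows vary (10–30 s vs 30–60 s), so the window is an explicit argument, not a default |
| `gravity` | m s$^{-2}$ | 9.81 | Configurable everywhere it appears |

**The segment-fraction table.** The default
(`hutsim_segments()`) allocates mass thorax 0.528, pelvis 0.150, knee
0.247, ankle 0.075 (group totals; leg groups split per side), with
attachment heights 0.039/0.285/0.53/0.81 of stature. It is derived from
Winter's standard segment fractions reorganised to this rig's rope
grouping: trunk mass split between the pelvis rope and the thorax rope
(which also carries head, neck and arms), and each shank split 50/50
between its knee and ankle ropes because the grouping assigns "part of the
lower leg" to each without a stated ratio. Published anthropometric models
differ at the percent level, so the table is an explicit, swappable input
(`segments =` argument, or a delimited file via `read_segment_table()`)
rather than a constant; the only hard requirements are fractions in (0, 1)
summing to 1 within $10^{-9}$ and strictly increasing attachment heights.

## Numerical choices

* **Angles** are degrees at every interface and radians internally;
  conversion happens in two helpers only.
* **Rig feasibility.** The geometry rejects configurations that drive any
  rope length below 0.1 m, a deliberately conservative floor for a rig in
  which a rope this short is unphysical; no natural lower bound exists in
  the tilt law itself.
* **Jump integrator.** `jump_apex()` advances $\ddot s = -a_{total}(s)$
  with a fixed-step velocity-Verlet scheme, interpolates the $\dot s = 0$
  crossing linearly inside the final step, and halves the step until the
  apex moves by less than $10^{-6}$ m. It is fully deterministic. Tests
  hold it to the ballistic closed form $v_0^2/(2g\sin\theta)$ within 0.5%
  as $L_{ankle}\to\infty$ and to an independent energy-balance oracle
  ($\int_0^A a(s)\,ds = v_0^2/2$ solved by quadrature plus root-finding)
  within 0.1% at rig scale.
* **Zero-phase filtering.** The Butterworth low-pass is applied forward and
  backward (standard biomechanics practice; the stated order is the design
  order of the underlying filter). Because a plain forward–backward pass
  assumes zero initial conditions, the record is padded with odd
  reflections of itself (10 time constants of the cut-off) so start-up
  transients die inside the pad; DC gain is exactly 1. Windowed means
  additionally exclude 0.5 s at each end of any filtered record.
* **Platform zeroing** is modelled as a per-trial baseline offset
  subtracted before analysis (`baseline_n`).
* **Degenerate inputs.** Zero-variance differences in a Bland–Altman call
  collapse the limits of agreement onto the bias and raise a warning rather
  than an error; `v0 = 0` jumps return a zero apex; a constant loading
  table yields ICC 1 exactly.

## Statistical conventions

* **ICC.** `icc_agreement()` implements the two-way, absolute-agreement,
  *single-measures* coefficient — ICC(A,1) in the McGraw–Wong taxonomy —
  from the two-way ANOVA mean squares (computed by `stats::aov`), with the
  standard F-based confidence interval using a Satterthwaite
  degrees-of-freedom approximation. Single measures is the right variant
  here because each visit contributes one measurement per participant;
  absolute agreement (not consistency) is required because a systematic
  visit offset is a real reliability failure for a rig that should
  reproduce the same loading each day. Qualitative labels follow the
  conventional cut-offs (<0.50 poor, 0.50–0.74 moderate, 0.75–0.90 good,
  ≥0.90 excellent).
* **Bland–Altman.** Bias is the mean difference; limits of agreement are
  bias ± 1.96 sample sd; the bias CI is t-based and each LOA's CI uses the
  classical normal-theory approximation $se = sd\sqrt{3/n}$ with a
  $t_{n-1}$ quantile. The analysis drops incomplete pairs per comparison
  (complete-case deletion), matching how a 14-of-19 complete subgroup is
  used in practice.
* **Printed-precision comparisons.** Where tests compare against values
  known only at one decimal place, the computed value is rounded to that
  precision first.

## What the synthetic generators emulate — and what they do not

`sim_loading_table()` produces participant × visit loading as
$y_{ij} = \text{target} + b_i + e_{ij}$ with independent Gaussian
components, so its ground-truth single-measures ICC is
$\sigma_b^2/(\sigma_b^2+\sigma_w^2)$ by construction. Defaults (19
participants, 3 visits, 16.5 %BW target, $\sigma_b = \sigma_w = 2$ %BW)
mirror a three-visit lunar standing study with per-visit SDs near 2.8 %BW.
`sim_standing_trial()` generates a constant axial load plus
low-pass-shaped Gaussian platform noise (default 5 N), optionally splitting
load onto the anteroposterior channel so the Fz–Fy resultant pathway is
exercised. `sim_manikin_campaign()` repeats noisy suspensions over a set of
tilt angles (default noise 0.7 %BW, matching condition-level SDs of
0.5–0.9 %BW in the packaged campaign; measurement bias defaults to 0 and is
injectable). All generators thread an explicit seed through a scoped RNG —
fixed seed, bitwise-identical output, global RNG state untouched.

These generators are deliberately idealised: Gaussian, additive,
uncorrelated across cells, quasi-static. Real suspension data contain
breathing and sway oscillations, occasional rope-slack events, drift in
platform zeroing, and heteroscedasticity across participants. Passing the
packaged recovery tests therefore demonstrates that the *pipeline* is
correct and unbiased under its stated noise model, not that any particular
rig achieves the simulated reliability.

## Problem sizes used in the packaged checks

The seeded checks run at sizes chosen to keep Monte-Carlo error well inside
the asserted tolerances: ICC parameter recovery at $n = 200, k = 3$ (true
ICC 0.8, tolerance ±0.05) and a 500-replicate near-unbiasedness check at
$n = 50, k = 3$ (mean within ±0.02); trial-level recovery uses 6–30 s
records at 200–500 Hz, where 5 N of 20 Hz-shaped noise leaves the windowed
mean within ~0.1 %BW of truth.

## Known limitations

* One-dimensional: no lateral or rotational motion, no anteroposterior
  spring-balance dynamics, no treadmill belt interaction, and no
  two-dimensional pendulum swing during locomotion.
* Displacement domain is $s \ge 0$ (motion away from the plate); rope
  slack and ground-contact phases are not modelled.
* The pendulum model's oblique-displacement behaviour is undefined — the
  additive $\theta$ in the rope-angle formula presumes displacement purely
  along the body axis.
* Segment fractions are population averages; subject-specific inertia is
  out of scope, though any alternative fraction table drops in.
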