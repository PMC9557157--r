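---
title: "Models and numerics behind laaoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind laaoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`laaoflow` asks a clinical question with a desk-scale simulation stack:
does occluding the left atrial appendage (LAAO) improve the
thrombosis-related flow environment of the left heart in a patient on a
continuous-flow left ventricular assist device (LVAD), with sinus rhythm
(SR) or atrial fibrillation (AF)? The package chains five stages — a
closed-loop lumped-parameter circulation, a parametric mitral-valve
surface, a synthetic labeled atrium + appendage flow domain, a pulsatile
incompressible flow solver, and thrombosis metrics with a virtual-ink
washout — and compares the four scenarios SR-LAA, SR-LAAO, AF-LAA and
AF-LAAO.

## The lumped-parameter circulation

The circulation is a closed loop of eight volume states: four elastance
chambers (LA, LV, RA, RV), systemic arterial and venous nodes, and
pulmonary arterial and venous nodes. Chamber pressure blends an active
and a passive part,

$$P(V,t) = e(t)\,P_{iso}\frac{V-V_0}{V_{ref}-V_0}
  \;+\; \alpha\left(e^{\beta (V-V_0)}-1\right),$$

with $e(t)$ a squared-sine activation pulse over the chamber's
activation window (atrial activation starts at 83% of the cycle and
wraps across the boundary, placing the atrial kick just before
ventricular systole). These are the simplest forms parameterized
directly by the quantities that define the scenarios: the peak
isovolumic pressure $P_{iso}$ and the end-diastolic pressure–volume
relation (EDPVR) constant $\alpha$. Heart valves are diodes with small
series resistances, so transmitral flow is identically zero whenever
ventricular pressure exceeds atrial pressure. The assist device is a
static quadratic head–flow law $H(Q) = h_0 + h_1 Q + h_2 Q^2$ solved per
time step for the flow at which the head matches the aorta–ventricle
pressure difference; retrograde flow is allowed, and the quadratic was
shaped with a small $|h_2|$ so its vertex lies far into the retrograde
branch and every transient head during the cycle stays on the
characteristic. Mean circulatory pressure sets the total stressed
volume: the initial state puts every node at that pressure, and the
closed loop conserves total volume to integrator rounding thereafter.

The committed baseline (`default_scenario_params()`) represents a
chronic heart-failure circulation (dilated chambers, low ventricular
elastance so the aortic valve stays closed under full support). Three
baseline constants — the pump head scale, the systemic resistance and
the LA peak isovolumic pressure — were calibrated once, by a damped
Newton/Broyden iteration, so that after the five standard LVAD-patient
adjustments (heart rate 80 bpm; LV peak isovolumic pressure 100→80 mmHg;
RV 80→50 mmHg; mean circulatory pressure 12.5→10 mmHg; systemic
resistance −6%; ventricular EDPVR $\alpha$ +70%) the sinus-rhythm
scenario sits at the clinical operating point: cycle-mean pump flow
5.2 L/min, mean arterial pressure 83.8 mmHg, mitral E/A ratio 1.2. The
calibrated values are frozen in the package source; nothing is re-fit at
run time. Atrial fibrillation is modeled as the complete loss of active
atrial contraction (the atrium follows its passive EDPVR only), which
removes the A wave and slightly reduces mitral filling.

A note on the E/A–$\alpha$ relation: in this model the E/A ratio
*decreases* monotonically as $\alpha$ *increases* (sweeping $\alpha$
over ±50% gives E/A 1.40 → 1.09). A stiffer ventricle raises diastolic
ventricular pressure, which suppresses the passively driven E wave more
than the actively driven A wave. This is the direction that makes a +70%
$\alpha$ adjustment lower E/A onto its target from above, and it is the
relation the property tests assert.

Integration is fixed-step classical Runge–Kutta at 750 steps per cycle
(halving the step changes the cycle-mean pump flow by under 0.001%),
run cycle by cycle until the state at the cycle boundary changes by less
than 0.5%.

## Mitral valve surface

The open mitral valve is a parametric surface over an angular coordinate
$\theta$ (100 samples) and a leaflet coordinate $s$ from annulus to free
edge (40 samples), with symmetry ratio $\varepsilon = 0.35$, ellipticity
$k = 0.6$ and opening angle $\varphi = 60^\circ$. At $s = 0$ every
leaflet term vanishes and the surface reduces to the circular annulus of
radius $R$ in the $z = 0$ plane. The typeset axial profile admits two
readings; the committed one,

$$z(\theta,s) = -\tfrac{s}{2}\left[(1+k^2) + \varepsilon\cos\theta +
  (1-k^2)\cos 2\theta\right] R\sin\varphi,$$

is the only grouping that uses every printed token, is linear in $s$,
and preserves the annulus at $s=0$; the alternative
$(1+k)/2,(1-k)/2$ grouping stays available behind the `z_grouping`
switch and neither is treated as ground truth. The valve is static and
rigid (open status); in the flow surrogate the mitral plane is an
orifice whose diameter also sets the default annulus radius. The mesh
export (ASCII STL and legacy VTK polydata) closes the strip in
$\theta$; the writers are deliberately plain text.

## Synthetic flow domain and the rigid-wall surrogate

No patient geometry is available, so the flow domain is an idealized,
labeled stand-in: a circular (2-D) or spherical (3-D voxel) atrium with
a single-lobe "windsock" appendage pouch (ostium 12 mm, pouch
20 × 18 mm) attached through a short neck on the atrial flank, two
pulmonary-vein inlet channels at the roof carrying a fixed 55/45
right/left split, a mitral orifice to the ventricle, and an apical
cannula outlet. Chamber sizes are calibrated by a secant iteration on
the discretized volumes so the labeled regions match the patient's
end-systolic volumes (atrium + appendage 169 cm³, ventricle 295 cm³);
the 3-D voxel mode reproduces both to well under 0.1%. The occluded
variant replaces the pouch and neck by wall and is cell-for-cell
identical elsewhere. The appendage sizes sit in the clinical range for
single-lobe appendages; multi-lobe morphologies are out of scope.

The original study moves the endocardial walls; re-implementing a
dynamic-mesh solver is out of desk scale. Instead the domain is rigid
and the wall motion is replaced by a *flux-equivalent boundary
program*: the pulmonary-vein inflow of the circulation model (which by
construction equals the cannula flow plus the flux equivalent of the
atrial + ventricular volume change) drives the inlets, and the outlet
balances the total inflow at every instant. This preserves the
through-flow, the phasic timing (E wave, diastasis, A wave, the small
pulmonary-venous reversal at the atrial kick) and the washout volume
budget. It is the package's single largest deviation from the study it
emulates, and its consequences are discussed under *Limitations*.

The 2-D mode (default 2.5 mm spacing, 40 mm out-of-plane depth for
area–volume conversion) is the solver scale; the 3-D voxel mode exists
for the volume-faithful geometry checks and is not solved.

## Flow solver

The solver is a Chorin fractional-step scheme on a masked staggered
(MAC) grid: explicit first-order upwind advection, centered diffusion
with no-slip ghost cells, plug profiles at the inlets, a flux-balancing
plug outflow, and an exact pressure projection via a sparse Cholesky
factorization of the masked Laplacian (one pinned cell removes the
constant null space; the prescribed boundary fluxes are balanced
exactly, so the singular system is compatible). The discrete divergence
after projection is at factorization rounding, around $10^{-12}$ s⁻¹,
against a contract of $10^{-8}$. Time step defaults to cycle/750
(0.94 ms at 80 bpm, matching the 0.001 s convention at the study's
heart rate), with automatic sub-stepping to a CFL number of 0.7; runs
cover 12 cycles of which the first 4 are initialization, and 50 fields
per cycle are retained for the metrics. Blood is Newtonian and laminar
(ρ = 1060 kg/m³, μ = 0.0035 Pa·s).

Validation: on a straight channel at low Reynolds number the
mid-channel profile matches plane Poiseuille to 0.25% and the wall
shear stress — evaluated as $\mu\,|u_t|/(h/2)$ from the first cell
center, the linear wall gradient consistent with the ghost-cell
discretization, for which discrete Poiseuille is exact — matches
$6\mu U/w$ to 0.5%.

## Thrombosis metrics

* **Stagnation volume**: fluid volume whose time-averaged velocity
  magnitude over the post-initialization window is below 1 mm/s.
  "Time-averaged velocity" is read as the time average of the
  magnitude — oscillating but moving blood should not count as
  stagnant; the magnitude-of-the-mean-vector alternative is exposed as
  `average = "vector"` and covered by tests.
* **Wall shear stress classification**: per-face time-averaged WSS
  binned into low non-physiological (0–0.2 Pa), physiological
  (0.2–9 Pa) and high (>9 Pa) wall area; the three bins always sum
  exactly to the total wall area. In 2-D, face lengths become areas via
  the out-of-plane depth.
* **Velocity statistics**: volume-weighted time-averaged speed, and the
  volume-weighted mean of each cell's temporal standard deviation (the
  aggregation is not uniquely defined by the source description;
  per-cell-then-average preserves spatial locality of the variation).
* **Recirculation detection**: the diastasis window is located from the
  transmitral minimum between the E and A waves; the detector requires
  simultaneous inflow and outflow across the neck plane (a closed
  exchange gyre) together with a pouch mean speed below the atrial
  mean.

The virtual-ink washout advects a fresh-blood marker (domain initialized
to 0, inflow carries 1) with first-order upwind finite volumes on the
stored fields, sub-stepped to CFL 0.9, clamped to $[0,1]$. Pure
advection is used — no explicit diffusivity — so the scheme's numerical
diffusion is the only mixing mechanism; it biases pouch residence
*downward* and front sharpness accordingly (a plug-flow front still
matches the method-of-characteristics washout to under 5%). Old-blood
percentages are reported at cycle boundaries; appendage residence
normalizes the pouch's old-blood content by its content at the end of
the first washout cycle, the only construction available to an Eulerian
marker (Lagrangian tracking is a non-goal).

## Reporting conventions

Percent changes between scenarios are reported as the integer ceiling
of the signed percentage. This is the convention that reproduces all
six published change/value pairs this package checks itself against
(+55% for 4.2→6.5 cm³, −66% for 4.2→1.4 cm³, −64% for 6.5→2.3 cm³,
+29% for 45→58 cm², −37% for 45→28 cm², −32% for 58→39 cm²): increases
round up, reductions are stated conservatively by their truncated
magnitude. Raw values are retained alongside.

## Problem sizes

The default study conditions are: 750 integrator steps per cardiac
cycle and up to 30 cycles to periodic steady state for the circulation;
a 2-D domain of roughly 1 900 fluid cells at 2.5 mm spacing solved for
12 cycles (9 000 steps) with 50 stored fields per cycle; 8 cycles of
ink transport. The four-scenario experiment completes in a few minutes
on one core. The validation cases (Poiseuille channel, plug-flow
washout) are sized to run in seconds.

## Design choices and degenerate inputs

* Diode valves use small series resistances (4–6 mΩ·s/mL scale); the
  aortic valve simply stays closed under full support, no special
  handling.
* The pressure projection pins one cell; boundary fluxes are balanced
  to rounding before each solve, so the Neumann problem is compatible
  by construction and the pinning does not perturb the solution.
* Inlet profiles are plug-shaped (the source description imposes
  velocity boundary conditions without stating a profile).
* Boundary inflow anywhere — including transient re-entry at the
  outlet — carries marker concentration 1; an Eulerian marker cannot
  distinguish returning old blood.
* Occluded domains report an explicit "no LAA" residence result, not an
  error; zero-flow fields yield full-region stagnation volumes and 100%
  old blood, and degenerate mitral waveforms without any diastolic flow
  raise errors.
* `simulate_lpm` refuses time steps coarser than 750 per cycle and
  reports a convergence error with the residual if the periodic state
  is not reached.

## Limitations

* **Rigid walls.** The flux-equivalent surrogate preserves through-flow
  and phasic timing but not intramural squeezing. In the moving-wall
  original, atrial contraction compresses the appendage and ejects most
  of its content each cycle (ninefold-millilitre exchange per cycle);
  in the rigid surrogate, pouch exchange is driven only by the neck
  shear gyre (~0.1 mL/cycle) and is therefore diffusion-limited and
  slow in *both* rhythms. Consequently the SR-vs-AF ordering of
  appendage residence — which in the original is dominated by the
  kick-squeeze mechanism — is not reproduced: the package's own
  acceptance suite records this as a failing directional check rather
  than masking it. All other directional findings (stagnation,
  low-WSS area, washout acceleration by occlusion, ventricular
  insensitivity, the diastasis recirculation pocket) are reproduced.
* **Pouch-interior velocity is not fully grid-converged.** The
  appendage gyre spins up on a ~10 s viscous timescale and its mean
  speed (≈0.1 cm/s) still changes by ~12% between 2.5 mm and 1.25 mm
  grids; the metrics the scenario comparisons consume (atrial mean
  velocity, atrial stagnation volume) change by ≤2% under the same
  refinement.
* 2-D cross-section flow cannot represent out-of-plane swirl; absolute
  stagnation volumes and WSS areas are not comparable to
  patient-specific 3-D values and are used directionally only.
* The synthetic generator emulates chamber volumes, inflow split,
  phasic waveforms and a single-lobe appendage. It does not emulate
  patient-specific wall shape, trabeculation, pulmonary-vein geometry
  or multi-lobe appendages — passing tests show the *methods* behave
  correctly and the *directional* physiology is reproduced, not that
  patient-specific magnitudes are predicted.
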