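---
title: "Methods: acoustic navigation of microparticles at a vessel bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic navigation of microparticles at a vessel bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(acoustonav)
```

# The model

acoustonav simulates a hybrid navigation scheme for micron-scale drug
carriers: blood-like flow provides the transport, and a focused ultrasound
field steers particles at a Y-shaped bifurcation by *blocking* the unwanted
branch — the acoustic radiation force bars entry, and drag carries the
particles down the open branch. The chain has four physical layers, each a
module of the package.

## Acoustic field: far-field piston array

Each of the (by default 30) transducers is a baffled circular piston of
aperture radius $a$ driven at $f = 1\,\mathrm{MHz}$. At a field point at
distance $d$ and angle $\theta$ from the element normal its contribution is

$$p_j = \frac{A_j}{d}\, D_f(\theta)\, e^{i(\varphi_j + k d)},\qquad
  D_f(\theta) = \frac{2 J_1(a k \sin\theta)}{a k \sin\theta},$$

with $k = 2\pi f / c_0$ and $A_j$ the per-element source strength (the
product of drive amplitude constants, folded into a single scale — see
*Normalisation* below). The array field is the coherent sum over elements;
back-lobe contributions ($\theta \ge \pi/2$) are set to zero because the
far-field piston derivation is forward-only, and points closer than a
quarter wavelength to any element are refused.

**Array geometry.** The elements sit on a spherical cap whose centre of
curvature is the nominal focus, 31 mm above the cap pole, so every element
is exactly equidistant from it; focusing phases
$\varphi_j = -k d_j \bmod 2\pi$ then align all contributions at the focus.
The 75 mm array diameter cannot be the cap chord of a 31 mm-radius
cap (the chord of any cap of that curvature is at most 62 mm), so the
package reads it as the bowl diameter measured along the curved surface.
That gives a deep, nearly hemispherical bowl with half-angle
$\approx 69^\circ$, consistent with a hemispherical multi-element actuator,
and a tight focal spot of roughly one wavelength ($\lambda = 1.45$ mm in
water). The exact ring arrangement is not prescribed anywhere; concentric
rings are the default, a Fibonacci spiral and a from-file table are
alternatives. Because every scenario is re-normalised to a stated peak
pressure, the navigation results are only weakly sensitive to the exact
layout.

**Normalisation.** Scenario strength is specified as the peak pressure
magnitude `acprmax`; `normalize_to_peak()` rescales all element amplitudes
by one factor so the grid maximum of $|P|$ over a box around the focus
equals the target. The field is linear in the amplitudes, so this is exact
and idempotent, and the radiation force scales exactly as
$\mathrm{acprmax}^2$.

## Radiation force: Gor'kov potential, modified convention

For a Rayleigh-regime sphere (diameter $\ll \lambda$) the time-averaged
acoustic force is $F = -\nabla U$ with

$$U = 2 K_1 |p|^2 - 2 K_2 \left(|p_x|^2 + |p_y|^2 + |p_z|^2\right),$$
$$K_1 = \frac{V}{4}\left(\frac{1}{c_0^2 \rho_0} - \frac{1}{c_1^2 \rho_1}\right),
\qquad
K_2 = \frac{3V}{4}\,\frac{\rho_0 - \rho_1}{\omega^2 \rho_0 (\rho_0 + 2\rho_1)}.$$

This is implemented literally. Note that these prefactors differ from the
textbook Gor'kov convention: the monopole term is twice the classic one and
the gradient (dipole) term enters with the opposite sign, so for
polystyrene in water *both* terms are repulsive and the potential hill at a
focus is about three times the classic height. This modified form is the
package default, and `gorkov_coefficients(variant = "classic")` provides
the textbook coefficients for cross-checks. The absolute force scale is in
any case anchored by the peak-pressure normalisation.

For 10 µm polystyrene in water at 1 MHz: $K_1 \approx 7.0\times10^{-27}$,
$K_2 \approx -1.7\times10^{-34}$; at a 1.5 MPa focus the potential hill is
$\sim 4\times10^{-14}$ J and the peak force $\sim 10^{-10}$ N, i.e. a
Stokes slip velocity of order 1 mm/s — deliberately comparable to the flow.

Derivatives (of the pressure for $U$, and of $U$ for the force) are
second-order central differences with step $\lambda/200$; the field varies
on the wavelength scale, so the relative stencil error is
$\sim (2\pi/200)^2/6 \approx 2\times10^{-4}$, and tests pin the gradient
against a ten-times finer stencil. Inside `simulate_particles()` the force
is precomputed once on a regular grid of spacing $\lambda/20$ (the field is
static while the tracer takes $10^4$–$10^5$ steps) and trilinearly
interpolated; the grid path agrees with the pointwise stencil force to a
few percent and a dedicated test keeps both paths within 5 %.

## Flow: analytic laminar bifurcation field

Rather than solving the creeping-flow equations numerically, the package
uses an analytic field. The lumen is a union of three cylinders (inlet
along $+X$, two mirror-image daughter branches separated by 60° — a
configurable modelling choice), and the velocity field is a construction:
Poiseuille profiles in each straight segment with mean speeds fixed by flux
conservation ($Q_\mathrm{in} = Q_L + Q_R$), blended over one inlet radius
around the apex with a smoothstep in the axial coordinate. The transverse
profile is built from the *union* signed wall distance, which makes no-slip
exact on the whole wall including the junction seam; flux conservation
holds exactly in the straight segments and the junction blend is the only
approximate region. At $\mathrm{Re} < 10$ this is a reasonable stand-in for
the numerical creeping-flow solution; what it does not reproduce are the
secondary-flow details inside the junction itself.

Two geometry presets ship:

* `"bench"`: 3.0 mm inlet tapering to two 1.5 mm outlets — the gelatin
  bench-phantom geometry, and the package default. Note that the taper
  *accelerates* the branch flow fourfold.
* `"uniform"`: uniform 2 mm vessel. Here each branch carries half the flux
  through the same cross-section, so the branch flow *decelerates* to half
  the inlet speed.

The navigation studies (focus optimisation, pressure/velocity sweeps) use
the uniform 2 mm preset: it keeps the Reynolds number in the intended 2–9
laminar window over the 1–4 mm/s operating range, and gating a branch with
megapascal-scale radiation forces (Stokes slip of order 1 mm/s) is only
dimensionally sensible where the junction decelerates the flow — in the
tapered phantom the branch flow outruns the force at any focus position.
The no-field baseline and the bench-count statistics use the tapered
phantom, which is the geometry they describe.

**Medium.** Water: $\rho_0 = 997$ kg/m³, $c_0 = 1450$ m/s,
$\eta = 10^{-3}$ Pa s — the working fluid of the bench experiment, and the
viscosity consistent with the Reynolds window above. A blood-like
$5\times10^{-3}$ Pa s ships as `medium_preset("blood_like")` and mainly
rescales the drag. Particle presets: polystyrene 1050 kg/m³ (default) and
a lighter 1032 kg/m³ suspension-bead variant.

## Particle transport

The equation of motion is
$m_p \dot v = F_\mathrm{rad} + F_d + F_c$ with Stokes drag
$F_d = (m_p/\tau_p)(u - v)$, $\tau_p = \rho_p d_p^2 / 18\eta$
(about 1 µs for a 10 µm bead — algebraically identical to
$3\pi\eta d_p (u - v)$). Transit times are seconds, so the default
integrator is the overdamped limit

$$v = u + \frac{F_\mathrm{rad}}{3\pi\eta d_p},$$

in which the velocity is slaved to the local force balance. The explicit
inertial integrator (stability-guarded at $\Delta t \le \tau_p/5$) is
retained for validation; a test drives both integrators over a millimetre
of a smooth synthetic field and requires agreement within a tenth of a
particle diameter.

**Release protocol.** 100 particles in 4 temporal steps of 25, released on
the inlet cross-section with the local fluid velocity. The default spatial
law is uniform over a disk of 0.9 of the inlet radius — particles are not
seeded into the extreme no-slip layer, where transit times diverge; the
0.9 fraction is a fixed modelling choice, not a fitted value. A `mirrored`
mode draws exact $\pm y$ pairs so that symmetric baselines split exactly
even; a `ring_biased` mode mimics a rim-weighted upstream distribution.
The schedule seed fully determines the ensemble and outcome counts are
bit-reproducible.

**Contact and adhesion ($F_c$).** Particle–wall contact has no canonical
closed form, so it is operationalised: within one particle
diameter of the wall the wall-normal velocity component is specularly
reflected (restitution 1 by default); a particle whose net acoustic force
presses it into the wall while it moves slower than 1 % of the mean inlet
speed for 50 consecutive steps adheres permanently. These thresholds are
configurable; the defaults are stated here once and used everywhere.

**Time step.** Chosen so the fastest particle moves about half a particle
diameter per step ($\Delta t = 0.5 d_p / (1.25\,v_\mathrm{peak})$), which
resolves the wall-gap bookkeeping; the force field varies on the 0.5 mm
scale, three orders of magnitude coarser. The time cap is twelve mean
transit times; particles still in transit then are reported `timed_out`
(under blocking these are particles held indefinitely against the acoustic
barrier — physically "blocked", but they are counted *against* the
navigation efficiency, which is strictly the percentage exiting the target
branch).

# The studies

`run_scenario()` wires the layers together: phase the array at a focus,
normalise to `acprmax`, precompute the force grid, trace the ensemble,
count outcomes. `optimize_focus()` formalises manual focus placement
as a grid search over candidate focal points — by
default a transverse line across the mouth of the blocked branch at the
vessel midplane — with a lexicographic objective: maximise efficiency,
then minimise adhesions. `run_sweep()` enumerates factorial grids and
reuses one force grid per focus (the force is exactly quadratic in the
peak pressure and cubic in the diameter, so rescaling is exact).
`size_dependence_study()` adds a single-particle probe released on the
inlet centreline whose lateral displacement at the apex plane measures the
field deflection; since force $\propto d_p^3$ and drag $\propto d_p$, the
probe deflection scales as $d_p^2$, and the study reports the fitted
log–log exponent.

Problem sizes used by the shipped tests and the acceptance script: 100
particles (the study protocol), five focus candidates per optimisation,
and ladders of three to five pressures/velocities; a full optimisation is
a few minutes of single-core time.

# Hemocytometer statistics

The bench-validation module is plain counting arithmetic, reproduced
exactly: concentration is the standard 4-square hemocytometer formula
(mean count per large square × 10⁴ per mL — the only factor that
reproduces the concentration row of the bundled bench table); channel
percentages are totals over the channel pair per sample; the cross-sample
"±" is the standard error of the mean (for two samples, half the absolute
difference — both channel pairs of the bench table verify this, ruling
out the standard deviation). All arithmetic is at full precision;
two-decimal rounding is presentation only.

# Numerical choices, degenerate inputs, limitations

* Ties and degeneracies: a single-element "array" is a legal layout (pole
  element, axial normal); `twin_trap_phases` refuses a split axis parallel
  to the array axis; zero-amplitude arrays short-circuit to the pure-drag
  baseline; a particle exactly on a vessel axis has no defined wall normal
  and is assigned an arbitrary one (it is a radius away from any wall).
* The force grid clamps interpolation at its box edges; the box always
  covers the lumen with margin, so clamping is never exercised by the
  simulator.
* Mirror-exactness: the flow kernel is written so that $\pm y$ mirror
  points evaluate to exactly mirrored velocities in floating point; the
  no-field mirrored baseline therefore splits exactly 50/50, not just
  statistically.
* What passing tests do **not** show: the analytic junction blend is not a
  Navier–Stokes solution, so adhesion counts and precise blocking-pressure
  thresholds of a finite-element treatment are reproduced only
  directionally (monotone trends, saturation ordering), not numerically;
  pulsatile or non-Newtonian flow, acoustic streaming, particle–particle
  interactions, wall elasticity and near-boundary corrections to both drag
  and radiation force are all out of scope.
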