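---
title: "Models, numerics and design choices in sawstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in sawstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sawstream)
```

sawstream simulates particle and cell separation in SSAW/taSSAW
microchannels through a chain of reduced physical models. This vignette
states each model, its assumptions, the tunable parameters with units and
defaults, the numerical choices, and what the synthetic configurations do
and do not establish.

## 1. The perturbation picture

All fluid quantities are split into a first-order time-harmonic acoustic
part and a second-order steady (time-averaged) part. The first-order
pressure obeys a lossy Helmholtz equation with wavenumber
$k = (1+i\gamma)\,\omega/c_0$; in water at MHz frequencies
$\gamma \ll 1$, so the bulk damping defaults to $\gamma = 0$ (the lossy
wavenumber is retained as an option). The steady part obeys creeping-flow
(Stokes) equations, $\nabla p_2 = \eta \nabla^2 v_2$,
$\nabla \cdot v_2 = 0$: inertia is negligible at microfluidic Reynolds
numbers.

## 2. The semi-analytic channel field

Instead of solving the Helmholtz boundary-value problem with impedance
walls (a finite-element task), the working-region field is the ideal
standing wave

$$p_1 = p_a \cos\!\big(k_s (x_r - x_{\rm ref})\big), \qquad
  k_s = 2\pi/\lambda_{\rm SAW}, \qquad
  x_r = x\sin\theta + y\cos\theta,$$

uniform in $z$. The geometry is exact for the taSSAW layout: nodal lines
(where positive-contrast particles collect) lie at angle $\theta$ to the
flow axis with spacing $(\lambda/2)/\cos\theta$ across the width. The
uniform-$z$ assumption rests on shallow channels ($h/\lambda \le 0.2$;
the constructor warns beyond that and hard-warns above $0.5$).

**Frequency convention.** Two requirements fix the field's internal
angular frequency: the imposed wavelength is $\lambda_{\rm SAW}$, and the
velocity relation $v_1 = -(i/\rho_0\omega)\nabla p_1$ must give the
standing-plane-wave amplitude $|v_1| = p_a/(\rho_0 c_0)$ (on which the
classical slip and radiation-force formulas rest). These hold together
only with $\omega_{\rm eff} = c_0 k_s$, the fluid dispersion of the
imposed wavelength. The SAW *drive* frequency (e.g. 19.32 MHz at
$\lambda = 200\,\mu$m) is therefore retained as metadata and is used
where the oscillation rate itself matters physically: the viscous
boundary-layer thickness $\delta_\nu = \sqrt{2\nu/\omega_{\rm drive}}$
entering the scattering coefficients. This is a deliberate reduction: in
the real device the channel field is three-dimensional and satisfies the
fluid dispersion through its vertical structure, which the shallow
uniform-$z$ model integrates out.

**Amplitude calibration.** $p_a$ maps linearly from the drive voltage
through a per-stage calibration pair, $p_a = p_{\rm cal} V/V_{\rm cal}$
(defaults: 7.5 V → 1 MPa for the validation device; 10 V → 0.5 MPa
focusing and 40 V → 1 MPa separation for the sheathless design). Input
power in dBm uses $P \propto V^2$:
${\rm dBm}(V) = {\rm dBm}_{\rm ref} + 20\log_{10}(V/V_{\rm ref})$,
rounded to the nearest integer by default. The two reference devices use
*incompatible* pairs (7.5 V ↔ 26.5 dBm vs 20 V ↔ 26.5 dBm), so
calibrations are always per-device configuration, never global.

## 3. Substrate: partial-wave SAW solver

The free-surface Rayleigh wave on the rotated piezoelectric half-space is
computed with the quasi-static 4-field Stroh formalism: plane waves
$\exp[i k (x + \alpha z - v t)]$ in displacement and potential lead to a
quadratic eigenproblem in the depth wavenumber $\alpha$; the four decaying
branches ($\mathrm{Im}\,\alpha < 0$ for a substrate at $z<0$) are combined
to zero the four surface conditions (traction-free, charge-free). The
phase velocity is found by a 201-sample scan of the normalized boundary
determinant over the bracket, `optimize()` refinement, and a final
vertex-sharpening of the smallest singular value (which varies as
$s\,|v-v^*|$ near a true root); boundary residuals reach $10^{-13}$.
Numerical notes:

- tensors are nondimensionalized (stiffness by $c_{\rm ref}$,
  permittivity by $\varepsilon_{\rm ref}$, potential rescaled by
  $\sqrt{\varepsilon_{\rm ref}/c_{\rm ref}}$); otherwise the $z$-block
  mixes $10^{11}$ Pa with $10^{-11}$ F/m and is numerically singular;
- eigenpairs from the companion linearization are polished by two
  Newton/inverse-iteration sweeps on the quadratic pencil;
- leaky/pseudo-SAW branches (complex roots) are out of scope.

The LiNbO₃ single-crystal constants are the standard literature set
(stress-charge form, class 3m); they are validated through the property
they are used for: the 128° YX cut must reproduce the known SAW speed
(3996 m/s computed vs 3997 m/s tabulated). The cut is a single rotation
about crystal X by $128°-90°$; with this package's rotation convention
the negative angle reproduces the known speed, and the `sense` argument
exposes the mirror cut (3677 m/s). A free-surface solver predicts the
unloaded-substrate operating point $c_{\rm sub}/\lambda \approx 9.99$ MHz
at $\lambda = 400\,\mu$m; the loaded-device resonance of a full IDT model
(9.63 MHz in the design this emulates) is *expected* to differ — the
discrepancy is documented, not reconciled, and device presets accept the
frequency as configuration.

## 4. Limiting-velocity slip and the streaming solve

Resolving the $\sim 0.2\,\mu$m boundary layer in 3D is prohibitively
expensive; instead the steady slip just outside the layer (Nyborg's
near-boundary solution with the Lee–Wang modification) is imposed on the
substrate face:

$$u_L = -\frac{1}{4\omega}\mathrm{Re}\Big\{u_{a0}\partial_x u_{a0}^* +
 v_{a0}\partial_y u_{a0}^* + u_{a0}^*\big[(2+i)
 (\partial_x u_{a0} + \partial_y v_{a0} + \partial_z w_{a0})
 - (2+3i)\partial_z w_{a0}\big]\Big\}$$

(and symmetrically for $v_L$), where the tangential amplitudes are
fluid-minus-wall differences and the normal one is continuous. For the 1D
standing wave this reduces to Rayleigh's
$-\tfrac38 (v_a^2/c_0)\sin 2kx$; at $p_a = 1$ MPa in water the slip
amplitude is $1.12\times10^{-4}$ m/s, the same order as (about half) the
0.23 mm/s maximum computed by the full finite-element treatment of the
reference device — an order-of-magnitude agreement is all the reduced
field warrants. The slip magnitude vanishes on both nodal and antinodal
loci, which is how the slip pattern registers with the pressure pattern.

Only the bottom (substrate) interface carries slip; top and side PDMS
walls are rigid no-slip. The Stokes solve uses a staggered (MAC) grid in
$(y, z)$ with a Fourier representation of the periodic flow axis: each
$x$-mode decouples into a small 2D saddle problem, assembled once and
solved directly (sparse LU) per mode, so the default $96\times48\times16$
grid takes seconds and the discrete divergence sits at solver precision
($<10^{-12}$ relative). Pressure is gauged by pinning one cell (velocities
are provably independent of the choice; the suite checks it). Channel
ends are periodic by default, matching the Fourier axis; a "stress-free"
option realizes symmetry planes at both ends by mirror extension.
Reported $p_2$ is the Stokes dynamic pressure only: peak second-order
pressures quoted for the reference device ($\sim$100 Pa) include
Reynolds-stress/Bernoulli contributions of order $\rho v_a^2/2$ that this
decomposition does not attribute to $p_2$, so no check is tied to that
number.

## 5. Forces and tracing

The radiation force is evaluated exactly as written in the
scattering-theory form with complex conjugations, the full velocity
Jacobian for $(v_1^*\!\cdot\!\nabla)v_1$, and analytic gradients for the
built-in field (central differences, step $\lambda/400$, for gridded
fields). Its closed-form standing-wave limit and the identity
$3\Phi = \varphi$ are enforced in the test suite to $10^{-10}$ and
$10^{-12}$. Viscosity enters only through
$\tilde\delta_\nu = \delta_\nu/r$ in the dipole coefficient; wall-drag
corrections, particle–particle interactions and thermoviscous effects
are out of scope.

Tracing defaults to the overdamped limit
$v^p = v_{\rm fluid} + F^{\rm rad}/(6\pi\eta r)$ (velocity relaxation
times $m/6\pi\eta r$ are microseconds), integrated with an adaptive
Dormand–Prince scheme; the inertial mode keeps $m\dot v$ with an
exponential integrator exact for the stiff drag term, and the two agree
to $<1\%$ at these Stokes numbers. The vertical coordinate is held fixed
by default (20 µm above the substrate, the plane on which reference
fields are reported) on the argument that vertical radiation force and
buoyancy balance vertical drag in shallow channels; full 3D is an option.
Side walls are impenetrable: trajectories are projected to keep particle
centers at least a radius away, which mirrors the sidewall-aggregation
behaviour discussed for these devices. Release positions are
deterministic from configuration; a particle released exactly on an
antinode sits on an unstable equilibrium, so optional jitter with an
explicit seed is the documented tie-breaker.

## 6. Devices, presets and the saturation regime

The sheathless three-stage preset encodes: focusing stage of width
$\lambda/2$ (exactly one nodal line, so both species collapse onto one
lane), a realignment junction where a side stream redirects the inclined
particle-laden flow parallel to the sidewall (side-stream direction from
transverse momentum balance, magnitudes from mass conservation — flux is
conserved to machine precision), and a taSSAW separation stage. Stage
lengths are not printed for the reference design; defaults (5, 1.5,
2.5 mm) give every stage a residence time at least three times the
relevant focusing/realignment time at the preset flows, and the
separation length keeps the geometric nodal-line drift
$L\tan\theta \approx 441\,\mu$m inside the 1 mm width. The validation
preset's inlet speed is likewise unprinted; it borrows 6 mm/s from the
sheathless design (overridable, and flagged in the preset help).

**What a green device test establishes — and the saturation caveat.** In
the uniform-amplitude field a species is *fully trapped* once its peak
radiation-force velocity exceeds the flow component perpendicular to the
nodal lines; a trapped species drifts along the lines at the geometric
rate regardless of further drive increases. Consequently the outlet
separation $\delta(V)$ grows roughly as $V^2(r_1^3 - r_2^3)$ while both
species are sub-trapped, peaks when only the large species is trapped
(≈382 µm at 20 V for the bead preset — the same scale as the reported
402.5 µm outlet distance of the reference design), and *collapses* once
both species trap (30–40 V here). The real device's non-uniform field
softens trapping, which is why its optimum sits at higher voltage. The
monotonicity-in-voltage invariant is therefore asserted on the
sub-saturation grid (6–18 V), and the printed outlet distances (180 µm
validation; 402.5/135.8 µm sheathless) are reported for qualitative
comparison only — they depend on unpublished full-FEM fields and flow
details. Size *ordering* (10 µm > 4 µm, MCF-7 > WBC in outlet lateral
displacement) is robust across regimes and is asserted at the presets.

## 7. Validity limits

The slip condition assumes boundaries flat on the scale of
$\delta_\nu$, strictly laminar flow, and a high Womersley-type number
$|M| = h\sqrt{\omega/\nu} \gg 1$; `limiting_validity()` computes
$\delta_\nu$, $|M|$ and curvature ratios and flags violations (at
9.63 MHz in a 75 µm water channel: $\delta_\nu \approx 0.17\,\mu$m,
$|M| \approx 10^3$ — comfortably valid; $\omega \to 0$ or
curvature radii comparable to $\delta_\nu$ are flagged).

Known limitations, beyond those already noted: no IDT/electrode or
mass-loading model (the substrate solver is an unloaded-surface
surrogate); no acoustic impedance or outlet-absorption boundary
conditions on the channel walls; no Brownian motion, lift forces, or
particle collisions; single-frequency continuous-wave drive only.

## 8. Numerical summary

| quantity | default | rationale |
|---|---|---|
| boundary-determinant scan | 201 samples/bracket | robust bracketing of the single Rayleigh root |
| SAW depth profile grid | 400 points over $2\lambda$ | mode energy ≥ 99% within $1\lambda$ |
| streaming grid | $96\times48\times16$ | divergence $<10^{-12}$; seconds at desk scale |
| linear solves | direct sparse LU per Fourier mode | exact linearity in slip amplitude |
| tracer tolerance | $10^{-6}$ relative (RK45) | halving changes outlet positions $<0.1\%$ |
| force gradients | analytic (built-in fields) | closed-form oracle agreement to $10^{-10}$ |
| gauge pin | cell (1,1) | velocities independent of the choice |

Every numerical claim above is asserted by the test suite; this vignette
states no empirical result that the tests or the acceptance script do not
themselves compute.
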