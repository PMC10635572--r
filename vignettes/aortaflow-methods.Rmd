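---
title: "Methods: immersed-boundary hemodynamics of aortic-stenosis jet flow"
author: "aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immersed-boundary hemodynamics of aortic-stenosis jet flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Severe aortic stenosis forces a narrow, fast systolic jet (peak velocities
around 2.7 m/s and above) through the valve into the ascending aorta (AAo).
Where that jet impinges on the outer curvature of the vessel it deposits a
*focal* patch of elevated, oscillatory wall shear stress (WSS) together
with a persistent pocket of elevated wall pressure; both are candidate
drivers of local aortic dilation. Whether the pattern is focal or
*dispersed* depends, among other things, on whether the brachiocephalic
artery inlet sits on top of the impingement site (its suction disturbs the
jet) or safely distal of it. `aortaflow` provides a desk-scale simulation
and analysis chain for exactly this question: an incompressible
Navier-Stokes solver with a sharp-interface immersed boundary, an
echo-derived plug-jet inflow, a two-element Windkessel outflow pressure
model, and the wall-field diagnostics (WSS maps, circumferential band
unwrapping, probe pressure traces, buildup/oscillation metrics) that
separate the two regimes.

## Model and discretization

The solver integrates the dimensionless incompressible Navier-Stokes
equations on a uniform staggered (MAC) Cartesian grid. Velocities are
scaled by a reference `U0` (normally the diseased peak jet velocity),
lengths by `L0` (the inlet lumen diameter), and the Reynolds number
`Re = U0 L0 / nu` sets the viscosity. Time stepping is the three-stage
low-storage Runge-Kutta scheme with an adaptive CFL-limited step capped by
the explicit diffusive limit `0.25 dx^2 Re` (CFL defaults to 0.5).

Spatial derivatives are centred finite differences. The exposed operator
`fd_apply()` provides orders 2/4/6 (sixth order is the interior default
for the viscous terms, reduced gracefully to second order within two cells
of the immersed boundary and the fringe zones, where no high-order closure
exists). The *advective* terms use the second-order skew-symmetric form
`N = -(u.grad u + div(u u))/2` on the staggered lattice. This is a
deliberate design choice: the skew form is discretely energy-conserving
for divergence-free fields, which is what keeps a non-dissipative central
scheme stable on the coarse grids this package targets; a pure
high-order advective form at 5-8 cells across the jet shear layer
aliases and blows up shortly after peak flow. A sixth-difference low-pass
filter (config `filter_amp`, default 0.1 at the Nyquist mode, exact on
polynomials through degree 5) is applied to the velocity once per step on
well-resolved interior faces only; it removes the residual grid-scale
pile-up that the energy-conserving advection cannot dissipate. The
advective time-step limit uses the summed form
`CFL / max(|u|/dx + |v|/dy + |w|/dz)`: a per-axis rule under-constrains
corner flows in which all three components are comparable and admits a
step-size-independent instability there.

Each Runge-Kutta stage ends with a pressure projection: the variable-free
7-point Poisson problem is solved by preconditioned conjugate gradients
(symmetric Gauss-Seidel preconditioner, matrix-free on the masked fluid
region) to a residual that keeps the post-projection divergence below
1e-8. Projecting per stage rather than per step is a tighter-divergence
choice the original formulation leaves open.

## Geometry and the immersed boundary

Geometry enters as a signed-distance field `phi` on cell centres,
negative in the fluid (the convention is fixed here; sources leave it
unstated). Two constructors exist: a procedural idealized ("candy-cane")
aorta — straight ascending/descending limbs of uniform lumen radius
joined by a half-torus arch, with three neck-artery branch tubes — built
from exact primitive distances combined by minimum; and
`levelset_from_mask()`, which converts a binary segmentation mask (raw
uint8 + JSON sidecar, emulating any segmentation export) through an exact
Euclidean distance transform with anisotropic spacing honoured.

Cells are tagged fluid (`phi < 0`), boundary (fluid with a solid
face-neighbour) or solid. The sharp interface is enforced by
reconstructing near-wall face velocities as the quadratic no-slip profile
through the wall (located sub-cell by `phi`) and two interpolated fluid
probes along the local normal at depths `2h` and `4h`. Probe depths
matter: shallower probes sample inside the reconstruction band itself,
and in concave corners (branch junctions) two mutually-reconstructed
faces can feed back with gain above one — a dt-independent instability.
A band of "ghost" faces just inside the solid carries the same quadratic
extension so that interpolation stencils and the traction extraction see
a smooth field across the wall; ghost faces are excluded from the
continuity equation (walls are impermeable) and from the CFL search.

### Default idealized anatomy

Lumen radius 14.5 mm, arch radius 35 mm, ascending length 45 mm; branch
radii 5.5/4.0/4.5 mm at arc angles 1.15/1.60/2.05 rad. Branch radii are
physiological (brachiocephalic diameter ~11 mm) and deliberately not
smaller: tubes only 2 cells in radius are unresolvable and were the first
source of spurious velocity at the desk resolution. Likewise the arc
spacing keeps at least 3 cells of solid between adjacent branch tubes — a
sub-cell sliver of wall between two tubes produces degenerate normals and
a local reconstruction instability. The jet impingement point is
geometric: the centred plug jet meets the outer arch wall at arc angle
`acos(R/(R+a))` (`impingement_angle()`), which is 45 degrees for the
default radii. The "proximal" variant of the mechanism experiment moves
the brachiocephalic inlet onto exactly that point
(`proximal_brachio_offset()`); the default geometry keeps it distal.

## Boundary conditions

All inflow/outflow forcing lives in *fringe zones*: straight tube
extensions outside the anatomical region. The inlet fringe forces the
plug jet of Eq-type `w = U_echo(t)` on the disc of radius
`r_jet = sqrt(Q_peak/(pi U_peak))` about the cross-section centroid and
zero on the surrounding cusp region, with an optional seeded white-noise
perturbation (1% of peak, jet region only) that triggers transition on
coarse grids. The descending-aorta fringe imposes the Windkessel pressure
as a Dirichlet value in the projection with zero-gradient velocity plus a
global flux correction that closes the mass budget each stage.

The neck arteries are modelled as *adaptive suction regions*: the whole
protruding branch tubes are prescribed (they are only a few cells wide —
too narrow to carry free dynamics at this resolution), and together they
draw 15% of the instantaneous inflow, the standard physiological split.
The split among the three branches is proportional to each mouth's
overpressure relative to the Windkessel reference, so a branch sitting on
the jet-impingement stagnation pocket discharges it preferentially —
which is precisely the wall-suction / pressure-discharge mechanism the
proximal-brachiocephalic experiment probes. A literal traction-free neck
outlet is not viable at desk scale: with no distal resistance, a
pressure-free hole over the stagnation pocket swallows several times the
physiological flow and destabilizes the run; fixing each branch at a
rigid 5% instead suppresses the discharge mechanism entirely. The
adaptive split keeps the physiological total while letting the
per-branch fractions respond to the local pressure, and the closing flux
correction at the descending outlet still balances mass exactly.

## Windkessel model

The two-element Windkessel `Q = P/R + C dP/dt` is integrated with a
fixed-step classic Runge-Kutta scheme (`dt <= T/1000`; 1 mmHg =
133.322 Pa internally). Because the ODE is linear, the periodic initial
pressure is the exact fixed point of the affine period map, obtained from
two integrations. Calibration to diastolic/systolic targets (80/120 mmHg
by default) initializes the resistance from the mean identity
`mean(P) = R mean(Q)` and solves the two-parameter root problem in
`log R, log C` by Nelder-Mead to 0.1 mmHg on both extrema. For the
sinusoidal-systole/null-diastole flow waveform the closed-form periodic
solution (particular sine/cosine response plus exponential decay) is used
as the independent oracle in the test suite.

## Wall fields and metrics

Wall samples sit at the foot of the normal from each boundary cell (no
surface mesh exists or is needed). At a no-slip wall the traction
simplifies: tangentially to `mu du_t/dn` (one-sided second-order normal
derivative through two quadratically interpolated fluid probes and the
zero wall value) and normally to `-p n` (pressure extrapolated linearly
along the normal, consistent with its Neumann closure; solid cells
adjacent to the wall mirror their fluid neighbours' pressure after every
projection). The WSS magnitude removes the normal component and is
invariant under flipping `n`. Stresses are dimensionalized with
`mu_eff = rho U0 L0 / Re` so reported values are consistent with the
simulated momentum balance; at physiological `Re` this is the blood
viscosity itself.

Beat instances follow the named fractions of the systolic waveform: PF is
the (earliest) flow maximum, ES the first decay below 2% of peak, MA half
way from pulse start to PF, 3QA halfway from MA to PF, MD halfway from PF
to ES, QD halfway from PF to MD.

The *band* is the wall cut by a plane normal to the local centreline at
the impingement angle, parameterized by the angle about the band centroid
(theta = 0 on the outer-curvature side); WSS is collected per time step
onto the (t, theta) plane. The *focality score* quantifies the
style focal/dispersed contrast as the circular concentration
`|sum(w e^{i theta})| / sum(w)` of weights `w(theta)` given by the
time-integrated WSS excess above the per-time band median: 1 for a single
hotspot, 0 for uniform or antipodally balanced elevation.

Probe pressures are sampled trilinearly at 1400 Hz. The oscillation
metric takes the window from 3QA to MD, high-pass filters it (zero-phase
Butterworth, 20 Hz cutoff — the scale separating beat-scale buildup from
turbulent oscillation; a config key) and reports `|dp|max / p_i`, the
filtered max-minus-min over the pressure at 3QA. Buildup is declared when
the complementary low-pass component stays above `p_i` (with a quarter-
margin allowance at the window edge, where the signal starts at `p_i` by
construction) and its mean exceeds `p_i` by a margin (default 200 Pa,
well below the ~4 kPa stagnation head of the diseased jet but above the
numerical noise floor). The zero-phase filters use odd-reflection padding;
without it the edge transients of a 20 Hz filter dominate a 0.1 s window.

## Desk-scale operating point and what it shows

The reference fidelity of this class of simulation is a 512-cube grid at
physiological Reynolds number, days of GPU time per beat. The package's
matched mechanism runs use a 2 mm grid (about 58 x 23 x 64 cells over the
idealized aorta), `Re = 1000`, the diseased waveform (peak 2.7 m/s,
60 bpm), 1% seeded jet noise, and integrate t in [0, 0.25 s], which
covers 3QA through MD; the Poiseuille/Womersley benchmarks run at up to
64 cells per diameter. At this scale the jet spans only ~7 cells, so the
flow is laminar-to-transitional rather than turbulent: passing the
mechanism tests shows that the *geometric* mechanism (disturbed versus
undisturbed impingement, removal of the focal pattern after virtual valve
replacement) survives coarse resolution, not that the turbulent
amplitudes of the full-fidelity study are reproduced. The ~1000 Pa probe
overpressure of the full-scale study is therefore retained only as an
ordering property (impingement probe A above its neighbours B-D) at desk
scale.

The synthetic inputs mirror the study conditions: `Q_peak = 4e-4 m^3/s`,
sinusoidal systole of 0.3 s in a 1 s beat, descending fraction 0.85,
Windkessel targets 80/120 mmHg, and the restored models (tripled jet
area at maintained flow waveform, 0.9 m/s; stressed variant doubled to
1.8 m/s). The generator does not emulate: patient-specific lumen shape
and out-of-plane arch bending, valve cusp asymmetry (jets are circular
and centred), wall motion, or beat-to-beat variability.

## Numerical choices and degenerate inputs

* Signed distance is exact for the analytic primitives and min-combined;
  the `|grad phi| = 1` property holds away from medial/junction creases
  (the classification and reconstruction only use `phi` near the wall,
  where it is clean; a handful of degenerate junction normals fall back
  to a nearest-neighbour rule and are logged).
* Ties at the waveform maximum take the earliest time with a warning; a
  waveform that never decays below 2% of peak sets ES to the period with
  a warning.
* A silent echo trace (`U_peak = 0`) produces an empty jet and a zero
  inflow field rather than an error.
* An all-Neumann pressure problem with incompatible right-hand side is
  projected onto the compatible subspace (mean removed) with a warning
  and returns the mean-zero solution.
* Probe locations are validated against `phi`; a probe in the solid is a
  placement error naming the probe.
* The flux-correction monitor counts steps whose pre-projection mismatch
  exceeds 10% of inflow only once the inflow is established (above 5% of
  peak); a persistent excess for more than 100 steps aborts the run.
* Checkpoints store the state, the RNG state and a configuration
  fingerprint; resuming reproduces the continued run bitwise. Snapshots
  and checkpoints use R native serialization (no HDF5 interface is
  assumed); legacy VTK structured-points/polydata and binary STL writers
  cover visualization export.

## Known limitations

Momentum advection is formally second order (the skew-symmetric
stabilization trades the interior sixth-order advective stencils for
discrete energy conservation); diffusion and the exposed derivative
operators are up to sixth order. Walls are rigid. The neck arteries carry
a prescribed physiological split rather than an impedance model, and the
descending outlet uses a two-element (not three-element) Windkessel. The
band and probe defaults are geometric constructions for the idealized
anatomy — on mask-derived patient geometries the user must place them.
Desk-scale runs under-resolve the jet shear layer; quantitative WSS and
pressure amplitudes at physiological Reynolds number require the
configuration-reachable fine-grid operating point and corresponding
compute.
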