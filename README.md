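# aortaflow

Desk-scale computational hemodynamics of aortic-stenosis jet flow, for
researchers studying why some stenotic aortas dilate and others do not.

Severe aortic stenosis drives a fast systolic jet (peak velocity ~2.7 m/s)
into the ascending aorta. Where the jet impinges on the outer curvature it
leaves a **focal** patch of elevated, oscillatory wall shear stress and a
persistent pocket of elevated wall pressure — a candidate driver of local
dilation. If the brachiocephalic artery inlet sits on the impingement site,
its suction disturbs the jet and the pattern becomes **dispersed**.
`aortaflow` implements the full simulation-and-analysis chain for this
mechanism at laptop scale:

* **Solver** — dimensionless incompressible Navier–Stokes on a staggered
  Cartesian grid; low-storage RK3 in time with per-stage pressure
  projection (preconditioned CG); skew-symmetric (energy-conserving)
  advection with centred stencils up to 6th order for diffusion and the
  exposed operators; sharp-interface immersed boundary from a
  signed-distance map (no surface mesh).
* **Geometry** — a procedural idealized ("candy-cane") aorta with three
  neck branches and a movable brachiocephalic inlet, or any binary
  segmentation mask (raw voxels + JSON sidecar) via an exact Euclidean
  distance transform.
* **Boundary conditions** — echo-derived plug jet of radius
  `r_jet = sqrt(Q_peak / (pi U_peak))` forced in an inlet fringe zone; a
  two-element Windkessel pressure `Q = P/R_out + C_out dP/dt` calibrated
  to diastolic/systolic targets at the descending outlet; neck arteries
  carrying the physiological 15% split.
* **Post-processing** — wall shear stress `sigma_w = |(sigma.n) -
  ((sigma.n).n) n|` and wall pressure maps, beat instances (MA, 3QA, PF,
  QD, MD, ES), circumferential band unwrapping over angle theta, probe
  pressure traces at 1400 Hz, the oscillation metric `|dp|max / p_i`, a
  pressure-buildup classifier and a circular focality score.

## Worked example

Calibrate the Windkessel to 80/120 mmHg on the standard sinusoidal-systole
flow waveform and run one diseased beat through peak flow on the idealized
aorta:

```r
library(aortaflow)

spec <- idealized_aorta_spec()                 # lumen 14.5 mm, arch 35 mm
geom <- make_idealized_aorta(spec, default_idealized_grid(spec, 0.002))

wf   <- synth_waveform(2.7, T_sys = 0.3, period = 1)   # 60 bpm echo trace
flow <- flowrate_waveform(wf, fraction = 0.85, Q_peak = 4e-4)
wk   <- wk2_calibrate(flow, 80, 120)
round(range(attr(wk, "waveform")$pressure_mmHg), 1)
#> [1]  80 120

inflow <- build_inflow(geom, wf, Q_peak = 4e-4)
round(inflow$r_jet * 1000, 2)                  # jet radius, mm
#> [1] 6.87

cfg <- sim_config(Re = 1000, U0 = 2.7, L0 = 2 * spec$lumen_radius,
                  noise_amp = 0.01, noise_seed = 7)
run <- run_beat(geom, cfg, inflow, wk, t_end = 0.25,
                probes = default_probes(geom),      # A at the impingement
                band = default_aao_band(geom))      # cut through it

inst <- beat_instances(flow)
sel <- run$probe$times >= inst$PF & run$probe$times <= inst$MD
round(colMeans(run$probe$values[sel, ]))       # mean probe pressure, Pa
#>     A     B     C     D
#> 14737 14670 14670 14179
pressure_buildup_detect(run$probe, inst)$buildup
#> [1] TRUE
round(focality_score(run$band, c(inst$QA3, inst$MD)), 2)
#> [1] 0.72
```

Probe A (centre of the impingement zone) carries the highest mean pressure
over `[PF, MD]`; the band WSS concentrates on the outer-curvature side
(focality 0.72 of a possible 1). Re-running with
`idealized_aorta_spec(brachio_offset = proximal_brachio_offset())` moves
the brachiocephalic inlet onto the impingement point and disperses the
pattern. The restored (post-valve-replacement) model is one call:

```r
restored_inflow(2.7, area_factor = 3)   # tripled jet area, same flow rate
#> $U_peak 0.9      $r_jet 0.0119
```

A thin command-line interface wraps the same functions
(`inst/cli/aortaflow.R`: `geometry`, `calibrate-wkm`, `simulate`,
`postprocess`, `fixtures`, `report`).

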