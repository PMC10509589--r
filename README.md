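# haemopost

Post-processing toolkit for time-resolved cardiovascular flow fields on
tetrahedral meshes, oriented at **type-B aortic dissection** (TBAD) — the
condition in which an intimal tear splits the descending aorta into a true
lumen (TL) and a false lumen (FL). Whether and how fast the false lumen
grows correlates with haemodynamic quantities that are not directly
measurable at clinical resolution, so they are computed from simulated or
imaged velocity fields. `haemopost` implements that analysis chain for
researchers running patient-specific CFD or working with 4D-flow MRI
(4DMR) data:

- **Inlet velocity profiles (IVPs).** Registration of per-timeframe inlet
  contours and voxel velocities onto a fixed inlet patch, and construction
  of the four standard IVP variants from one reference: the full
  three-component (4D) profile, the flat profile (uniform plane-normal
  velocity at the same flow waveform), the through-plane (TP) profile
  (normal component only), and a velocity-scaled profile (+25%, emulating
  the known underestimation of velocity by 4DMR). Flow-rate matching across
  4D/flat/TP holds to 1e-10 by construction.
- **Outlet boundary calibration.** Aortic pressure targets from a brachial
  cuff measurement (`Ps = 0.83 Ps' + 0.15 Pd'`, `Pd = Pd'`), branch-flow
  normalisation to aortic plane differences, and tuning of three-element
  Windkessel (WK3) parameters against a 0D lumped network of parallel
  outlets (`R_tot = MAP / Qbar` split by a per-outlet fraction rho, global
  capacitance scale tuned on pulse pressure until systolic and diastolic
  pressures land within 1% of target).
- **Wall shear stress indices.** TAWSS, OSI, RRT, ECAP per wall node, with
  circumferential station profiles and pointwise between-case difference
  statistics:

  TAWSS = (1/T) ∫ |τ| dt,  OSI = ½ (1 − |∫ τ dt| / ∫ |τ| dt),
  RRT = [(1 − 2 OSI) · TAWSS]⁻¹,  ECAP = OSI / TAWSS.

- **Helicity.** Helicity density H_k = v · ω, regional time series H(t) and
  |H|(t), local normalized helicity (LNH ∈ [−1, 1]), and the bulk indices
  h1–h3 by aortic subdomain (AA, TLt, FLt, TLa, FLa) and cycle phase.
- **Reduced-order analysis.** Snapshot proper orthogonal decomposition
  under a volume-weighted inner product, normalized modal energy spectra,
  truncated reconstruction obeying the Parseval tail identity, and WSS
  indices recomputed from truncated wall-shear reconstructions.
- **Clinical correlates.** Transmural pressure (TMP = P_TL − P_FL per
  station), false-lumen ejection fraction (FLEF, net retrograde tear-flow
  volume per cycle over stroke volume), luminal growth profiles at 5 mm
  stations, and plane-wise Pearson correlation of velocity magnitude
  between cases.

Everything is testable without patient data: the package ships analytic
generators (Womersley pulsatile pipe flow with closed-form flow and
wall-shear waveforms, helical cylinder flow with uniform helicity density,
an MRI-like inlet sampler with seeded noise and contour motion, and a
two-lumen dissection phantom with prescribed TMP/FLEF) whose ground truth
anchors the whole test suite.

## Worked example

```r
library(haemopost)

## pressure targets from a brachial cuff measurement of 138/81 mmHg
targets <- derive_pressure_targets(c(138, 81), round_targets = TRUE)
cat(sprintf("Ps %d, Pd %d, pulse %d mmHg\n",
            targets$ps, targets$pd, targets$ps - targets$pd))
#> Ps 127, Pd 81, pulse 46 mmHg

## analytic pulsatile tube flow (94 bpm, steady + first harmonic)
spec <- womersley_spec()
wom  <- womersley_field(spec, n_snapshots = 16)
cat(sprintf("Womersley number alpha = %.1f\n", wom$alpha))
#> Womersley number alpha = 17.2

## wall shear indices from the velocity field
tau <- wall_shear_from_field(wom$field)
ix  <- compute_wss_indices(tau)
summary(ix$tawss)   # Pa; ~0.509 on every wall node (axisymmetric flow)
summary(ix$osi)     # 0.239: partially oscillatory shear

## tune Windkessel outlets to the pressure targets
q_wave <- data.frame(time_s = wom$field$grid$times,
                     q_mls  = wom$flow(wom$field$grid$times))
qt <- c(arch = 0.25, abdominal = 0.55, iliac = 0.20) * mean(q_wave$q_mls)
wk <- tune_wk3(q_wave, targets, qt, rho = c(0.03, 0.056, 0.056),
               period = spec$period)
round(wk$achieved, 1)
#>  ps  pd
#> 127  81
```

The achieved systolic/diastolic pair lands on the targets within the 1%
tuning tolerance; `wk$params` holds the per-outlet `R1`, `R2`, `C` in
clinical units (mmHg·s/ml, ml/mmHg).

`run_experiment(default_config(seed = 1))` chains the whole pipeline —
synthetic inlet frames, registration, the four IVP variants, WK3 tuning
(re-tuned for the scaled case), and the per-case WSS/helicity/POD metric
tables — into a dated run directory with CSV reports and a provenance log.
A thin CLI wrapper is installed under `inst/scripts/haemopost`.

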