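---
title: "Methods: haemodynamic post-processing for aortic dissection flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haemodynamic post-processing for aortic dissection flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haemopost)
```

## Scope and model

`haemopost` post-processes time-resolved velocity fields of dissected aortic
flow. In type-B aortic dissection an intimal tear splits the descending aorta
into a true lumen (TL) and false lumen (FL) connected through a primary entry
tear (PET) and re-entry tears. The package covers the analysis chain that
surrounds a 3D CFD solver without including the solver itself:

1. construction of inlet velocity profiles (IVPs) from 4D-flow-MRI-style
   inlet frames — the full three-component (4D) profile and its flat,
   through-plane (TP) and velocity-scaled (+25%) variants, all derived from
   the one reference so their flow waveforms match;
2. derivation of aortic pressure targets from a brachial cuff measurement and
   calibration of three-element Windkessel (WK3) outlet parameters with a 0D
   lumped network;
3. wall shear stress indices (TAWSS, OSI, RRT, ECAP), helicity metrics
   (helicity and helicity-magnitude time series, local normalized helicity,
   bulk indices $h_1$–$h_3$ by subdomain and cycle phase), snapshot proper
   orthogonal decomposition (POD) with truncated reconstruction, and clinical
   correlates (transmural pressure, false-lumen ejection fraction, luminal
   growth profiles, plane-wise Pearson correlation between cases).

Because no patient fields ship with the package, every stage is validated
against synthetic analytic flows with closed-form ground truth (below).

## Conventions

All internal quantities are SI (m, s, Pa, m$^3$/s); mmHg and ml/s appear only
at interfaces, converted by the exact factor 133.322 Pa/mmHg. Node and cell
indices are 1-based, the natural convention in R. Fields are node-centred on
tetrahedral meshes; cycle-periodic series store one cycle $[0, T)$ of $N$
uniformly spaced snapshots under the convention $x(T) = x(0)$, so every
snapshot carries the equal quadrature weight $T/N$ in cyclic time integrals
(a trapezoidal rule with periodic closure). This makes time averages exact
means over snapshots and renders all indices invariant under cyclic shifts of
the snapshot ordering — a property the test suite asserts.

Analysis planes carry their own triangulated quadrature (points and areal
weights generated once from a disk), rather than intersecting the volume
mesh; the stored plane area is the sum of the weights, so uniform-flow fluxes
are exact by construction. Quadrature points falling outside a faceted wall
contribute zero — admissible because velocity vanishes at no-slip walls.

## Wall shear stress extraction and indices

The solver-independent wall shear is computed from the velocity field itself:
the velocity gradient is evaluated per wall-adjacent tetrahedron by linear
(P1) shape functions, volume-averaged to wall nodes, and the tangential part
of the viscous traction $\mu (\nabla v + \nabla v^\top)\,\hat n$ is retained.
Blood defaults to Newtonian ($\mu = 3.5$ mPa s, $\rho = 1056$ kg/m$^3$); a
Carreau–Yasuda model may be supplied by its coefficients, in which case
viscosity is evaluated at the local shear rate. The coefficients are
user-supplied because no canonical value set ships with the package.

The indices are
$$\mathrm{TAWSS} = \frac{1}{T}\int_t^{t+T} |\tau|\,dt, \qquad
\mathrm{OSI} = \frac12\left(1 -
  \frac{\left|\frac{1}{T}\int \tau\,dt\right|}{\frac{1}{T}\int |\tau|\,dt}\right),$$
$$\mathrm{RRT} = \big[(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}\big]^{-1}
  = \left|\tfrac{1}{T}\int \tau\,dt\right|^{-1}, \qquad
\mathrm{ECAP} = \mathrm{OSI} / \mathrm{TAWSS}.$$
RRT is implemented as the inverse of the mean-shear magnitude — the standard
definition, consistent with OSI/ECAP usage; purely oscillatory nodes
(zero mean vector) have infinite RRT and are reported as such, while nodes
with identically zero shear are flagged undefined rather than zero. Pointwise
case differences report the mean percentage difference two ways — mean of
pointwise ratios (default) and ratio of means — because the averaging rule
for such tables is not standardised; nodes whose baseline index falls below
$\max(10^{-12}, 10^{-6}\times$ region maximum$)$ are excluded from the ratio
statistic.

## Helicity metrics

Helicity density $H_k = v \cdot \omega$ is evaluated cell-centred (nodal-mean
velocity against the P1 cell curl, exact for linear fields) and integrated
with cell volumes; $|H|(t)$ integrates $|H_k|$ to distinguish symmetric
counter-rotation from absent swirl. LNH $= H_k / (|v||\omega|)$ is clamped to
$[-1, 1]$ and set to zero where $|v||\omega| < 10^{-12}$ (SI) to avoid
spurious $\pm 1$ in stagnant regions. The bulk indices $h_1$ (signed
time-volume average), $h_2$ (unsigned) and $h_3 = h_1/h_2$ are computed per
subdomain (AA, TL$_t$, FL$_t$, TL$_a$, FL$_a$) and per cycle window. Systole
and diastole boundaries are explicit configuration values; the default end of
systole is the first down-crossing of the inlet flow through 5% of its peak
after peak systole, falling back to $0.35\,T$ — a decision the package makes
explicitly because no universal definition of the split exists.

## Snapshot POD

Snapshots are mean-subtracted and the temporal Gram matrix formed under a
weighted inner product — cell-volume (or lumped wall-area) weights by
default, so modal energy is mesh-independent; uniform weighting is available.
Eigen-decomposition of the Gram matrix gives eigenvalues sorted
non-increasing, orthonormal modes, and temporal coefficients; the sign of
each mode is fixed by making its largest-magnitude component positive,
resolving the inherent eigenvector sign ambiguity deterministically.
Truncation error obeys the eigenvalue tail sum (Parseval), asserted to
$10^{-8}$ in the tests. Wall-shear reconstruction applies POD to the
wall-shear vector snapshots directly rather than to reconstructed velocity
gradients: the problem is well-posed on the wall surface and keeps the
reconstruction error budget interpretable per index.

## Inlet profile construction

Registration of each inlet frame onto the fixed inlet maps the frame contour
by a similarity transform (centroid translation, mean-radius scale, in-plane
rotation chosen by circular matching of the polar radius functions, with ties
resolved to the smallest rotation) followed by a regularised non-rigid radial
refinement: the angular scale profile is Fourier-damped by
$1/(1 + \text{rigidity}\,k^2)$, so a large rigidity weight suppresses
distortion of the velocity pattern while still closing the contour gap; the
refinement is radial and positive, hence fold-over free, which the tests
verify by checking triangle orientations. In-plane velocity components rotate
with the alignment. A registration residual above 20% of the inlet radius
aborts with diagnostics.

The reference (4D) profile interpolates each mapped frame onto a uniform
intermediate grid (spacing 1/40 of the inlet diameter) by quadratic moving
least squares, then performs temporal spline interpolation periodically — the
frame cycle is tiled three times and the central cycle extracted — and
finally interpolates to the inlet nodes, zeroing perimeter nodes to honour
no-slip. The flat variant is deliberately uniform up to and including the
boundary (discontinuous at the wall), carrying $Q_{in}(t)/A$ in the normal
direction; the TP variant keeps the normal component pointwise; the scaled
variant multiplies all components. Flux equality of 4D/flat/TP and exact
stroke-volume scaling of the +25% variant are construction properties and are
asserted to $10^{-10}$ relative.

## 0D Windkessel network and tuning

Outlets are WK3 elements in parallel on a single zero-resistance junction
with imposed inlet flow — the simplest closure reproducing the calibration
targets, adopted because the reference network topology is not published.
The distal reference pressure is 0 mmHg, consistent with total resistances of
magnitude MAP$/\bar Q$. Integration is implicit first-order at 1 ms (the
junction closure is solved exactly each step), so the scheme is stiff-safe
and discretely mass-conserving; periodicity is declared when systolic and
diastolic junction pressures change by less than 1% between cycles.

Tuning sets $R_{tot,i} = \mathrm{MAP}/\bar Q_i$ with
$\mathrm{MAP} = P_d + (P_s - P_d)/3$, splits it by the per-outlet fraction
$\rho = R_1/R_{tot}$, and finds a single global capacitance scale by
bracketed root finding on the simulated pulse pressure; an outer global
resistance correction shifts the mean until both $P_s$ and $P_d$ land within
1% of target. The published tuning procedure this stands in for is not
recoverable from its description, so the acceptance surface is the achieved
pressure pair, not specific parameter values; the +25% case is re-tuned with
1.25-scaled flow targets and unchanged pressure targets, reproducing the
reported behaviour (parameters change, pressures do not).

## Synthetic data and what the tests show

The generators define the study conditions and return their own ground truth:

- **Womersley pipe flow** — per-harmonic Bessel-function velocity profiles
  with closed-form flow and wall-shear waveforms. The complex $J_0$, $J_1$
  are evaluated by power series (accurate far beyond the physiological
  Womersley range; a warning fires above $\alpha = 50$). Defaults: radius
  10 mm, period $60/94$ s (a 94 bpm heart rate), blood density/viscosity as
  above, a steady plus first-harmonic waveform.
- **MRI-like inlet sampling** — 16 timeframes on a coarse voxel grid
  (mirroring a 2.25 mm in-plane acquisition scaled to the phantom), a
  sinusoidally translating and dilating contour, and additive Gaussian noise
  per component from a single caller seed. Rician noise and acquisition
  physics are deliberately out of scope.
- **Helical cylinder flow** — $v = \Omega r \hat\theta + W \hat z$ with
  exactly uniform helicity density $2\Omega W$; the analytic oracle for all
  helicity metrics.
- **Two-lumen phantom** — two duct lumens with subdomain labels, prescribed
  TL/FL plane pressures (offset 2 mmHg), and a tear waveform with prescribed
  retrograde volume (1.5 ml against a 70 ml stroke volume, i.e.
  FLEF $= 2.142\%$), sampled at 128 points per cycle (≈5 ms cadence).

Passing tests demonstrate correctness of the numerics on smooth analytic
fields at desk scale — they do not certify accuracy on patient-specific
geometries with turbulence, imaging noise of realistic structure, or
segmentation uncertainty, none of which the generators emulate. Mesh sizes
used in the tests (a few thousand cells, 8–32 snapshots) are chosen as the
smallest on which the discretisation errors of each oracle comparison are
comfortably inside the asserted tolerances: wall-node shear extraction is
first-order in the near-wall spacing (the default cylinder grading ends at
1.5% of the radius), and oracle flux comparisons use a circumferential
resolution at which polygonal-area deficit is below 0.3%.

## Numerical decisions and limitations

- Degenerate inputs error early with typed conditions (non-tetra cells,
  single-snapshot grids, empty regions, zero-length windows, planes outside
  the mesh, unpaired stations).
- Rank-deficient POD inputs flag trailing zero modes instead of erroring.
- The brachial transfer formula accepts $P_s' = P_d'$ as a degenerate input
  (with a warning) and errors only when a strictly ordered input inverts
  after the transform.
- The pipeline (`run_experiment()`) derives every case from one reference
  profile and re-tunes the Windkessel set only for the scaled case. With
  synthetic data and no 3D solver, the flow-rate-matched cases share the
  metric field; their difference tables are exact zeros and serve as
  plumbing verification, not as physiological results.
- Patient-specific results (pressure tables, helicity tables, modal energy
  percentages of aortic CFD fields) are properties of fields this package
  does not ship; the package reports the same statistics for any input but
  makes no attempt to reproduce those numbers.
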