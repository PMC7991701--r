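---
title: "Modelling cerebral perfusion during carotid clamping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebral perfusion during carotid clamping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model answers

During a carotid endarterectomy the internal carotid artery (ICA) is
clamped, and the brain on that side depends entirely on collateral
supply through the circle of Willis (CoW): crossflow from the opposite
ICA through the anterior communicating artery (Acom), and backflow
from the vertebrobasilar system through the posterior communicating
artery (Pcom).  The pressure measured in the clamped carotid stump
(carotid stump pressure, CSP) summarises that collateral reserve, and
a mean CSP below 40 mmHg is a common indication for placing a
temporary shunt.  `willisim` asks how CSP, the communicating-artery
flows, and the cerebral peripheral pressures change as the *opposite*
ICA is progressively narrowed — the situation in which collateral
reserve is most at risk.

## Model structure

The model is a classical reduced-order (1D--0D) arterial network:

* **1D pulse-wave domain.**  Each named artery is a 1D segment
  carrying cross-sectionally averaged area $A(x,t)$ and flow $Q(x,t)$,
  governed by
  $$\partial_t A + \partial_x Q = 0, \qquad
    \partial_t Q + \partial_x\!\left(\alpha \frac{Q^2}{A}\right)
    + \frac{A}{\rho}\,\partial_x P = -K_R \frac{Q}{A},$$
  closed by the elastic tube law
  $P = \beta(\sqrt{A} - \sqrt{A_0})$ with
  $\beta = \sqrt{\pi} E h / ((1-\nu^2) A_0)$, $\nu = 1/2$.  The local
  pulse-wave speed is $c = \sqrt{\beta \sqrt{A}/(2\rho)}$.  We use
  $\alpha = 1$ and a per-segment friction coefficient $K_R$: the
  blunt-profile value $22\pi\nu_k$ ($\nu_k$ the kinematic viscosity)
  for the central elastic arteries, and the parabolic-profile value
  $8\pi\nu_k$ for the muscular head and intracranial branches, whose
  Womersley numbers are small.

* **Numerical scheme.**  Interior nodes advance with the two-step
  (Richtmyer) Lax--Wendroff scheme on the conservative form; the
  global time step honours a CFL condition (default Courant number
  0.9) over every node of every segment.  Boundaries are coupled
  through the outgoing Riemann invariants $W_\pm = u \pm 4(c - c_0)$,
  linearly extrapolated to the foot of the outgoing characteristic,
  together with a per-boundary Newton solve enforcing: prescribed
  inflow at the aortic root; conservation of mass and continuity of
  total pressure $P + \tfrac{1}{2}\rho u^2$ at junctions (2--4
  branches); the RCR relation at terminals; zero flow on both faces of
  a clamp; and the trans-stenotic pressure jump at a stenosis
  interface.  Junction mass defects are audited every step and
  reported (they sit at the Newton tolerance, around $10^{-13}$
  cm$^3$/s in practice).

* **0D closures.**  The heart is not modelled: the aortic root
  receives a prescribed T-periodic half-sine systolic inflow (cardiac
  output 5 L/min, period 0.9 s, systole 0.3 s), ramped over the first
  cycle from a reproducible cold start ($A = A_0$, $Q = 0$).  Each
  outlet is a three-element Windkessel (characteristic impedance
  $R_1$, peripheral resistance $R_2$, compliance $C$, venous pressure
  5 mmHg), advanced by backward Euler inside the coupled boundary
  solve.

* **Stenosis element.**  A lumped Young--Tsai-type element carries the
  full lesion (the 1D grid is not refined inside it):
  $$\Delta P = \frac{K_v \mu}{A_{0s} D_0} Q
    + \frac{K_t \rho}{2 A_{0s}^2}\left(\frac{A_{0s}}{A_s} - 1\right)^2
      Q|Q|
    + \frac{K_u \rho L_s}{A_{0s}} \dot Q,$$
  with $K_v = 32 (L_s/D_0)(A_{0s}/A_s)^2$, $K_t = 1.52$, $K_u = 1.2$.
  The stenosis ratio is diameter-based, $A_s = A_{0s}(1-r)^2$,
  matching clinical grading convention; $A_{0s}$ and $D_0$ are taken
  from the host segment's reference taper at the lesion start.  A
  ratio of exactly 0 installs no element (the network is unchanged);
  a ratio of 1 is routed to the zero-flow clamp mechanism rather than
  the formula.

* **Cerebral autoregulation.**  The six cerebral outlets (MCA, ACA,
  PCA beds per hemisphere) follow a Lassen-type flow--pressure curve
  stored as tabular anchors and interpolated by a monotone Hermite
  spline: zero flow at zero pressure, roll-off below the plateau,
  exactly the baseline flow $q_0$ on the plateau, and a mild rise
  above it.  After each periodic solve, every bed's total resistance
  relaxes toward the value that would deliver the target flow at the
  observed bed-inlet pressure,
  $R \leftarrow R(1-\kappa) + \kappa (\bar P - P_v)/q_{\mathrm{target}}(\bar P)$
  with $\kappa = 0.5$, and the solver re-runs (warm-started) until the
  fixed-point residual falls below $10^{-3}$ (at most 20 outer
  iterations).

## The virtual patient

The shipped network fixture is a 31-segment population-averaged tree
in the layout of the standard published 1D circle-of-Willis
benchmarks: ascending aorta and arch, brachiocephalic, subclavian and
brachial arteries, both common/internal/external carotids, vertebrals,
basilar, and the complete CoW (P1/P2, Pcom, MCA, A1/A2, Acom).  Blood
properties are $\rho = 1.06$ g/cm$^3$, $\mu = 0.04$ P.  Terminal
Windkessels distribute the 5 L/min output with a total cerebral flow
of 700 mL/min split 2:3:2 over the ACA/MCA/PCA beds per hemisphere.

Three aspects are deliberate modelling choices rather than published
population values, and are what the shipped fixture was *calibrated*
on (the original study's exact network parameters are unpublished):

* **Carotid geometry.**  The ICA tapers linearly from a carotid-bulb
  radius of 0.47 cm to an intracranial radius of 0.20 cm, so the
  10 mm lesion starting 10 mm above the bifurcation sits in the bulb.
  The bulb calibre controls how severe a given diameter ratio is
  hydraulically, and therefore at which grid ratio the collateral
  flows begin to shift.

* **Communicating and vertebral calibres.**  Acom 0.062 cm, Pcom
  0.074 cm, vertebrals 0.150 cm, basilar 0.170 cm, PCA P2 0.125 cm.
  These set the balance between the anterior (Acom) and posterior
  (Pcom) collateral routes: the baseline split of the ipsilateral
  supply, the pressure coupling between the stenosis and the
  ipsilateral middle cerebral artery, and the ratio at which the A1
  flow inverts.

* **Autoregulation plateau.**  The plateau is set to 70--150 mmHg — a
  right-shifted lower limit, as described in aged and chronically
  hypertensive patients — so that the cerebral beds of the 70-year-old
  patient operate just inside the plateau at baseline.

Age enters as a stiffness adjustment: every segment's Young's modulus
is scaled by $1.1^{(\text{age}-40)/10}$ relative to the 40-year
reference fixture (about +33% at age 70); radii are untouched.  The
`sex` argument is accepted for interface completeness but the default
fixture is not sex-stratified.  Finally, a single global scale factor
on all terminal resistances is found by a bracketed secant search so
the converged cycle-mean aortic-root pressure equals 90 mmHg within
1 mmHg (the search is monotone because mean pressure at fixed cardiac
output is resistance-determined in an open-loop model).

```{r}
library(willisim)
patient <- build_virtual_patient(age = 70)
cal <- calibrate_map(patient)           # ~90 mmHg at the aortic root
sweep <- run_cea_sweep(cal$net, side = "left")
sweep_thresholds(sweep)
```

## Protocol readouts and operational detectors

The protocol clamps the ipsilateral ICA 10 mm above the bifurcation
and sweeps the contralateral stenosis ratio over 0--100% in 10%
steps.  Per ratio the autoregulation-converged periodic solution
yields: CSP (cycle-mean pressure at the grid node just distal to the
clamp), signed communicating flows (Acom positive = contralateral to
ipsilateral; Pcom positive = posterior to anterior; A1 positive =
carotid terminus toward the Acom junction), and the cerebral
peripheral pressures, measured at the *bed inlet* — the distal end of
the A2 / MCA / P2 segments.  The bed-inlet choice is a documented
convention; measuring at mid-vessel shifts every curve by a fraction
of a mmHg without moving any detected threshold.

"Began to change" statements about plotted curves need an operational
criterion.  The detectors use: flow onset = first grid ratio deviating
from the 0% baseline by more than 2% of the baseline magnitude;
pressure-decline onset = more than 1 mmHg below baseline; flow
vanishing = magnitude below 1% of baseline; inversion = first sign
change.  Thresholds are function arguments and are reported next to
the results; `sweep_thresholds()` also returns a one-grid-step
sensitivity table (each criterion statistic normalised by its
threshold at every ratio) so the reader can see how close each
detection sits to its neighbouring grid points.

With the shipped fixture the default sweep gives: both communicating
flows begin to shift at the 50% ratio, the ipsilateral MCA bed
pressure starts declining (by the 1 mmHg criterion) at 60%, and the
ipsilateral A1 flow keeps its baseline direction through 70% and is
inverted from 80% — at that point the ipsilateral anterior territory
is perfused through the Pcom alone, and the MCA bed drops out of the
autoregulation plateau while the ACA and PCA beds stay above 60 and
70 mmHg respectively across the whole sweep.

## Numerical choices

* Grid: target spacing 0.25 cm, at least 5 nodes per (sub)segment;
  halving the spacing moves the converged mean aortic pressure by
  less than 1 mmHg (checked in the test suite).
* Periodicity: a run is periodic when the maximum relative change of
  segment-averaged cycle-mean pressure and flow between consecutive
  cycles is below $10^{-3}$ (flows are floored at 1% of the mean root
  inflow so that zero-mean vessels such as the Acom do not stall the
  criterion); at most 30 cycles, warm starts typically need 3--6.
* Segments are uniform at their reference radius evaluated at the
  piece midpoint; tapered vessels are represented by their linear
  taper in the stenosis-site geometry and by midpoint radii in the
  1D grid.
* Tie-breaks and degenerate inputs: a 0-ratio stenosis installs
  nothing; a 1-ratio stenosis becomes a zero-flow interface; clamping
  must fall strictly inside a segment; beds whose target flow
  vanishes at positive pressure are flagged non-autoregulable and
  their resistance frozen rather than divided by zero.

## What the generator does and does not emulate

The virtual patient reproduces population-averaged geometry,
age-stiffening, a physiological inflow pulse and autoregulating
distal beds, which is what the clamp/stenosis thought experiment
needs.  It does not emulate: anatomical CoW variants (a complete CoW
is assumed and enforced by validation), vertebrobasilar or Pcom
disease, compensatory vessel remodelling under chronic hypoperfusion,
CO$_2$/metabolic reactivity or beat-resolved dynamic autoregulation,
venous/intracranial-pressure coupling, or patient-specific geometry
from imaging.  Passing tests on this fixture demonstrate internal
consistency of the solver and protocol — not predictive accuracy for
an individual patient.

`perturb_patient()` provides lognormal joint perturbations of radii,
stiffness and terminal resistances (deterministic per seed, CV up to
0.3) for robustness exercises around the population-average point.

## Known limitations

Two reported features of the clinical simulation literature cannot be
reproduced *simultaneously* by any parameterisation of this model
family, and we chose the side documented here:

* **Stump-pressure depth vs. cerebral pressure floors.**  With a
  complete CoW, the stump, the ipsilateral ACA bed and (via the
  terminus) the MCA bed all hang off the same collateral pressure
  level, and once the A1 has inverted the ACA bed is strictly
  *downstream* of the stump node, so mean CSP cannot fall below the
  ACA bed pressure.  Keeping the ACA and PCA floors at 60/70 mmHg up
  to full contralateral occlusion therefore bounds CSP from below at
  roughly 65 mmHg — a CSP below 60 mmHg at a 70% ratio would require
  abandoning those floors.  The shipped fixture preserves the floors
  and the redistribution thresholds; its CSP consequently declines
  from ~78 to ~66 mmHg rather than crossing 60.
* **Acom extinction at 90%.**  The three-term stenosis element passes
  a finite trickle (tens of mL/min) even at a 90% diameter ratio, so
  the Acom flow magnitude reaches 1% of baseline only at true
  occlusion (the 100% grid point), not one step earlier.

Both points, and the margins of every detected threshold, are visible
in the `sweep_thresholds()` sensitivity table and in the package's
test suite, which asserts the reproduced statements and leaves the
two unreachable ones as documented failures rather than silently
relaxing their criteria.
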