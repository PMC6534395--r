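---
title: "Measuring single-cell growth through mitosis with an SMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell growth through mitosis with an SMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrgrowth)
```

## The measurement

A suspended microchannel resonator (SMR) is a cantilever with a fluid
channel buried inside it, driven at its second flexural bending mode
(baseline ~1.1 MHz). A cell flowing through the channel shifts the resonant
frequency by an amount proportional to its buoyant mass — cell mass minus
the mass of displaced medium, a proxy for dry mass — weighted by the squared
mode displacement at the cell's position. In the second mode the channel
path crosses the interior displacement antinode twice per transit with the
displacement node between, so each transit appears as two frequency minima
separated by a near-baseline node region. Averaging the two refined minima
and scaling by a polystyrene-bead calibration gives one mass point; cycling
a cell back and forth yields a point every ~1 min at sub-0.1 pg precision.

The package converts raw `(time, frequency)` records to mass points
(`detect_transits()` → `refine_minimum()` → `calibrate()` →
`transits_to_masses()`), assembles per-cell traces, annotates cell-cycle
events, corrects the cytokinetic elongation bias, and estimates growth
rates and population summaries.

## Beam model and the elongation bias

The second mode of a clamped-free Euler–Bernoulli beam,

$$u(\xi) \propto \cosh\lambda_2\xi - \cos\lambda_2\xi -
  \sigma_2(\sinh\lambda_2\xi - \sin\lambda_2\xi), \qquad
  \lambda_2 = 4.69409113,$$

has its interior node at $\xi_0 \approx 0.782$ and interior antinode at
$\xi_a \approx 0.470$. A point mass at the measurement antinode defines the
calibration; a cell of finite axial extent $\ell$ instead samples
$u^2$ over its axial mass distribution $\hat\lambda(s)$, giving an apparent
mass reduced by

$$\kappa = \max_{\xi_c} \int \hat\lambda(s)\,
  u\!\left(\xi_c + s/L\right)^2 ds \;\Big/\; u(\xi_a)^2 \;\le\; 1 ,$$

maximised over the centroid position because the instrument reports the
extremal shift of a transit. During cytokinesis the cell is modelled as a
sphere (before elongation), two overlapping equal spheres (anaphase,
centre separation ramping linearly over $\tau_e$ = 12 min for L1210), and a
touching doublet afterwards, with the sub-sphere radius solving union-volume
conservation at every separation. Because the bead calibration already
absorbs the finite-size bias of a round cell, the applied correction is the
*relative* factor $\kappa_{rel}(t) = \kappa(t)/\kappa_{sphere}$, exactly 1
before elongation — which also makes the corrected trace continuous at the
metaphase–anaphase (M/A) transition. For a typical L1210-sized cell
(R ≈ 6 µm on a 350 µm cantilever) the doublet bias is a few tenths of a
percent to a few percent depending on geometry — a small correction, which
is why applying it changes cytokinesis masses only slightly.

Two modelling choices are worth stating explicitly. First, the channel
U-turn is placed at the displacement node: this is the simplest geometry
that produces the observed transit morphology (two equal minima with the
node region between), and it makes the raw-peak generator and the bias
model use the same measurement antinode, so forward bias injection and
correction are exact inverses. Second, the mass-to-radius conversion uses a
configured density contrast (default 75 kg/m³) — an instrument/medium
setting, not measured biology.

## Cell-cycle events

Three events bound the stages of interest:

- **Abscission** — an ~50% loss of buoyant mass between two points at most
  2 min apart (the discarded daughter is flushed away). The accepted loss
  band defaults to [0.35, 0.65]: wide enough for division asymmetry, far
  above the few-percent anaphase dip. A 30-min refractory interval guards
  against double counting.
- **M/A transition** — primary: the FUCCI mAG-hGeminin reporter is degraded
  at M/A; the detector finds the first sustained drop below half the rolling
  pre-mitotic plateau. With first-order degradation (half-life ~10 min) that
  crossing lags the biological transition by
  $t_{1/2}\log_2(1/f_{drop})$, so `annotate_cycle()` subtracts the
  configured lag. Fallback: the biophysical signature — a sharp node-
  deviation drop coincident with a momentary dip in the uncorrected mass
  trace. Growth decays to zero approaching M/A and the elongation bias pulls
  the measured mass down immediately after it, so the dip onset is located
  as the local maximum of the lightly smoothed mass near the node drop,
  refined by a quadratic vertex fit; a genuine dip must decline by at least
  3 noise SDs afterwards.
- **G2/M (mitotic entry)** — assigned as a fixed offset before M/A (30 min
  for L1210), the standard assignment for this cell type; the node-deviation
  changepoint (two-piece linear fit minimising SSE) is available as an
  independent check and for cell types where the offset is unknown. For
  perturbations that prolong early mitosis the offset must come from the
  experiment, not the default.

M-phase is `[t_g2m, t_abscission]`, early mitosis `[t_g2m, t_ma]`,
cytokinesis `[t_ma, t_abscission]`, and the anaphase (elongation) window is
`(t_ma, t_ma + tau_e)`.

## Growth-rate estimation

MAR is the ordinary least-squares slope of mass against time — unweighted,
since nothing in the measurement model favours weighting. Stage fits add
linearly interpolated points at the exact stage boundaries so stages are not
quantised to the sampling grid. Sliding windows default to 10 min every
5 min (a 4/2 high-resolution variant is available); MAR/mass divides each
window's slope by its mean mass, giving a size-normalised specific growth
rate that is constant for exponential growth (the window estimate deviates
from the true rate only at second order in the rate-window product, <0.5%
for 0.08/hr and 10-min windows).

The per-cell "peak comparison" contrasts the maximum windowed MAR/mass in
late G2 (the 30 min before mitotic entry) with the maximum in early mitosis
(entry to M/A). Two details matter for an unbiased estimate, both verified
by design-stage simulation: windows are assigned to a segment only when
fully contained in it (a window straddling mitotic entry would leak burst
growth into the G2 maximum), and the two segments have equal length so the
maxima carry the same noise-driven inflation. With a 90-min G2 segment the
G2 maximum is taken over ~3× more windows and the estimated increase is
biased several points low; the symmetric 30-min segment also matches the
definition of the late-G2 stage used everywhere else.

## Population summaries

Per cell, the total cycle accumulation is defined as half the abscission
mass (birth is taken as exactly half of abscission), and the mass gained in
early mitosis and cytokinesis is expressed relative to it; only
pre-abscission points enter, so the halved daughter point cannot
contaminate the event masses. For ensemble dynamics, each cell's MAR/mass
series is aligned at M/A (or at mitotic entry for arrest experiments, after
a per-cell moving average of length 3), linearly interpolated onto a common
100-point grid over a configurable span (default −90 to +60 min, covering
late G2 through late cytokinesis), and averaged pointwise with SD and SEM
both reported. Hypothesis tests wrap the standard implementations
(`t.test`, `aov`/`TukeyHSD`); the test suite checks them against explicit
sum-of-squares arithmetic.

## The synthetic-data generator

The simulator is first-class, tested code: it is the package's ground-truth
oracle, and every detector and estimator is validated against it. One
piecewise-linear specific-growth-rate profile $\alpha(t)$ drives each cycle:

| parameter | default | meaning |
|---|---|---|
| `interdivision_hr` | 9 (CV 5%) | cycle length |
| `sampling_min` | 1 | measurement cadence |
| `noise_sd_pg` | 0.05 | additive mass noise (sub-0.1 pg instrument) |
| `birth_mass_pg` | 35 (CV 10%) | L1210-like scale (~70 pg at abscission) |
| `alpha_interphase` | 0.08/hr | exponential interphase MAR/mass |
| `prophase_multiplier` | 1.16 | burst after mitotic entry |
| `prophase_duration_min` | 20 | burst length; decay to zero fills the rest |
| `g2m_offset_min` | 30 | entry precedes M/A |
| `tau_e_min` | 12 | elongation, MAR exactly 0 |
| `recovery_min` | 40 | linear MAR recovery after elongation |
| `cytokinesis_min` | 50 | M/A to abscission |
| `division_asymmetry_sd` | 0.02 | Gaussian asymmetry of the halving |

The burst length, decay span and recovery are free parameters (the
underlying biology constrains only the ~30-min entry-to-M/A span and the
12-min elongation); the defaults were fixed once so that the analytically
integrated profile puts ~7.4% of cycle growth in early mitosis and ~4.8% in
cytokinesis (~12.2% in M-phase) and lets recovery continue through
abscission into the newborn daughter. `true_fractions()` integrates the
profile in closed form and is the oracle for parameter-recovery tests. The
birth-mass default follows from the instrument's own precision statement
(<0.1 pg being <0.07% of a lymphocyte's mass implies ~58 pg mid-cycle).

Auxiliary channels emulate the detectors' inputs: node deviation (plateau,
linear decline from entry, sharp drop at M/A, recovery after abscission) and
FUCCI (accumulation through S/G2, exponential degradation from M/A,
half-life 10 min), both with Gaussian noise. The forward elongation bias
multiplies true masses by $\kappa_{rel}(t)$ using the same radius rule as
the correction, so inject-then-correct is exact to numerical precision.
Scenarios: `control`, `prometaphase_arrest` (MAR decays to zero over
~2.5 hr, no M/A or division), `cytokinesis_block` (recovery amplitude
scaled).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: trap loss and gaps, baseline drift and
1/f frequency noise, mass-dependent noise, biological heterogeneity of the
burst and of stage durations beyond simple Gaussians, the acoustic physics
behind node deviation (only its changepoint phenomenology is reproduced),
and deviations of real cells from coaxial sphere-union geometry.

## Numerical choices

- Quartic peak refinement uses a centred/scaled least-squares fit and the
  analytic roots of the derivative cubic; the refinement window (±60
  samples, ~±20 ms at 3 kHz) matches the antinode-crossing dip width so the
  fitted minimum is noise-averaged rather than noise-tracking.
- Transit thresholding is scale-free (5 × MAD of the baseline-subtracted
  signal); the two kept minima must be separated by an interior recovery of
  at least half the deeper dip (the node region), which prevents noise from
  splitting one antinode dip into two "minima".
- κ is evaluated by trapezoidal quadrature on a 1001-point axial grid
  (relative error ≪ 1e-6 for these smooth integrands) with `optimize()`
  over the centroid position; schedules evaluate each distinct geometry
  once (the doublet value is reused after elongation completes).
- Sub-sphere radii solve union-volume conservation with `uniroot()` at
  1e-12 tolerance; degenerate endpoints (d = 0, d = 2r) short-circuit to
  their closed forms.
- Interpolation everywhere is linear; event-time masses use rule-2
  (constant) extension only at trace ends.
- The lineage integrator evaluates the piecewise-linear profile's
  cumulative integral exactly (trapezoid on the breakpoint-augmented grid),
  so noiseless simulations are exact to floating point.

## Problem sizes in the tests

The suite validates on populations of 100 cells (event detection, parameter
recovery) and 180 cells (population summaries at the generator's calibrated
operating point), 1000-window regression-oracle sweeps, and 2×10⁵-point
Monte-Carlo geometry checks; these sizes give comfortable statistical margin
for every tolerance tested while keeping the whole suite around a minute.

## Known limitations

- The node-deviation scalar is a changepoint signal only; no acoustic model
  is attempted.
- Cells are assumed aligned with the channel axis and small relative to the
  cantilever (`bias_factor()` warns above ℓ/L = 0.2).
- Only one daughter is followed through division, mirroring the instrument.
- The biophysical M/A detector assumes measurable measurement noise; on
  idealised noise-free data its noise-scaled dip test is vacuous.
- Deposited-data layouts vary; `read_source_data()` requires an explicit
  schema map rather than guessing.
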