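---
title: "Models and methods behind phototherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phototherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototherm)
```

## The lumped-capacitance heating model

The central object of the package is the lumped-capacitance description of a
laser-heated colloidal sample. The suspension, its solvent and its container
are treated as one body at a uniform temperature with total heat capacity
$\sum_i m_i C_i$, gaining heat from the laser and losing it to the
environment at a rate proportional to the rise $\Delta T$ above ambient.
Under constant irradiation,

$$\Delta T(t) = \frac{\tau\,[\,I(1-10^{-A_\lambda})\,\eta + Q_0\,]}
  {\sum_i m_i C_i}\,(1 - e^{-t/\tau}),$$

and after switch-off $\Delta T(t) = \Delta T_{\mathrm{off}}\,e^{-t/\tau}$
with the same time constant $\tau$. The model assumes the sample is well
mixed (no internal gradients), that losses are linear in $\Delta T$, and that
heating and cooling share one $\tau$ — standard assumptions at
Eppendorf-vial scale with mild (tens of °C) rises.

One modelling point deserves emphasis: $Q_0$, the power picked up by the
solvent and vial rather than by the nanoparticles, must carry units of watts
for the balance to be dimensionally coherent, and the denominator of the
bracket is the heat-capacity sum alone. That is the only reading under which
both sides of the equation are temperatures, and it is the reading
implemented throughout.

Default component inventory: 1.0 g of water (4.184 J/g°C) and a 1.0 g
polypropylene tube (1.9 J/g°C), both overridable; experiments that quote a
bare solvent heat capacity can pass a single water component. Units are °C,
seconds, and watts everywhere.

## Efficiency estimation

`estimate_eta()` inverts the model in four steps.

**Steady-state rise.** `delta_t_max()` averages the last $k=3$ heating
samples (at the 1 frame/min cadence of a typical thermal camera, three
samples span the final 2 minutes of a 15-min irradiation). A trailing mean
is only unbiased once the plateau is genuinely reached, i.e. after roughly
ten time constants. Because the heating law is a known exponential, the
finite-duration bias has closed form: the trailing mean sees the fraction
$\frac{1}{k}\sum_j (1 - e^{-t_j/\tau})$ of the true plateau, with $t_j$ the
averaged sample times. `estimate_eta()` divides by this factor using the
cooling-fit $\tau$, which makes the plateau estimate exact on noiseless
model traces of *any* duration and is a no-op (factor $\to 1$) for long
ones. This correction is the package's deliberate design choice: thermal
protocols often stop heating after 2–3 $\tau$, where the raw trailing mean
would understate the plateau — and hence the efficiency — by 5 % or more.

**Time constant.** Cooling is source-free, so $\tau$ is fitted there:
$\log\theta$ with $\theta = (T - T_{amb})/(T_{off} - T_{amb})$ is regressed
on time, and $\tau = -1/\text{slope}$. Samples with $\theta \le 0$ (noise
below ambient) are dropped. The regression is weighted by $\theta^2$: for
additive camera noise of variance $\sigma^2$, the delta method gives
$\mathrm{Var}[\log\theta] \approx \sigma^2/\Delta T^2$, so inverse-variance
weighting is exactly $\theta^2$-weighting (up to a constant). Unweighted
log-linear fits let the noise-dominated tail of the decay swamp the slope —
on a 20 °C decay with 0.1 °C noise sampled to six time constants the
unweighted estimate can err by 70 % where the weighted one stays within a
couple of percent and tracks a nonlinear least-squares fit closely. On
noiseless data the weights are irrelevant and the fit is exact.

**Heat-transfer closure.** At steady state the dissipated power
$hA\,\Delta T_{max}$ balances the absorbed power, and the cooling ODE gives
$1/\tau = hA / \sum m_i C_i$; hence `estimate_hA()` returns
$\sum m_i C_i / \tau$. $h$ and $A$ never appear separately.

**Parasitic fraction.** A water-only control irradiated under identical
conditions heats purely parasitically, so
$\zeta = hA\,\Delta T_{max}^{(water)} / I$, and the forward model's $Q_0$
is $\zeta I$ — the package treats the two symbols as one physical quantity,
since no separate calibration recipe exists for them. A control whose
implied $\zeta$ reaches 1 is rejected as a calibration error. Without a
control, $\zeta = 0$ (efficiencies are then ceilings that include container
losses).

The final balance is
$\eta = (hA\,\Delta T_{max} - I\zeta)\,/\,(I(1-\zeta)(1-10^{-A_\lambda}))$.
A value outside $[0,1]$ is *reported as computed* with a warning flag rather
than clipped: an out-of-range $\eta$ is diagnostic (wrong absorbance, wrong
heat-capacity inventory, unreached plateau) and silent clipping would hide
it.

## Spectra

`find_lspr_peaks()` locates bands by topographic prominence (the height of a
local maximum above the higher of its two bounding valleys, valleys ending
at the nearest higher point). The most prominent peak in 450–620 nm is
reported as the out-of-plane/nanosphere band and the most prominent in
620–1300 nm as the in-plane band; the windows separate a ~534 nm sphere
resonance from in-plane bands anywhere in the NIR, and the default threshold
of 0.02 OD ignores baseline ripple at typical spectrometer noise. The
optical density entering the energy balance is linearly interpolated
(`od_at_wavelength()`); at 1 nm instrument resolution higher-order
interpolation is pointless. `normalize_to_od()` rescales a spectrum so its
in-plane band hits a target OD (0.56 by default), the concentration
normalization applied before comparative thermal runs; it is exactly
idempotent at the target.

## Phantom heat-diffusion simulator

`build_phantom()` assembles a 2-D cross-section (unit depth) of the
two-layer agarose skin phantom: a 4 mm epidermal band above an 8 mm dermal
band (dermal fills any extra grid depth), with a 1.25 mm-wide
nanoparticle-doped inclusion punched centrally into the epidermis. The
default grid is 64 × 96 cells at 0.25 mm — the inclusion then spans exactly
5 cells. All layers default to water-like thermal constants
($k = 0.6$ W/m°C, $\rho c = 4.18\times 10^6$ J/m³°C): agarose hydrogels are
thermally water; the optical additives (intralipid, melanoidin) affect only
the optics, which the model collapses into the beam's absorbed fraction.
The laser deposits $P\,(1-10^{-A_\lambda})\,\eta$ watts as a volumetric
source confined to inclusion cells with a Gaussian lateral profile
(1/e² spot diameter 3 mm by default), normalized so the total equals the
absorbed power exactly; optical attenuation through the epidermis is
neglected, attributing all heating to the doped region.

The integrator is explicit forward-time/central-space in flux form: face
conductivities are arithmetic means of the neighbouring cells, and each
step moves energy between cells through face fluxes, so on an insulated
grid the discrete energy $\sum \rho c\,T\,dx^2$ is conserved to round-off —
the `energy_audit()` identity input = stored + boundary loss is exact by
construction, not approximate. Time steps are validated against the
stability bound $dx^2 \min(\rho c) / (4 \max k)$ and rejected above it (the
error message quotes the computed bound); the default step is 90 % of the
bound, shortened so an integer number of steps fits each emitted frame.
Camera noise is added to emitted frames only, never to the evolving field,
and the noiseless final field travels with the stack for diagnostics.
Boundaries are insulated or uniformly convective
($h_b$, $T_{ext}$); pre-cooled protocols are expressed through the initial
temperature. Verification is against closed forms: the 2-D heat-kernel
solution (a Gaussian pulse stays Gaussian with variance growing as
$2\alpha t$; the simulator matches it to ~0.03 % RMS on a 64×64 grid), exact
linear mean-temperature growth under a constant source, a discrete maximum
principle, and `calibrate_inclusion_power()`, which exploits linearity of
the heat equation to scale a unit-power run onto any target hotspot rise.

**Known limitation — heat confinement.** In this 2-D unit-depth conduction
model, lateral decay away from a continuously driven source is
logarithmic, and by 300 s the diffusion length $\sqrt{4\alpha t}$ is about
13 mm. Consequently, when the inclusion hotspot is calibrated to +20 °C at
300 s, the simulator puts the surrounding region 2 mm from the inclusion at
roughly +12 °C — not the ≤ 3 °C confinement observed on real bench
phantoms. The discrepancy is structural, not numerical: a physical phantom
spreads heat in three dimensions and loses it from every exposed surface,
both of which steepen the lateral falloff, and by linearity no choice of
source power can change the simulated healthy-to-hotspot ratio. The 2-D
cross-section was chosen deliberately (it is what a thermal camera images,
and it keeps desk-scale runtimes); quantitative confinement claims need a
3-D or fin-loss extension, which is out of scope here. Relatedly, the
package's locality property is checked at the diffusion arrival time
$L^2/4\alpha$ of a 2 mm offset, where the far-cell rise is below 10 % of
the hotspot's; by $L^2/\alpha$ the ratio has already grown several-fold.

## Thermography

`roi_timeseries()` reduces each frame over an ROI with `max` by default —
thermal-camera readouts of heating experiments report peak temperatures, and
the hotspot maximum is robust to ROI size — with `mean` available. The
ambient reference comes from stack metadata when present, else from the
first frame outside the ROI. `thermal_contrast_map()` is last-frame minus
baseline-frame, and `dissipation_metrics()` reports per-region maxima of
that contrast for disjoint tumor/healthy masks. Stacks serialize to a
directory of plain CSV matrices plus `manifest.json`; vendor thermal-camera
formats are proprietary, so the package defines this open dialect instead.

## Viability

`compute_viability()` subtracts the 670 nm reference from the 570 nm
reading *per well* before any averaging (subtraction order is otherwise
unspecified in common protocols; per-well subtraction cancels well-level
optical offsets), then normalizes group means to the non-irradiated control
and propagates replicate standard deviations onto the same percent scale.
Plates need at least 3 replicates per group; statistical testing beyond the
table (ANOVA and friends) is deliberately left to standard tools.

## Synthetic data

The generators produce every input the pipeline reads, each with its ground
truth embedded in the output, so estimator accuracy is measurable end to
end. `generate_trace()` emulates the standard irradiation protocol — one
15-min heating and one 15-min cooling phase sampled once per minute —
with additive Gaussian camera noise (a realistic microbolometer noise floor
is 0.1–0.3 °C; tests use 0.1–0.2 °C). `generate_spectrum()` sums Lorentzian
bands (plasmon resonances are homogeneously broadened; for peak-picking
tests the line shape is cosmetic). `generate_mtt_plate()` draws well net
ODs as control × effect × (1 + CV·noise) around a 0.6 control OD with a
fixed 0.05 reference band. All noise goes through one explicit-seed
interface (`noise_spec()`), and seeded runs are bit-reproducible.

What the generators do *not* emulate: baseline drift and emissivity error
of real cameras, convective plumes in vials, scattering contributions to
the measured OD, spatial nonuniformity of MTT plates, or optical transport
through tissue. Passing round-trip tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to every
instrument artifact.

## Problem sizes and tolerances

The validation suite runs at desk scale by choice: traces of 31–101
samples, 200-replicate noise ensembles for bias checks, phantom grids of
64 × 96 (0.25 mm) for scenario runs and 24–64 cells for property checks,
and 10–300 s of simulated time. Key tolerances: noiseless efficiency
round-trips recover ground truth to 10⁻³ absolute across
$\eta \in [0.1, 0.9]$, $\tau \in [60, 600]$ s; with 0.2 °C noise the
estimator mean over 200 replicates stays within ±0.05 of truth; the cooling
fit is exact on noiseless decays and within 5 % at 0.1 °C noise; energy
audits close to 1 % (in practice to round-off); heat-kernel agreement is
required at 2 % RMS.
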