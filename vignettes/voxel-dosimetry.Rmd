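---
title: "Voxel-level dosimetry for a theranostic pair: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level dosimetry for a theranostic pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

`voxdose` projects absorbed doses for a therapeutic radiolabel (Lu-177) from
PET images acquired with an imaging surrogate (Zr-89) on the same targeting
vector. This vignette is the package's account of the science: the models at
each stage, the assumptions they rest on, the tunable parameters and their
defaults, and the places where a design decision had to be made.

## The theranostic substitution

Both labels are assumed to share their biological kinetics: the imaged
distribution differs from the therapeutic one only through physical decay.
Writing $\lambda = \ln 2 / t_{1/2}$ (Zr-89: $t_{1/2} = 78.41$ h; Lu-177:
$t_{1/2} = 159.53$ h, both from the shipped constants file
`inst/extdata/nuclides.json`), each voxel of a frame at time $t$ post
injection is rescaled:

$$A_{th}(t) = A_{img}(t)\, e^{(\lambda_{img} - \lambda_{th})\,t}.$$

Because $\lambda_{89} > \lambda_{177}$, the ratio exceeds 1 and grows with
$t$; the decay-corrected (biological) distribution is untouched. All decay
arithmetic uses the injection time as the time origin.

The half-lives and emission summaries live in one versioned JSON constants
file, loaded by `default_nuclides()` and overridable by `load_nuclides()`:
a single source of truth for code and tests. The Lu-177 emission summary is
a deliberate condensation — one charged line at the mean charged-particle
energy per decay (147.9 keV, yield 1) and the two principal gamma lines
(208.4 keV at 0.104/decay, 112.9 keV at 0.062/decay). Absolute dose values
therefore depend on this adopted table, which is stated rather than hidden:
a different nuclear-data summary shifts all doses proportionally. The
gamma-dose-rate constants used by the point-source release estimate
(`external_dose_rate()`) are likewise nominal configuration values, and that
estimate is documented as an upper-bound screen (no self-attenuation).

## Dose-rate engines

Three interchangeable engines convert an activity-concentration volume
(Bq/mL) plus a density volume (g/cm³) into absorbed dose rate (Gy/h).

**Local deposition** assigns each decay's charged-particle energy to its
source voxel:

$$\dot D = \frac{C \cdot E_{ch}}{\rho} \times 3.6 \times 10^6
\quad \left[\frac{\text{Bq}}{\text{mL}} \cdot \frac{\text{J}}{\text{g/cm}^3}
\to \frac{\text{Gy}}{\text{h}}\right].$$

The justification is the range of the Lu-177 beta spectrum: roughly 0.2–2 mm
in soft tissue, small against the 4 mm default voxel. This is the standard
voxel S-value approximation for the charged component; it is exact in the
engine's own terms, which is what the energy-conservation test asserts.

**Kernel convolution** adds the photon component by convolving the
decay-rate field with a discretized first-collision kernel. The photon model
is single-interaction full-absorption: a photon of energy $E$ travels with
the water attenuation coefficient $\mu(E)$ scaled by local density, and
deposits its full energy at its first interaction, whose radial density
around a point source is $\mu e^{-\mu r}/(4\pi r^2)$. This deliberately
ignores scatter cascades; for Lu-177 the photon yield is small (the photon
component is a few percent of the total dose), so the error is second-order
and bounded by the energy-balance test (deposited + escaped = emitted to
better than 1%). The kernel tabulates, per voxel offset, the energy
deposited per decay for a source uniformly distributed in its voxel. It is
built by deterministic quadrature — stratified source offsets × a Fibonacci
sphere of directions × free-path quantiles — so that shell totals follow the
analytic radial law exactly and the kernel sum equals
$\sum_l y_l E_l (1-e^{-\mu_l R})$ at truncation radius $R$ (default 30 cm;
energy beyond $R$ is accounted analytically as escaped). Center-point
evaluation was rejected because the $1/r^2$ singularity makes it inaccurate
for near offsets; the quadrature integrates the same continuous model the
Monte Carlo engine samples, while remaining a distinct numerical route.
Heterogeneous density enters through the division by local voxel mass; the
kernel itself is a water kernel at unit density, an approximation consistent
with the narrow density range of the phantom (1.0–1.4 g/cm³).

**Monte Carlo** samples the same physics per decay: the charged energy is
scored analytically in the source voxel (hence bitwise equality with the
local engine when a nuclide has no photon lines — a deliberate design
property, not an accident), and each photon is emitted from a uniform
position in the voxel in an isotropic direction, with its free path sampled
against the density-weighted optical depth along the ray (Amanatides–Woo
traversal). Tallies are scaled by true decay rate over simulated decays, so
the result is exactly linear in the activity field under a fixed seed. The
per-voxel relative standard error uses the analog estimator
$\sqrt{\sum w_i^2}$ over deposition weights; it follows the $1/\sqrt N$ law
(quadrupling the decays per voxel halves it), which the suite asserts over
seeds. The default is 8000 decays per activity-rich voxel; "activity-rich"
defaults to every voxel with nonzero activity and is configurable as a
fraction-of-maximum threshold. No claim is made about the absolute
uncertainty at 8000 decays — that number depends on the variance structure
of the transport code used, so only the scaling law is asserted.

Cross-validation: on a 16³ uniform Lu-177 phantom the MC and kernel
whole-volume mean dose rates agree within three standard errors across
seeds; both engines conserve energy in their own accounting.

## Time integration

Dose-rate maps at the scan times are integrated per voxel by the
trapezoidal rule. The schedule covers 4–73 h, which leaves two segments
open, and the handling of each is an explicit flag:

* **Head** (0 to first frame): `constant_backfill`
  ($H = \dot D_1 t_1$; the default — activity is present from injection, so
  backfilling the first measured rate is the conservative choice) or
  `zero_at_origin` ($H = \tfrac12 \dot D_1 t_1$, a linear rise).
* **Tail** (after the last frame): `physical_decay`
  ($T = \dot D_{last}/\lambda_{th}$; the default — once biological excretion
  has finished, elimination is physical decay only, which matches the
  observed late behaviour of this antibody system) or `none`.

With the default tail, a mono-exponential dose rate sampled densely is
integrated to $1/\lambda$ within 0.1%, and the tail term is exactly the
closed-form residual integral. Whether a head segment belongs in the
integral at all is genuinely open for this kind of schedule; both options
are surfaced in reports rather than silently fixed. Parametric
(mono/bi-exponential) time-activity fits are out of scope by design: the
pipeline is trapezoid-only.

## ROI metrics and prescription

SUV is the body-weight convention with the implicit 1 g/mL bridge between
tissue volume and mass:

$$\mathrm{SUV} = \frac{\bar C_{ROI}}
{A_{inj}\, e^{-\lambda_{img} T} / m_{subject}},$$

dimensionless with concentration in Bq/mL, activity in Bq and mass in grams.
ROI values are means (not maxima), and are labelled as such. The whole-body
QC decay-corrects the earliest frame and compares with the injected
activity; the pass criterion is ±10%.

Dose coefficients (Gy/GBq) come from a dose map whose frames were rescaled
so the administered therapy activity is 1 GBq ($10^9 / A_{inj,Bq}$ per
voxel, applied to the substituted frames); the per-ROI mean dose in Gy then
numerically equals the coefficient. The map carries that normalization as
provenance, and `dose_coefficients()` refuses maps without it — an
intentional guard against mixing absolute and per-unit maps.

Prescription divides the dose limit (default 3 Gy, the bone-marrow planning
constraint) by a binding coefficient. Two binding rules ship because the
choice is genuinely ambiguous in practice: `max_over_rois` (default;
safety-conservative — no constraint ROI exceeds the limit) and
`named_roi(<marrow site>)`, which anchors the prescription to one reference
marrow ROI even when another marrow ROI has a larger coefficient. With the
shipped reference table the named-left-shoulder rule reproduces the
reference activities (0.487–0.563 GBq across the three subjects), while the
max rule binds the spine for subject F-1 and prescribes less (0.381 GBq);
neither rule is asserted to be the "true" intent of the reference analysis.
Activities are reported to 3 decimals and doses to 2, with projected doses
computed from the unrounded activity.

## The synthetic phantom

No imaging data are publicly deposited for this problem, so the package
generates its own: a voxelized beagle on a 64 × 64 × 128 grid at 4 mm
isotropic (a desk-scale stand-in for a 256 × 256 / 2.5 mm clinical
acquisition — the grid is an emulation parameter, not a physics one). The
body is a soft-tissue ellipsoid (1.04 g/cm³, ≈ 11.5 L ≈ 12 kg, inside the
10–13 kg range of the emulated subjects) holding heart, liver, spleen,
adrenals, kidneys, spinal and shoulder marrow (1.03 g/cm³, wrapped in a
1.4 g/cm³ cortical-bone shell so the engines exercise density division) and,
for male subjects, testes. Voxels outside the body carry air density
(0.0012 g/cm³), as a CT-derived density map would.

Kinetics are compartmental with closed forms. Organ $o$ receives fraction
$f_o$ of the injected activity with uptake rate $k_{up}$ and clears it
biologically at $k_{bio}$ toward urinary/hepatobiliary excretion:

$$b_o(t) = f_o \frac{k_{up}}{k_{up}-k_{bio}}
\left(e^{-k_{bio}t} - e^{-k_{up}t}\right),$$

with activity still in blood transit ($f_o e^{-k_{up}t}$) held spatially by
the remainder-of-body compartment, which also has its own kinetics for the
unassigned fraction. The books balance exactly: resident + in-transit +
excreted = injected at every time, decay-corrected, which the suite checks
to 10⁻⁹. Cleared activity before the first voiding time (default 5 h, after
the first scan — the emulated protocol confirms no excretion before the
first frame) remains inside the body as bladder/gut content; afterwards the
cumulative urinary and hepatobiliary curves rise with the closed-form
clearance terms.

Default PK parameters were chosen once to reproduce the qualitative pattern
of the emulated antibody study and are not tuned further: liver dominates
(f = 0.35, slow hepatobiliary clearance), adrenals next, marrow accumulates
over time (small $k_{up}$ = 0.04 h⁻¹, mimicking osteophilic catabolite
deposition — marrow SUV rises from 4 h to 73 h), the heart is a fast blood
pool (SUV falls steeply), spleen and kidneys are minor, and the body
remainder clears at 0.05 h⁻¹ so that ≥ 80% of eventual biological excretion
has occurred by 73 h, after which physical decay dominates. The adrenal
uptake fraction (0.0013 per gland) was set against the *voxelized* gland
volume, since at 4 mm the ≈ 2 mL glands rasterize coarsely and
concentration — not uptake — determines SUV rank. The magnitudes of
published SUV curves are figure-read values and are deliberately not
targets; only orderings and trend directions are asserted.

Imaging degradation is an isotropic Gaussian PSF (σ = 4 mm) followed by
multiplicative Gaussian voxel noise (CV = 0.03), negatives clipped to zero,
fully seeded. The blur kernel is normalized, so activity is conserved up to
boundary truncation (< 0.5% for the interior-supported body). What the
phantom does **not** emulate: anatomical realism, respiratory/cardiac
motion, reconstruction artefacts (sinograms, the Bayesian penalized
likelihood chain), partial-volume recovery coefficients, registration error
between time points (frames share the grid; resampling handles grid
mismatch only, under a rigid-identity assumption). Tests passing on this
phantom therefore validate the *pipeline arithmetic and bookkeeping*, not
scanner behaviour on real data.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; world = origin + index · spacing (voxel
  centres). Volumes are stored as NIfTI (float32 for continuous fields,
  int16 for labels) with a JSON sidecar for units, timestamp, nuclide and
  origin; the round-trip contract is float32 precision.
* Label volumes must be resampled nearest-neighbour (trilinear is refused),
  which can only shrink the label set.
* $k_{up} = k_{bio}$ makes the compartment closed form degenerate and is
  rejected at construction rather than patched with a limit.
* Zero density under nonzero activity is rejected (it would make the dose
  rate infinite); organs overlapping or poking outside the body are
  rejected at rasterization.
* The MC uses R's RNG (seeded per call, previous state restored), so every
  stochastic result is reproducible from a single integer and the pipeline
  digest-test passes end to end.
* Dose coefficients are stable under voxel-resolution refinement (8 mm vs
  4 mm agree within 2%) for organs large against the voxel; thin structures
  such as a 12 mm-radius marrow cylinder at 8 mm spacing are partial-volume
  limited and do not satisfy this — a known limitation shared with real
  low-resolution PET dosimetry.

## Problem sizes

The shipped tests and the acceptance script run at deliberate desk scale:
the default phantom (64 × 64 × 128), a 16³ uniform phantom for the
engine cross-validation at 8000 decays per voxel, 20 noise realizations for
the whole-body QC, and single-voxel grids for integration closed forms.
These sizes were chosen so the full suite exercises every code path in
about a minute while leaving all tolerances attainable honestly; nothing in
the physics changes with the grid.

## Known limitations

Absolute agreement with any specific full transport code cannot be claimed:
the photon model is first-collision only, the charged component is local,
and the emission table is summarized. What the package does claim — and
tests — is internal consistency (energy balance, cross-engine agreement,
closed-form recovery) and exact reproduction of the reference prescription
arithmetic from a published-style coefficient table.
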