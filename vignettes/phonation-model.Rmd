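---
title: "A prescribed-motion model of glottal insufficiency and asymmetric phonation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A prescribed-motion model of glottal insufficiency and asymmetric phonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonosim)
```

## The problem

During phonation the two vocal folds oscillate and periodically interrupt the
tracheal air stream. Incomplete closure — *glottal insufficiency* — leaves a
residual gap (typically posterior and triangular, or midmembranous and
rectangular) through which air leaks during the nominally closed phase.
Left–right *asymmetric* oscillation, as in unilateral paresis, reduces one
fold's amplitude. Both disorders change the aerodynamic load on the folds and
degrade the acoustic output: the voice becomes breathier (lower cepstral peak
prominence), softer (lower sound pressure level), and less efficient (lower
vocal efficiency).

`phonosim` models this chain at desk scale with *prescribed* vocal-fold
motion: no tissue elasticity and no fluid–structure interaction. The flow and
wave-propagation stages are deliberately reduced-order surrogates for
resolved 3D computations, so the package reproduces exactly the *model
constants* and the *directional orderings* across conditions, not absolute
flow, energy, or level values.

## Glottal closure types

Five closure configurations span increasing insufficiency. Each is defined by
two parameters: the fraction of the fold length in contact at minimum opening
and the residual (initial) gap area $A_{i0}$:

| type | closed length | gap shape | $A_{i0}$ (mm²) |
|------|---------------|-----------|----------------|
| GC1  | 100%          | hairline slit | 0.5 (stability floor) |
| GC2  | 60%           | triangular, posterior | 2 (package default) |
| GC3  | 30%           | triangular, posterior | 5 (package default) |
| GC4  | 0%            | triangular, posterior | 10 (package default) |
| GC5  | 0%            | rectangular | half the baseline GAW maximum |

GC1's 0.5 mm² floor mimics the residual area a body-fitted flow solver needs
for stability; it is materialized as a uniform hairline slit so the profile
integrates exactly to the floor area while every practical width criterion
treats the glottis as closed. The GC2–GC4 areas are *package defaults*: in
the experiments these types derive from, they follow from a glottal gap index
whose areas are not published. They are required to be strictly increasing
and bounded by GC1's floor and GC5's half-maximum; override them via
`make_gc(overrides = )` if better estimates exist.

## Kinematics

The baseline glottal area waveform (GAW) is a skewed raised-cosine pulse:
closed for phases $[0.9, 1) \cup [0, 0.1)$, rising smoothly to the maximum
$A_{0\max} = \tfrac{2}{\pi} L\, d_G \approx 44.5\ \mathrm{mm^2}$ (with fold
length $L = 15$ mm and maximum width $d_G = 4.66$ mm) at peak phase 0.36, so
the opening phase is shorter than the closing phase (speed quotient < 1).
The original waveform this stands in for was digitized from high-speed video
and is not published point-by-point; `read_gaw_csv()` accepts a measured
waveform as a drop-in replacement.

Each closure type modifies the baseline affinely,

$$A_i(t) = A_{i0} + \frac{A_{0\max} - A_{i0}}{A_{0\max}}\, A_0(t),$$

which pins the cycle minimum at $A_{i0}$ and preserves the maximum.

The gap is distributed along the anterior–posterior axis as the
minimum-opening profile plus a half-sine envelope $\sin(\pi z / L)$ carrying
the oscillatory part. The envelope spans the full fold length for every
closure type (an envelope confined to the non-closed length would vanish for
GC1); the closure fraction lives entirely in the minimum-gap profile. Each
fold carries half of the gap scaled by its amplitude factor; setting one
factor to 0.5 scales the oscillatory part of the area waveform to exactly
$\tfrac{1 + 0.5}{2} = 75\%$ of the symmetric case, while the offset $A_{i0}$
is left untouched — the residual gap is a geometric insufficiency, not a
motion amplitude.

The mucosal wave is prescribed as a duct-angle schedule: convergent during
opening (0.1 T–0.32 T, 0° to +5°), divergent afterwards (0.32 T–0.9 T, −10°
to 0°), zero during closure. Only the interval ranges are fixed by the model
definition; the trajectory here is piecewise linear through vertices at the
interval midpoints (+5° at 0.21 T, −10° at 0.61 T), which is continuous and
attains both extremes.

Quotients: with the strict area criterion the open quotient of the baseline
is 0.8 (the prescribed closure interval). Reported values for the validated
configuration elsewhere use an unstated measurement threshold and are higher
(≈ 0.93); `gaw_quotients()` therefore exposes the threshold, and OQ/SQ are
reported but not treated as pinned constants.

## Flow surrogate

The glottal flow is quasi-steady incompressible orifice flow,

$$Q(t) = C_d\, A(t) \sqrt{2 \Delta p / \rho},$$

with $\Delta p = 775$ Pa, $\rho = 1.18415$ kg/m³, and $C_d = 1$ by default.
Inertance and viscous losses are omitted (the kinematic viscosity is kept
only for Reynolds-number reporting). This surrogate makes the mean flow
$\bar Q$ proportional to the cycle-mean area, which produces the expected
orderings — $\bar Q$ rising with insufficiency, falling with asymmetry, and
the glottal resistance $R = \Delta p / \bar Q$ ordered inversely — but not
the absolute values of a resolved turbulent simulation, which sees a larger
effective pressure drop and jet losses.

Wall pressure for the energy transfer is blended between two limits by the
instantaneous duct angle: near-inlet pressure on the convergent (opening)
duct, and the Bernoulli static pressure of a contracted intraglottal jet,
$\Delta p\,(1 - C_d^2/k^2)$ with contraction $k = 1 + \theta/40$, on the
divergent (closing) duct. This captures the push during opening and the
suction during closing that make the net aerodynamic work on the folds
positive over a cycle — the physiological regime that sustains flow-induced
oscillation — and reproduces the orderings: net work decreasing with
insufficiency (the oscillatory area amplitude shrinks by the factor
$1 - A_{i0}/A_{0\max}$) and reduced by asymmetry (wall velocities scale with
the mean amplitude factor). The wall-work surface uses a duct depth of 3 mm,
a typical medial-surface depth for M5-style fold geometries; it scales all
energies linearly and affects no ordering.

Units: resistance is reported in Pa·s/l (pressure per l/s), the convention
under which published glottal resistances have magnitudes near 10³.

## Acoustic synthesis

The source is the far-field monopole of the pulsating flow,
$p(t) = \frac{\rho}{4 \pi r}\, \dot Q(t)$, evaluated at 1 m and rescaled to
the microphones by spherical spreading (1/r). Because the source already
contains the single time differentiation of the radiated field, the optional
+6 dB/octave lip-radiation stage of classical source-filter synthesis is
**off** by default in the pipeline — applying both tilts the spectrum by
+12 dB/octave and promotes the third harmonic above the fundamental. The
stage remains available (`apply_vocal_tract(lip_radiation = TRUE)`) for
sources given as flow rather than flow derivative.

The /a/ vocal tract is an all-pole cascade of two-pole resonators at 1020
and 1350 Hz with conventional bandwidths of 130 and 160 Hz (bandwidths of
the reference tract are unpublished). Neighbouring resonances skew each
other's maxima, so pole angles are calibrated numerically at construction
until the cascade's magnitude peaks sit at the requested formants (fixed
point on a 0.25 Hz grid, ~0.1 Hz accuracy).

Aspiration noise — produced in a real larynx by turbulence at the residual
gap — is modeled as seeded Gaussian noise added to the source with RMS
proportional to the leakage flow through the minimum opening:
$\sigma = c_n \frac{\rho}{4\pi r} 2\pi f_0\, Q_{\min}$ with $c_n = 0.25$,
chosen so the harmonic-to-noise ratio of the rectangular-gap case lands in
the breathy range (≈ 6 dB). This is what makes CPP fall with insufficiency
and with asymmetry (the harmonic part scales with the motion amplitude, the
leakage noise does not). The two symmetry variants of each closure type
share a noise seed in `canonical_cases()` (common random numbers), so the
symmetric/asymmetric contrast isolates the motion effect.

Absolute SPL and VE therefore depend on the monopole calibration and the
noise coefficient; only differences and orderings across cases are
meaningful, and the package claims nothing else.

## Metrics

* **ASD** — Welch-averaged one-sided amplitude spectral density, Hann
  windows of four fundamental periods, 50% overlap, Parseval-consistent.
* **SPL** — $20 \log_{10}(p_{\mathrm{rms}} / 20\,\mu\mathrm{Pa})$, reported
  after extrapolating the 8 cm microphone to 20 cm.
* **VE** — $4 \pi R^2\, 10^{(SPL - 120)/10} / (P_{sub} \bar Q)$. The
  subglottal pressure entering the ratio is a configuration value
  (default: the 775 Pa driving pressure); resolved simulations see a
  different effective $P_{sub}$, which is one reason absolute VE values are
  not comparable.
* **CPP** — Hillenbrand-style: 40 ms Hann frames, 50% overlap, power
  cepstrum of the log power spectrum, linear regression over quefrencies
  1–15 ms, peak search 60–300 Hz, mean over frames. Both log transforms are
  floored 200 dB below their in-frame peak so exact spectral zeros cannot
  dominate the cepstrum. Frame length and regression band follow common
  convention (the reference implementation's parameters are unpublished).
* **Formants** — local maxima of the lightly smoothed log spectrum with a
  1 dB prominence threshold (the F1/F2 saddle of this /a/ is only ≈ 1.5 dB
  deep), refined by the three-point parabolic vertex. Noise-driven spectra
  need heavy segment averaging (tens of seconds of signal) before the
  saddle is resolved reliably.
* **OQ/SQ** — area-threshold quotients, threshold 0 by default (see above).

## Pipeline and problem sizes

`run_case()` executes geometry → kinematics → flow → energy → synthesis →
metrics for one of the ten canonical cases (GC1–GC5 × symmetric/asymmetric)
and is bit-reproducible given the case seed. Default resolutions: 2048 GAW
samples per cycle, 128 stations along the folds, 44.1 kHz audio, 10
initialization cycles discarded, 10 cycles for the aerodynamic and spectral
averages. The cepstral layer alone gets 256 synthesized cycles (~1.7 s),
because 40 ms frames need several hundred milliseconds of signal for a
stable mean; the extra cycles repeat the deterministic waveform and extend
only the noise realization. A full ten-case study takes a few seconds on one
CPU.

```{r study, eval = FALSE}
study <- run_study()
study$table
study$trends
```

## What the synthetic generator does and does not emulate

The generator reproduces: the prescribed kinematics and its printed
constants, quasi-steady flow orderings, a harmonic voice source with
formant filtering, and leakage-scaled aspiration noise. It does **not**
emulate: turbulent jet structure and its spectral shaping, cycle-to-cycle
flow variability, jet deflection by triangular gaps, ventricular-fold
interaction, vocal-tract propagation effects beyond two formants, or any
fluid–structure interaction. Passing the packaged tests therefore validates
the kinematic/aerodynamic model algebra and the metric implementations, and
the *direction* of the disorder effects — not absolute agreement with
resolved 3D simulations or with measured voices.

## Known limitations

* Absolute $\bar Q$, $W_{net}$, SPL, VE, and CPP values are
  surrogate-specific; comparisons are meaningful only within a study.
* GC2–GC4 initial gap areas are package defaults, not published values.
* The baseline GAW is a parametric stand-in; supply a measured waveform via
  `read_gaw_csv()` where available.
* The open quotient follows the strict area criterion; threshold-based
  conventions report higher values.
* The wall-pressure blending is a closure for the energy transfer's sign
  and ordering, not a pressure-field model.
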