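# phonosim

Desk-scale simulation of voiced sound production with **prescribed
vocal-fold motion**, built for studying two common voice disorders and their
acoustic consequences:

* **glottal insufficiency** — incomplete closure of the glottis, from a
  small posterior gap to a full-length rectangular gap, parameterized as
  five closure types GC1–GC5 (closed-length fraction and initial gap area
  `A_i0`);
* **left–right asymmetry** — one vocal fold oscillating at reduced
  amplitude (50% by default), which scales the oscillatory part of the
  glottal area waveform to 75% of the symmetric case.

The package is aimed at voice scientists and students who want a fast,
fully reproducible working model in which the *model-defining constants* and the
*directional effects* of these disorders can be computed, rather than a
replacement for resolved 3D aeroacoustic simulation.

## Model

One oscillation cycle at fundamental frequency f0 = 148 Hz is prescribed:

1. **Glottal area waveform (GAW).** A baseline pulse `A_0(t)` is closed on
   phases [0.9 T, 0.1 T), peaks at `A_0max = (2/π)·L·d_G ≈ 44.5 mm²`
   (fold length L = 15 mm, maximum width d_G = 4.66 mm). Each closure type
   modifies it affinely:

   `A_i(t) = A_i0 + (A_0max − A_i0)/A_0max · A_0(t)`

   so the minimum becomes `A_i0` (0.5 mm² for GC1, half of `A_0max` for
   GC5) while the maximum is preserved.

2. **Motion.** The gap is spread along the folds by a half-sine envelope
   plus the minimum-opening profile (triangular posterior gaps for GC2–GC4,
   rectangular for GC5); a convergent–divergent duct-angle schedule (0° to
   +5° while opening, −10° to 0° while closing) prescribes the mucosal
   wave; per-fold amplitude factors implement asymmetry.

3. **Flow.** Quasi-steady Bernoulli orifice flow
   `Q(t) = Cd·A(t)·√(2Δp/ρ)` at Δp = 775 Pa, with a duct-angle-blended wall
   pressure driving the fluid-to-tissue energy transfer
   `Ė_net = Σ p_wall (v·n̂) dS`.

4. **Acoustics.** Far-field monopole source `p = ρ/(4πr)·dQ/dt`, plus
   leakage-scaled aspiration noise, filtered through an all-pole /a/ vocal
   tract with formants F1 = 1020 Hz and F2 = 1350 Hz, radiated by spherical
   spreading to microphones at 5, 8 and 20 cm.

5. **Metrics.** Mean flow Q̄, glottal resistance `R = Δp/Q̄` (Pa·s/l), net
   cycle work `W_net`, Welch amplitude spectral density, SPL re 20 µPa,
   vocal efficiency `VE = 4πR²·10^((SPL−120)/10)/(P_sub·Q̄)`,
   Hillenbrand-style cepstral peak prominence, formant extraction, and
   open/speed quotients.

The flow and propagation stages are openly reduced-order surrogates;
absolute flows, energies and levels are model-specific, while printed
constants and the orderings across the ten cases are reproduced exactly.
See the methods vignette (`vignettes/phonation-model.Rmd`) for assumptions,
parameter meanings and limitations.

## Worked example

```r
library(phonosim)
rep <- run_case(case_spec("GC3", "asymmetric"))
print(rep)
#> <metrics_report GC3-asy>
#>   Q_mean     0.610 l/s     R_glottis  1271.3 Pa.s/l
#>   W_net      71.8 uJ      SPL(20cm)  82.3 dB
#>   VE         0.0180 %      CPP        18.1 dB
#>   f0 peak    148.0 Hz     formants   1020, 1350 Hz
#>   OQ 0.80  SQ 0.48  A_min 5.00 mm^2  A_max 34.62 mm^2
```

Reading: a 30%-closed posterior gap with one fold at half amplitude passes
a mean flow of 0.61 l/s under the 775 Pa drive (resistance ≈ 1271 Pa·s/l);
the airflow feeds 71.8 µJ per cycle into the folds; the radiated signal at
20 cm is voiced at 148 Hz with the /a/ formants, at 82.3 dB SPL and a CPP
of 18.1 dB. Rerunning the symmetric variant raises Q̄, W_net, SPL and CPP —
the directional signature of the disorder. The full ten-case comparison:

```r
study <- run_study()          # GC1–GC5 × {symmetric, asymmetric}
study$table                   # per-case metric table
study$trends                  # all directional flags, TRUE under defaults
```

A command-line front end with `geometry`, `gaw`, `flow`, `synth`,
`metrics` and `run` subcommands lives in `inst/cli/phonosim.R`:

```sh
Rscript inst/cli/phonosim.R run --all --out-dir out --seed 1
Rscript inst/cli/phonosim.R synth --case GC1-sym --mic 8cm --wav gc1.wav
```

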