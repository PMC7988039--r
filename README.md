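# biosonarsim

Desk-scale simulation of how a dolphin's biosonar "sees" objects that
differ only in material composition.

In an echoic-to-visual matching-to-sample experiment, a bottlenose
dolphin inspected a sample object by echolocation and then had to pick
the matching object by eye. With air-filled PVC pipe objects (AF) and
closed-cell-foam-wrapped pipes (SF) the animal matched far above the
1/4 or 1/2 chance level; with the same shapes built from water-filled
PVC pipes (WF) or foam-ball arrays (FB) it dropped to near chance. The
physical explanation lives in the echoes: an air backing reflects the
click almost totally, a water-filled pipe returns only the weak
reflections of its two thin walls, and a column of foam balls scatters
the click into a multi-lobed interference field.

`biosonarsim` reproduces the acoustic side of that experiment as a 2D
time-domain simulation, plus the behavioral statistics:

- **Scenes** (`build_scene`): a seawater domain with one of the four
  targets rasterized 1.1 m from the source, built from the published
  material constants (seawater 1527 m/s / 1022 kg/m³, PVC 2218/1350,
  foam-ball 500/300, closed-cell foam 1700/330, air 343/1.2).
- **Source** (`generate_pulse`, `calibrate_aperture`): the
  Gaussian-windowed 60 kHz click
  `Q(t) = -A exp(-2π²f₀²(t-t_p)²) sin(2πf₀t)` on the open window
  `t_p ± 1/f₀` (RMS bandwidth 37.7 kHz), radiated by a line aperture
  calibrated by bisection against the analytic uniform-line directivity
  to the published 11.1° far-field 3-dB beamwidth.
- **Solver** (`run_simulation`): a velocity–pressure staggered-grid
  FDTD scheme for heterogeneous (c, ρ) media with dispersion-matched
  fourth-order stencils, harmonic-mean face densities (so interface
  reflections converge to the Fresnel coefficients `(Z₂-Z₁)/(Z₂+Z₁)`),
  pressure-release treatment of sealed air, and a graded-damping
  absorbing boundary measured below −40 dB spurious return.
- **Echo characterization** (`echo_metrics`, `beam_pattern_from_arc`,
  `detect_highlights`, …): energy flux density (dB re 1 µPa²·s), −10 dB
  envelope duration, spectral centroid and RMS bandwidth, echo-to-click
  level ratio at the on-axis 0.5 m point, highlight structure, beam
  patterns on the 0.5 m circle with 3-dB beamwidths and an in-plane
  directivity index, and the 264 µs energy-detector window.
- **Behavioral statistics** (`simulate_trials`, `binomial_test`,
  `summarize_case`, `power_curve`): synthetic Bernoulli trial records
  and the exact binomial test against chance (direct summation, no
  normal approximation), with Monte-Carlo power analysis.
- **Analytic oracles** (`reflection_coefficient`, `stack_reflection`,
  `analytic_line_directivity`, `measure_interface_reflection`,
  `measure_boundary_reflectivity`): closed-form references every solver
  claim is tested against.

## Worked example

```r
library(biosonarsim)

# the click: 60 kHz Gaussian-windowed sinusoid
p <- generate_pulse(f0 = 60e3, sample_rate = 2e6)
spectral_moments(p$samples, 1 / p$sample_rate) / 1e3
#>      centroid rms_bandwidth
#>      62.59019      38.02931        # kHz; RMS bandwidth ~37.7

# the surrogate transmit aperture
calibrate_aperture(11.1)$length
#> [1] 0.1158763                      # m, ~0.116

# one full case (about 80 s at the desk preset)
af <- run_case("AF")
af$metrics[, c("case_kind", "echo_click_ratio_db", "duration_us",
               "centroid_khz", "rms_bandwidth_khz", "n_highlights")]
#>   case_kind echo_click_ratio_db duration_us centroid_khz rms_bandwidth_khz n_highlights
#> 1        AF           -5.026471    13.35075     61.64317          32.09398            1
beamwidth_3dB(af$beam)
#> [1] 14.9889                        # degrees, single main lobe

# behavioral analysis at the AF regime
summarize_case(simulate_trials("AF", 96, 0.927, 4, seed = 1))
#>   case_kind n_trials n_correct chance_level  accuracy      p_value significant
#> 1        AF       96        92         0.25 0.9583333 4.348788e-50        TRUE
```

The AF echo-to-click ratio of about −5 dB decomposes exactly as the
package's analytic oracles predict: image-source spreading over the
0.5 m vs 1.7 m paths (−5.3 dB) plus the broadband reflectivity of the
3 mm-PVC-over-air front wall (+0.6 dB, `stack_pp_reflectivity`). The
water-filled pipe sits ~8 dB lower, the foam-wrapped pipe within 1 dB
of AF, and the foam-ball echo spreads into three or more lobes where
the pipes return one — the ordering that tracks the dolphin's
behavioral performance. See the methods vignette
(`vignettes/biosonar-target-discrimination.Rmd`) for the model's
assumptions and which published quantities are and are not reproducible
from a surrogate-source model.

## Command line

A thin wrapper over the same functions lives at
`inst/cli/biosonarsim.R`:

```sh
Rscript inst/cli/biosonarsim.R run-case --case AF --out out/
Rscript inst/cli/biosonarsim.R compare-cases --out out/
Rscript inst/cli/biosonarsim.R simulate-trials --case WF --n 48 \
    --accuracy 0.625 --alternatives 2 --seed 1 --out out/
Rscript inst/cli/biosonarsim.R selftest
```
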