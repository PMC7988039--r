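---
title: "Simulating biosonar discrimination of material-matched targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating biosonar discrimination of material-matched targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bottlenose dolphin inspecting an object by echolocation receives an echo
whose level, highlight structure and spectrum depend on the object's
material composition, not just its shape. In a cross-modal
matching-to-sample experiment, a dolphin matched air-filled PVC pipe
objects (AF) and closed-cell-foam-wrapped pipes (SF) far above chance, but
performed near chance with the same shapes built from water-filled PVC
pipes (WF) or foam-ball arrays (FB). `biosonarsim` reproduces, at desk
scale, the acoustic side of that experiment: a 2D time-domain simulation
of a single echolocation click travelling 1.1 m to a target of one of the
four material compositions, the characterization of the returning echo,
and the exact binomial analysis of (synthetic) behavioral trials.

## The model

### Scene and materials

The scene is a vertical 2D slice of seawater containing the source, the
receivers, and the target. All media are lossless fluids described only by
sound speed and density: seawater (1527 m/s, 1022 kg/m^3), PVC (2218,
1350), foam-ball material (500, 300), soft closed-cell foam (1700, 330),
and air (343, 1.2) for the sealed pipe interiors. The acoustic impedance
mismatches at the material interfaces drive everything: water/PVC reflects
with amplitude coefficient +0.315, water/foam-ball -0.82, water/foam
-0.47, and any interface against air is near-total and phase-reversed
(-0.9995).

The published study's geometry describes the targets only as simplified 2D
cylindrical sections; the exact sections are not quantified. This package
models the three pipe cases as a vertical pipe seen in cross-section
through its axis: a rectangular section of outer width 48 mm and length
300 mm, with walls on all sides, so the click crosses the front and back
walls at normal incidence. AF has 3 mm PVC walls and a sealed air
interior; WF is the identical shell filled with seawater; SF is a 16 mm
PVC pipe (2 mm wall, air interior) centered in a 48 mm closed-cell foam
wrap. FB is a vertical column of six 48 mm foam-ball disks at 50 mm
center-to-center spacing (the mono-filament line is ignored); six balls at
that spacing fill the same 300 mm footprint as the pipe sections. These
section choices are assumptions, and the absolute echo levels are
sensitive to them (see *Limitations*).

### The source

The excitation is a Gaussian-windowed sinusoid with center frequency
`f0 = 60` kHz (the peak frequency dolphins favor for in-tank target
detection), truncated to the open window `tp - 1/f0 < t < tp + 1/f0`. The
envelope decays to ~3e-9 at the window edges, so the only consequential
free parameter is the carrier phase under the envelope peak, set by `tp`.
At `tp = 1/f0` the two spectral lobes at plus and minus `f0` interfere so
that the power-spectrum RMS bandwidth collapses to 33.1 kHz; at
essentially any other phase it is 37.3-37.8 kHz. The default
`tp = 1.125/f0` (phase pi/4) reproduces the 37.7 kHz RMS bandwidth of the
emitted broadband click while keeping the window inside `t >= 0`.

The dolphin's head, which focuses the click into an ~11 degree beam, is
not modeled; its one externally relevant property is reproduced by a
surrogate: a vertical line aperture whose length (~0.116 m) is calibrated
by bisection against the analytic uniform-line directivity so that the
far-field 3-dB beamwidth at `f0` is 11.1 degrees. A point-source mode is
retained for oracle tests.

Two subtleties of driving a 2D grid deserve note. First, a soft pressure
source radiates the time derivative of its drive, and 2D propagation adds
a half-order integration near the wavefront; the aperture is therefore
driven with the half-order time integral of the configured pulse
(frequency-domain multiplication by `(i 2 pi f)^(-1/2)`), so the radiated
far-field waveform is the pulse itself and the emitted spectrum stays
centered where the pulse says. Second, the 11.1-degree calibration is a
single-frequency property: the peak-to-peak pattern of the full
octave-bandwidth click is intrinsically a degree or two narrower than the
60 kHz pattern (the aligned peak loses its high-frequency content faster
off axis). Transmit-beam width is therefore measured on the spectral
amplitude at `f0` per angle (`component = "tone"` of
`beam_pattern_from_arc()`), while echo beam patterns keep the
peak-to-peak reading used for the published patterns.

### The solver

Wave propagation uses a velocity-pressure staggered-grid finite-difference
time-domain scheme for heterogeneous `(c, rho)` media. Spatial
differences are fourth-order staggered stencils with dispersion-matched
coefficients (`c2 = (1 - S^2)/24`, `c1 = 1 + 3 c2`, with `S` the Courant
number of the background water): this cancels the leading combined
space-time phase-error term along the grid axes, which carry the long
source-target-receiver paths. With plain second-order differences the
~1% phase-speed error at 100 kHz visibly violates the `1/sqrt(r)`
spreading law over metre-scale paths at the default resolution; with the
matched fourth-order stencil the measured 0.3 m / 0.6 m peak-to-peak
ratio is `sqrt(2)` to four digits. The price is a tighter stability
bound: `solver_config()` requires a Courant safety factor of at most
0.85 (default 0.8). `max_stable_dt()` reports the classical 2D bound
`safety * dx / (c_max * sqrt(2))`.

Face densities are harmonic means of the adjacent cells, which makes
normal-incidence interface reflections converge to the plane-wave Fresnel
values (verified against water/PVC, water/foam and water/air half-spaces).
Air is the exception: a resolved thousand-fold density contrast makes the
explicit scheme locally unstable at any practical time step, so cells with
density below 50 kg/m^3 are treated as pressure-release (`p = 0`), the
standard underwater-acoustics limit; the measured water/air reflection is
then -0.9975 against the analytic -0.9995. The absorbing boundary is a
graded-damping sponge (cubic profile, 40 cells by default) whose measured
spurious return, isolated by differencing against an enlarged-domain
reference run, is below -40 dB.

Receivers sit at cell centers: a "lower-jaw proxy" 0.10 m below and
0.05 m behind the source (the study gives no coordinates for its
receiving point), an on-axis calibration point 0.5 m from the source
where echo-to-click level ratios are defined, and an optional arc on the
0.5 m circle centered on the target for echo beam patterns. All levels
are scaled after the run so the outgoing click at the calibration point
has a 220 dB re 1 uPa peak-to-peak level; the simulation is linear, so
this is purely a unit convention and every reported comparison is a
ratio.

### Resolution presets

The `"desk"` preset (dx = 1.5 mm, 1.6 m x 1.0 m domain) is used for
routine runs and the test suite; `"paper"` (dx = 1.0 mm, larger domain)
for closer quantitative work. 1.5 mm is simultaneously the coarsest grid
satisfying the ten-cells-per-wavelength rule at 60 kHz with margin
(~17 cells) and the coarsest that puts two cells across the 3 mm PVC
pipe wall. The SF inner pipe wall is 2 mm, which the desk grid covers
with one to two cells; `build_target_map()` accepts that (down to one
cell) for SF while holding the two-cell rule for the AF/WF 3 mm wall.
One caveat of the wavelength rule: it references the background water;
the foam-ball interior (c = 500 m/s) has a 8.3 mm wavelength that the
desk grid resolves with only ~5.5 cells, so FB interior transmission is
the least resolved part of the model (the half-space oracle test for
foam therefore runs at dx = 0.8 mm).

### Echo characterization

`echo_metrics()` mirrors the five-column characterization of the study:
energy flux density `10 log10(integral p^2 dt)` in dB re 1 uPa^2 s,
duration between the outermost -10 dB crossings of the Hilbert envelope,
spectral centroid and RMS bandwidth of the power spectrum (moments over
10-200 kHz by default, excluding DC and grid-dispersion artifacts, with
8x zero-padding), and peak-to-peak level. A sliding 264 us energy window
emulates the dolphin ear's energy-detector integration.

Two estimator notes. The Hilbert envelope equals the true envelope only
for narrowband signals; for the octave-bandwidth source click itself the
-10 dB duration reads ~10 us rather than the 8.05 us Gaussian closed
form (the closed form is exact for narrowband pulses, and the test suite
verifies it there). And highlight detection defines a highlight as an
envelope peak within 10 dB of the strongest peak (mirroring the -10 dB
duration convention), with at least 10 dB of topographic prominence and
15 us separation. In the SF echo this finds three highlights, not two:
the water/foam front face (-4.2 dB), the interior PVC/air reflection
(0 dB), and the first-order reverberation inside the planar foam wrap
(-5.8 dB, one foam round trip after the main peak, rising from a deep
interference null). The reverb sits only 1.6 dB below the true first
highlight, so no threshold can separate them robustly; rather than tune
the detector to the desired count, the count is reported as the
detector sees it, and the two-highlight characterization is asserted on
the two strongest peaks, which are exactly the two claimed interfaces
at the foam-transit separation.

The in-plane directivity index `10 log10(2 pi / integral D^2 dtheta)` is
a 2D definition; it is reported for completeness but not compared against
the published value, whose 2D-vs-3D convention is not stated.

## What the simulation does and does not reproduce

The simulation's own physics is validated by a chain of independent
oracles: Fresnel coefficients at half-spaces, `1/sqrt(r)` cylindrical
spreading, rigid-wall energy conservation, reciprocity, mirror symmetry,
and a 1D transfer-matrix oracle for the layered target sections
(`stack_reflection()`, `stack_pp_reflectivity()`). The echo-to-click
level ratio of each pipe case is predicted by composing the image-source
spreading term `20 log10(sqrt(0.5 / 1.7)) = -5.3` dB with the broadband
stack reflectivity (AF ~ +0.6 dB, WF ~ -7.3 dB, SF ~ -1.6 dB); the
solver lands within a fraction of a dB of these compositions, so the
desk-scale ratios are AF ~ -5, WF ~ -12.7, SF ~ -5.6 dB with an AF-WF
gap of ~8 dB.

The published ratios (-9.1, -23.1, -10.2 dB; a 14 dB AF-WF gap) are not
reproducible from this geometry: the transfer-matrix oracle shows the
gap for flat 3 mm PVC walls at normal incidence is 7-8 dB at any
bandwidth or resolution. The difference is attributable to what the
surrogate deliberately omits - the CT-derived head on the receive path
and the actual, unquantified 2D target sections. The relative ordering
that carries the study's interpretation is reproduced: WF is the weakest
reflector by a wide margin, AF and SF are comparable and strong, the FB
pattern is multi-lobed while the pipe echoes have a single dominant
lobe, and the SF echo carries two highlights separated by the foam-wrap
two-way travel time (~23 us here; the published ~30 us depends on the
same unquantified geometry).

## Synthetic behavioral trials

`simulate_trials()` generates Bernoulli trial records at a stated true
accuracy against a chance level of 1/2 or 1/4 - the statistical skeleton
of the matching experiment (n = 96 at chance 0.25 for AF and SF, n = 48
for WF and FB, per the study's design). It deliberately omits session
structure, learning, and any dependence between trials; passing tests
therefore show that the analysis pipeline (exact binomial test by direct
summation, per-stratum summaries, Monte-Carlo power) is correct, not that
real dolphin choices are exchangeable Bernoulli draws. Trial sets mixing
2- and 4-alternative designs must be split per stratum before testing;
for this reason the published pooled p-values for the mixed WF/FB designs
are not reproduction targets.

## Numerical choices, in one place

- Time step: CFL-derived (default safety 0.8); the study's fixed 0.8 us
  step is unstable for an explicit scheme at these grids.
- Source injection: additive soft pressure source over the aperture
  cells, half-order-integral drive shaping.
- Gating: outgoing click and returning echo at the calibration point are
  split at the click peak plus the 0.5 m-to-target round trip minus a
  60 us guard; the jaw-receiver echo window opens 80 us before the
  geometric first arrival.
- Problem sizes: the test suite runs the four desk-preset cases
  (~1070 x 670 cells, ~5600 steps each), one free-field transmit run,
  one finer AF run at 20 cells per wavelength for grid convergence, and
  small oracle scenes; grid convergence is assessed between the coarsest
  wall-resolving grid (17 cells per wavelength) and 20 cells per
  wavelength because 10 cells per wavelength cannot resolve the 3 mm
  wall.

## Limitations

- Absolute echo levels and durations depend on the assumed rectangular
  sections; only relative, ordering-level statements are robust. The
  planar foam wrap also preserves internal reverberation that curved
  sections would defocus, which is why the SF highlight count reads
  three rather than two.
- Cell-center (staircase) rasterization quantizes the 3 mm pipe wall to
  whole cells, so the front-wall internal-bounce phasing shifts between
  grids and the peak-to-peak echo level converges only at first order
  in dx (~0.5 dB between 17 and 20 cells per wavelength); centroid and
  bandwidth converge below 5% there.
- All media are lossless fluids; PVC shear waves and material absorption
  are not modeled (the study's pressure-acoustics treatment makes the
  same assumption).
- The 2D model spreads cylindrically, not spherically; level ratios
  between unequal path lengths differ from 3D by the square root of the
  distance ratio.
- The receive path has no head anatomy: the jaw receiver reads the free
  field at a point.
- The foam-ball interior is under-resolved at the desk preset, biasing
  FB echo levels slightly upward.
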