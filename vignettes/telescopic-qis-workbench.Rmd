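---
title: "Methods: the telescopic-QIS bioluminescence imaging workbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the telescopic-QIS bioluminescence imaging workbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qisbench)
```

`qisbench` models the design and evaluation of photon-starved microscopes
built around three detector classes: sCMOS, EMCCD and photon-number-
resolving QIS sensors. This vignette is the package's account of the
science it implements: the models, their assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## 1. Optical-train scaling laws

A microscope train is an objective (focal length $f_\mathrm{obj}$,
numerical aperture NA), an optional afocal Keplerian relay
($f_1$ objective-side, $f_2$ camera-side), a tube element and a camera.
The effective magnification is

$$M_\mathrm{eff} = \frac{f_\mathrm{tube}}{f_\mathrm{obj}} \cdot \frac{f_1}{f_2},$$

the relay factor being the angular magnification of the afocal pair
acting on the infinity-space field angles. With $f_1 > f_2$ the relay
*demagnifies*: the image of a given sample region shrinks, so the same
collected photons land on fewer pixels. That is the telescopic trick —
image brightness scales as $\mathrm{NA}^2/M_\mathrm{eff}^2$ and photon
flux per pixel as $\mathrm{NA}^2 d^2 / M_\mathrm{eff}^2$ ($d$ = pixel
pitch), so a 2.6x train feeds a 1.1 µm-pixel QIS far more photons per
pixel than a 20x train feeds a 16 µm-pixel EMCCD per unit *area*, while
the resolution limit (for sampling-limited systems) improves as
$M_\mathrm{eff}/d$, the inverse effective pixel size.

Nominal magnifications convert to focal lengths through the
manufacturer's reference tube length, 180 mm by default (the Olympus
convention matching the bundled objectives); it is a parameter of
`lens_spec()` for other manufacturers. The relay orientation $f_1/f_2$
is the only one consistent with a 40x objective (f = 4.5 mm), a 20x tube
objective (f = 9 mm) and a 45/35 mm relay producing an overall 2.57x
(quoted 2.6x) magnification; `microscope_config()` implements exactly
that composition.

Spec-sheet configurations can also be declared directly by their nominal
`m_eff` and `na`. The bundled presets do this, carrying the *quoted*
magnifications (20x, 2.6x, 8x, 6.5x): design ratios printed in a spec
sheet are arithmetic on quoted values, and 2.6 rather than the underlying
2.571 is what reproduces the published two-decimal resolution ratio 1.89.
Ratios are reported at full precision alongside half-away-from-zero
rounding to printed precision (`round_printed()`).

Field of view is reported as sensor side and diagonal divided by
$M_\mathrm{eff}$; it is an upper bound since internal-aperture vignetting
is deliberately out of scope (no ray tracing, aberrations or diffraction
PSF — see §3 for the empirical blur stand-in). Whether a single quoted
FOV number refers to a side, a diagonal or an illuminated circle varies
by instrument, so the package never guesses: both numbers are emitted.
The QIS chip area is taken from the manufacturer-stated 20.25 mm²
(`sensor_area_mm2` override) because the exact active pixel count of the
16 MP part is not public; side lengths still derive from pitch x count.

## 2. Detector noise model

`expose()` simulates, per frame and pixel, in order:

1. photoelectrons $n \sim \mathrm{Poisson}(\phi\,QE\,t + D\,t)$ from flux
   $\phi$ (photons/pixel/s), quantum efficiency $QE$, exposure $t$ and
   dark current $D$;
2. electron multiplication when `em_gain` $g > 1$: the default register
   model draws $\mathrm{Gamma}(\mathrm{shape}=n, \mathrm{scale}=g)$, the
   standard continuous approximation whose output variance under Poisson
   input is exactly $2\lambda g^2$ — excess noise factor $F^2 = 2$. The
   physical 604-stage Bernoulli branching register (each electron
   duplicating with probability $p$, $(1+p)^{604} = g$) is implemented in
   `em_register(method = "branching")` and serves as the validation
   oracle; its $F^2 \to 2$ as gain grows. Amplified electrons clip at the
   register full well;
3. Gaussian read noise (rms `read_noise_e`, applied post-register in raw
   electrons, so the input-referred floor of an EMCCD is
   $\sigma_r / g$);
4. ADC: $\mathrm{DN} = \mathrm{round}(e/\mathrm{adc\_gain}) +
   \mathrm{offset}$, clipped to the bit-depth ceiling. Saturation (full
   well or DN ceiling) is recorded in a mask;
5. photon-number-resolving sensors skip steps 2–4 and report the exact
   photoelectron count plus offset — ideal counting, with an optional
   per-pixel `bit_error` probability (default 0) for miscounts.

Clock-induced charge, fixed-pattern noise, pixel non-uniformity and
rolling shutter are not modelled. Dark current is a spec-sheet parameter,
not fitted; the bundled values are data-sheet figures, which is why
long-exposure QIS behaviour (where dark accumulation can matter) is only
as good as that figure.

The closed-form oracle is

$$\mathrm{SNR} = \frac{S\,QE}{\sqrt{F^2\,(S\,QE + D\,t) + \sigma_r^2}},$$

with $F^2 = 2$ for EM cameras and 1 otherwise, and
$\sigma_r^2 = (\mathrm{read}^2 + \mathrm{adc\_gain}^2/12)/g^2$. The
quantisation term makes the prediction match the *digitised* output; it
is dropped when electrons reach the ADC as exact integers (no read noise,
no EM smearing), and photon-number-resolving sensors have $\sigma_r = 0$.
`monte_carlo_snr()` computes the empirical counterpart — mean of
dark-subtracted DN over its standard deviation — and the suite requires
agreement within three delta-method standard errors at 1–1000
photons/pixel for all bundled cameras.

### The equalised benchmark flux

The simulated three-camera benchmark (`run_benchmark_sim()`) equalises
photon flux per pixel across cameras, implementing the neutral-density
normalisation of a physical benchmark as exact scaling. Its default is
**0.5 photons/pixel per 2 s exposure**, chosen from the closed form
before any simulation: the EMCCD's advantage over the sCMOS exists only
where read noise dominates shot noise, i.e. below
$S \lesssim \sigma_{r,\mathrm{sCMOS}}^2 / QE \approx 1.3$ photons/pixel
for the bundled spec sheets; above that, quantum-efficiency differences
dominate and the ordering changes. Bioluminescent samples genuinely
occupy this sub-photon regime, which is why EMCCDs (and now QIS sensors)
exist. At 0.5 photons/pixel the per-pixel SNR ordering is
QIS > EMCCD > sCMOS both analytically and by Monte Carlo; the magnitude
of the gaps depends on spec-sheet values and is not a claim the package
calibrates.

## 3. Phantoms

All generators are pure functions of (parameters, seed) returning flux
fields in photons/pixel/s with full provenance records.

**Bar targets.** `make_resolution_target()` renders five-bar square waves
by *analytic area sampling*: each pixel's flux is the exact mean of the
continuous pattern over the pixel footprint, so contrast loss near
Nyquist arises from physical sampling rather than generator aliasing.
A configurable sub-pixel phase offset tests phase sensitivity. An
optional Gaussian blur stands in for the optical PSF — the package has no
diffraction model — with default width $0.25\,\lambda/\mathrm{NA}$ at
$\lambda = 460$ nm (blue luciferase emission); with blur the pixel
average uses 16-point sub-pixel quadrature of the analytically blurred
profile.

**Spots.** Lorentzian ($b + A\gamma^2/(r^2+\gamma^2)$) and Gaussian
profiles, the shapes the profile-fit SNR procedure assumes.

**Cell scenes.** Elliptical cell bodies at an intracellular flux with
separated Gaussian puncta, plus faint point emitters along linear
extracellular trails — the structure of luciferase-tagged cells shedding
extracellular vesicles, spanning the detector dynamic range. Flux levels
are free parameters (no enzyme-kinetics photon budget exists for such
scenes); defaults are order-of-magnitude placeholders and the provenance
record says so. Punctum and vesicle centres snap to pixel centres so the
configured peak contrast is realised exactly on the grid.

**Brownian time-lapses.** Per axis,
$x_{t+1} = x_t + v\,\Delta t + \mathcal{N}(0, 2D\Delta t)$; emitters are
rendered as Gaussian spots and ground truth recorded. Particles reflect
at the field boundary to stay in view; tests that need unreflected steps
use fields large enough that reflection never triggers.

What passing tests on these phantoms shows — and does not: parameter
recovery on simulated data validates the *procedures* (fitting,
averaging, linking, root finding) under the stated noise model. It does
not validate the noise model against any particular physical camera, nor
does it capture optical aberrations, sample motion or substrate
depletion in real recordings.

## 4. Measurement procedures

**Averaging and subtraction.** Signal and background stacks are averaged
pixel-wise and subtracted; negative values are retained, since clipping
at zero would bias subsequent noise statistics.

**Two SNRs.** Both use the same noise figure: the standard deviation of
each background ("source off") frame, averaged over frames — a whole-
frame statistic by default, with an ROI variant available.
`snr_lorentzian()` fits $b + A\gamma^2/((x-x_0)^2+\gamma^2)$
(Levenberg–Marquardt, `minpack.lm`) to a horizontal line profile of the
subtracted average and takes the fitted amplitude $A$ as signal;
`snr_max()` takes the maximum gray value. Zero background noise is an
error, not an infinite SNR.

**MTF.** For each spatial frequency the averaged image's box profile
(column means) yields Michelson contrast from the five peaks and four
interleaved troughs; $C(0)$ comes from the brightest/darkest 5% pixel
fractions of a zero-frequency reference; $\mathrm{MTF}(f) = C(f)/C(0)$,
clipped to [0, 1]; a least-squares cubic is fitted and its x-intercept is
the resolution limit. Numerical choices, each configurable:

* *Extremum location*: a 3-sample moving average stabilises peak
  location, but contrast values are always read from the unsmoothed
  profile; the smoothing is skipped when the known half-period is below
  3 samples, where it would erase the modulation being measured.
* *Alias rejection*: detected peaks must be spaced like the imaged line
  set — mean spacing within max(15%, 0.35 px) of the known period.
  Beyond Nyquist, moiré fringes mimic bars at the wrong spacing; an
  analyst comparing the image against the printed target spacing would
  reject them, and so does the code (contrast 0, flagged, and retained
  in the fit rather than dropped — unresolved frequencies must pull the
  curve down).
* *Root selection*: a cubic can have spurious low- or far-frequency
  roots. The limit is the smallest real root above the highest frequency
  whose fitted MTF is ≥ 0.2; the fit runs on $f/f_\mathrm{max}$ and
  trailing coefficients below $10^{-8}$ of the largest are zapped before
  root finding, so collinear samples yield the linear root rather than a
  floating-point artefact.

On a simulated pixel-limited 2.6x telescopic train
(`run_mtf_experiment()`, 16 frequencies to 1.35x Nyquist, 10 frames each)
the recovered limit is ~1.3x the 1182 pl/mm Nyquist frequency —
sampling-limited as designed. The measured contrast above Nyquist is
phase-dependent in any single image; the experiment fixes a 0.3-pixel
phase offset so bars are never grid-aligned.

**Dynamic range.** Maximum gray value over the mean of a signal-free
background patch. On a two-level scene whose bright plateau drives the
EM register into saturation, an EMCCD at gain 300 measures a strictly
smaller dynamic range than a photon-counting camera — the directional
content of the published comparison; the exact factor depends on well
depths and ADC ranges.

## 5. Particle tracking

Localisation is the intensity-weighted centroid of the ROI after
subtracting the ROI median (a spot is "found" when the maximum exceeds
the median by 3 robust deviations). Linking is nearest-window: each
frame is searched within `search_radius_um` of the previous position,
with one refinement pass recentring the window on the first estimate so
truncated tails are symmetric about the spot — without it, window
truncation biases drifting particles. Multi-hypothesis assignment and
gap closing are out of scope (isolated particles only).

The reported "diffusion velocity" is the mean Euclidean step length over
the frame interval, as the measured-image procedure defines it. For
Brownian motion this statistic is interval-dependent
($\mathbb{E}[v] = \sqrt{\pi D / \Delta t}$, the Rayleigh mean), so an
MSD-based estimator $\hat D = \overline{s^2}/(4\Delta t)$ ships alongside
as a clearly-labelled extension. Diameters come from a Gaussian fit to a
line profile (orientation is a parameter; default horizontal through the
brightest pixel), reported as FWHM $= 2\sqrt{2\ln 2}\,\sigma$; values at
or below the configured instrument resolution limit are censored to
"≤ limit", since there the optics, not the particle, set the width.

## 6. Denoising preparation

`n2n_targets()` builds Noise2Noise training pairs: each target is the
exact pixel-wise mean of 7 adjacent frames centred on the input frame.
Edge frames are excluded rather than given a shrunken window, keeping
target noise uniform across pairs; sums are accumulated before a single
division, so targets equal brute-force window means bit-for-bit. The
networks themselves are out of scope — any image-to-image callable can
register by name (`register_denoiser()`), and the non-learned window
mean ships as a baseline. Everything downstream of a denoiser (or of
`gamma_display()`, the display-only min–max + power transform) carries a
`denoised` flag, and metrics propagate it as `photon_calibrated = FALSE`:
after denoising, intensities are no longer detected photon counts.

## 7. Problem sizes and determinism

The simulation experiments in the test suite use deliberately modest
sizes, chosen as the smallest that leave the relevant standard errors
well inside the asserted tolerances: 2–4 x 10⁴ pixels for Monte-Carlo
SNR (3-SE agreement), 3 x 10⁴ draws for the branching-register oracle
(5%), 16 frequencies x 10 frames for the MTF experiment, 50 particles x
19 steps for the Rayleigh-mean speed (3 SE). Every stochastic path is
seeded; `expose()` is bit-reproducible given a seed, and experiment
runners derive per-stage sub-seeds from one master seed and record them
in a manifest.

## 8. Known limitations

* No optics beyond the scaling laws: vignetting, aberrations and
  diffraction are absent, and the Gaussian blur is an empirical stand-in.
  Real MTF limits can fall below the sampling limit for optics-limited
  trains; the simulated experiment only reproduces the sampling-limited
  case.
* The noise model omits clock-induced charge, which in practice degrades
  real EMCCD backgrounds and widens the QIS advantage; simulated EMCCD
  figures are therefore *optimistic*.
* Bundled spec sheets are data-sheet values for the three detector
  classes, not measurements of any individual camera.
* The tracker assumes isolated particles; crossing trajectories will be
  mislinked.
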