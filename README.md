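# qisbench

Bioluminescence microscopy is photon-starved: luciferase reporters emit
orders of magnitude fewer photons than fluorophores absorb and re-emit, so
every design choice in a bioluminescence microscope trades signal-to-noise
ratio (SNR) against spatial resolution, field of view (FOV) and dynamic
range. `qisbench` is a workbench for reasoning about those trades
quantitatively. It targets microscope builders and image analysts working
with the three detector classes used in low-light imaging — scientific
CMOS (sCMOS), electron-multiplying CCD (EMCCD) and photon-number-resolving
quanta image sensors (QIS) — and in particular the *telescopic*
configuration in which a Keplerian relay between objective and tube
objective demagnifies the image onto a small, tiny-pixel QIS chip without
vignetting the field.

## What it computes

**Optical-train design calculus.** Image brightness scales as
$B \propto \mathrm{NA}^2 / M_\mathrm{eff}^2$ and the photon flux per pixel
as $\mathrm{NA}^2 d^2 / M_\mathrm{eff}^2$, where $\mathrm{NA}$ is the
objective's numerical aperture, $M_\mathrm{eff}$ the effective
magnification of the train (objective x relay x tube element) and $d$ the
pixel pitch. For pixel-sampling-limited systems the resolution limit
scales as $M_\mathrm{eff}/d$ — the inverse of the effective pixel size
$d/M_\mathrm{eff}$. `qisbench` evaluates these for arbitrary lens/camera
spec sheets (`lens_spec()`, `camera_spec()`, `microscope_config()`,
`run_design_report()`), with a bundled library of benchmark
configurations (`microscope_preset()`).

**Detector noise simulation.** `expose()` converts a photon-flux scene
into digital frames through the full chain: Poisson photoelectrons and
dark current, stochastic electron multiplication (gamma register model,
with an exact per-stage Bernoulli branching oracle in `em_register()`),
Gaussian read noise, ADC gain/offset/quantisation, full-well and bit-depth
clipping, and ideal photon-number-resolving readout for QIS-class
sensors. `analytic_snr()` is the closed-form per-pixel SNR
$S\,QE / \sqrt{F^2 (S\,QE + D t) + \sigma_r^2}$ (excess-noise factor
$F^2 = 2$ for EM cameras) that the simulator is validated against.

**Phantoms.** Five-bar resolution targets (exact area sampling over pixel
footprints), Lorentzian/Gaussian illumination spots, bioluminescent
cell + extracellular-vesicle scenes spanning the detector dynamic range,
and Brownian point-emitter time-lapses with ground truth.

**Measurement procedures.** Frame averaging with background subtraction;
SNR by Lorentzian profile fit and by maximum gray value (noise = mean of
per-frame background standard deviations); bar contrast
$C = (I_\mathrm{peak}-I_\mathrm{trough})/(I_\mathrm{peak}+I_\mathrm{trough})$,
MTF$(f) = C(f)/C(0)$ and the cubic-fit x-intercept resolution limit;
max-over-background dynamic range; single-particle tracking with mean 2D
step speed and Gaussian-fit FWHM diameters; Noise2Noise target
construction (pixel-wise mean of seven adjacent frames) and the gamma
display transform.

## Worked example

```r
library(qisbench)

# the conventional 20x EMCCD train vs the 2.6x telescopic QIS train
rep <- run_design_report(microscope_preset("lv200_emccd_20x"),
                         microscope_preset("qiscope_2.6x"))
rep
#> <design_report> lv200_emccd_20x vs qiscope_2.6x
#>   lv200_emccd_20x: M_eff 20, pixel 800 nm, Nyquist 625 pl/mm, FOV 409.6 um, sensor 67.11 mm2
#>   qiscope_2.6x: M_eff 2.6, pixel 423.1 nm, Nyquist 1182 pl/mm, FOV 1733 um, sensor 20.25 mm2
#>   photon flux/pixel (a/b): 3.83549 (printed 3.8)
#>   brightness (a/b):        0.0181287 (printed 0)
#>   resolution (a/b):        0.528846 (printed 0.53)
#>   sensor area / FOV side (a/b): 3.314 / 0.2364
```

The conventional train collects 3.8x more photons per (much larger)
pixel, but the telescopic train samples the sample plane 1.89x finer
(`1 / 0.529`; 423 nm vs 800 nm effective pixels) and sees a 4.2x wider
field despite the 3.3x smaller chip.

```r
# simulated camera benchmark at equalised, photon-starved flux
run_benchmark_sim(seed = 1)
#> <benchmark_sim> equalised photon flux per pixel: 0.5 photons/px
#>  camera photons_per_pixel  snr_max snr_lorentzian mc_pixel_snr analytic_snr
#>   scmos               0.5 1.847523      0.4473635    0.3128283    0.3128187
#>   emccd               0.5 8.679247      3.1794217    0.4697591    0.4674752
#>     qis               0.5 3.303374      1.0593885    0.5739429    0.5776938
```

At half a photon per pixel the per-pixel SNR ranks QIS > EMCCD > sCMOS:
the QIS counts photons with no read-noise penalty, the EMCCD beats the
sCMOS read-noise floor but pays the excess-noise factor 2, and the
Monte-Carlo column agrees with the closed-form prediction.

```r
# resolution limit of a simulated pixel-limited telescopic system
ex <- run_mtf_experiment(microscope_preset("qiscope_2.6x"), seed = 1)
ex$fit
#> <mtf_fit> 16 frequencies, C(0) = 0.9224
#>   resolution limit: 1534 pl/mm
```

The recovered bar-target limit brackets the 1182 pl/mm Nyquist frequency
of the 423 nm effective pixel, as expected for a sampling-limited system.

## Documentation

The methods vignette (`vignettes/telescopic-qis-workbench.Rmd`) describes
the noise model, the measurement procedures and every numerical design
choice; function-level documentation is in the roxygen comments.
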