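# sdoptics

Optical diagnosis of the rodent cortex exposed to a laser-induced shock wave
(LISW): an R implementation of the full analysis pipeline behind fiber-based
diffuse reflectance spectroscopy and intrinsic optical imaging of
shock-wave-induced spreading depolarization (SD).

A topical shock wave to the rat brain triggers spreading depolarization — a
slowly propagating wave of near-complete neuronal depolarization — followed by
long-lasting vasoconstriction, oligemia and hypoxemia. All of these events
leave optical signatures: a drastic light-scattering transient at 805 nm, a
blood-volume dip at the 569 nm hemoglobin isosbestic point, an oxygenation
swing in R578/R569, a heme aa3 redox dip in R605/R620, EEG suppression, a
negative DC potential shift, and a bright/dark scattering wave expanding over
the cortex at millimetres per minute. `sdoptics` provides, for each of those
readouts, the forward model, the estimator, and a synthetic-data generator so
the whole chain is testable without any instrument.

## What is inside

* **Photon transport** — MCML-style weighted-photon Monte Carlo in layered
  tissue (Henyey–Greenstein scattering, Fresnel boundaries, Russian
  roulette) for an 800 µm / 2 mm source–detector fiber pair, with an exact
  azimuthal-arc detection estimator, per-photon sampling-depth statistics,
  and diffusion-theory closed forms as oracles
  (`simulate_reflectance()`, `sampling_depth()`).
* **StO2 inversion** — absorbance `A(λ) = −log10 R(λ)` regressed on
  tabulated HbO/HbR extinction spectra over 500–620 nm, and a pre-computed
  quadratic conversion model mapping the regression coefficients
  `(α_HbO, α_HbR, α_0)` to `(C_HbO, C_HbR, a)`; saturation is
  `StO2 = C_HbO / (C_HbO + C_HbR)`
  (`fit_conversion_model()`, `invert_spectrum()`, `invert_series()`).
* **Event detection** — baseline normalization, band ratios, and detectors
  for the scattering transient, EEG suppression, DC shift, long-lasting
  hypoxemia and heme aa3 reduction, assembled into per-animal event rows
  (`detect_*()`, `classify_recording()`).
* **Wave kinetics** — difference imaging, front tracking (95th-percentile
  radius of super-threshold pixels) and least-squares speed fits; expansion
  speed from multichannel onset regression
  (`difference_stack()`, `track_front()`, `fit_front_speed()`,
  `onset_regression()`).
* **Cohort summary** — the packaged 24-animal event table with exact tallies
  and the linear fluence → peak-pressure / impulse calibration
  (`lisw_cohort()`, `tally_events()`, `fit_pressure_calibration()`).
* **Synthetic data** — deterministic generators for every input modality:
  trace bundles with programmed SD morphology, forward-modeled reflectance
  spectrum series, expanding-annulus image stacks, distance-ordered
  multichannel traces, and Bernoulli cohorts (`gen_*()`).

## Worked example

```r
library(sdoptics)

## cohort tallies from the packaged event table
tally_events(lisw_cohort())
#> Animals: 24; SD (scattering change + EEG suppression): 18
#>   long-lasting hypoxemia among SD: 15 (83.3%)
#>   heme aa3 reduction among SD:     14 (77.8%)

## shock-wave calibration: peak pressure rises linearly with laser fluence
fit_pressure_calibration(lisw_calibration(), "pressure")
#> pressure calibration: slope 79.2 MPa cm2/J, intercept 4.9, R^2 0.9970

## scattering-wave speed from a synthetic NIR image stack
stack <- gen_wave_stack(speed_mm_per_min = 2.4, seed = 1)
fit_front_speed(track_front(difference_stack(stack)))
#> Front track: 16 samples, speed 2.38 mm/min (intercept 0.41 mm, R^2 1.000)

## hypoxemia expansion speed from three fiber channels at 2.0/4.5/7.0 mm
ch <- gen_multichannel(speed_mm_per_min = 2.6, seed = 1)
est <- hypoxemia_expansion_speed(lapply(ch, baseline_normalize), c(2, 4.5, 7))
est$speed_mm_per_min
#> [1] 2.63
```

The tally says that 18 of 24 exposed animals showed spreading depression
(scattering change plus EEG suppression), and that among those, 83.3% went on
to long-lasting hypoxemia and 77.8% to heme aa3 reduction — the strong
coupling between SD and metabolic compromise that motivates the pipeline. The
recovered wave speeds (2.38 and 2.63 mm/min against programmed 2.4 and 2.6)
are within the estimators' stated tolerances.

The StO2 chain works the same way at larger compute:
`fit_conversion_model(method = "mc")` builds the conversion model from Monte
Carlo forward runs (a few minutes), after which `invert_spectrum()` turns any
reflectance spectrum into concentrations and saturation. A quick analytic
stand-in for exploration is `method = "diffusion"`.

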