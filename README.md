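# dmiq — deuterium metabolic imaging analysis

dmiq quantifies [6,6′-²H₂]glucose metabolism from dynamic deuterium
(²H) MR spectroscopy and 3-D chemical shift imaging (CSI) of brain
tumors. It is written for MRS/preclinical-imaging researchers who
acquire serial ²H spectra after a deuterated-glucose bolus and need
absolute lactate, Glx (glutamate+glutamine) and glucose
concentrations, kinetic summaries, glycolytic-vs-mitochondrial
subtype calls, and pre/post-treatment response statistics — plus a
synthetic-data generator that makes the whole chain testable without
scanner data.

## The models at the core

**Spectral fitting** (`fit_resonances()`): prior-knowledge
time-domain least squares in the AMARES tradition, with Gaussian
lineshapes. The FID is modeled as

    s(t) = Σ_m a_m e^{iφ} e^{2πi f_m t} exp(−(π w_m)² t² / (4 ln 2))

with frequencies constrained to the known ²H shifts (water 4.7,
glucose 3.72, Glx 2.3, lactate 1.3 ppm), linewidths `w_m` bounded,
non-negative amplitudes and a shared zero-order phase. Amplitudes are
solved by variable projection; frequencies/widths/phase by bounded
Levenberg–Marquardt. The fit returns a classed model object with
`coef()`, `summary()`, `fitted()`, `residuals()`, `plot()` and
`simulate()` methods.

**Quantification** (`concentration_from_areas()`): water-referenced
absolute concentrations

    c_m = [I_m / (n_m F_m)] / [I_w,base / (n_w F_w)] × 12.48 × 0.80 mmol/L

with deuteron counts `n_m` and the steady-state saturation factor
`F = (1 − E₁)/(1 − cos α · E₁)`, `E₁ = exp(−TR/T₁)`, per-species T₁
(water 320, glucose 64, Glx 146, lactate 297 ms) at TR 140 ms and
nominal flip 50°.

**CSI** (`csi_reconstruct()`, `tensor_denoise()`,
`metabolite_maps()`): centered unitary spatial DFT reconstruction of
9 × 9 × 3 phase-encoded dynamic data, multilinear low-rank (HOSVD)
denoising of the (x, y, z, FID, frame) array at ranks (6, 6, 3, 24,
5), and per-voxel fitting into concentration maps (NIfTI export).

**Kinetics & response** (`kinetics_summary()`, `subtype_score()`,
`response_analysis()`): initial rates (OLS slope over the first
20 min), steady-window averages (20–65 min), the lactate/Glx subtype
score, one-way ANOVA with Tukey post-hoc tests, and paired pre/post
percent-change reports.

## A worked example

Simulate a glycolytic tumor's 65-min dynamic series at the default
noise preset, fit every 5-min frame, quantify against the baseline
water signal, and summarize:

```r
library(dmiq)
acq    <- dmi_acq()          # 2003 Hz / 256 pts / TR 140 ms / 50 deg
priors <- dmi_priors()       # water, glucose, Glx, lactate
truth  <- simulate_timecourses(subtype_preset("glycolytic"))
series <- simulate_dynamic_series(truth, acq, priors,
                                  noise_sd = 0.7, seed = 1)
tc <- quantify_series(fit_series(series))
kinetics_summary(tc)
#> kinetic summary (rates mmol/L/min, averages mmol/L):
#>  metabolite   rate rate_se window_avg window_sd
#>     glucose 0.0971 0.01162      0.763     0.473
#>         glx 0.0321 0.02339      0.752     0.149
#>     lactate 0.0626 0.00164      1.018     0.160
#> subtype call: glycolytic (lactate/Glx score 1.35; lac 1.02, Glx 0.752 mmol/L)
```

The lactate steady-window average (1.02 mmol/L) recovers the preset
plateau (1.08 mmol/L, ~98% saturated across the window); the
lactate/Glx score 1.35 is well above the calibrated glycolytic
threshold (0.90). A single frame's fit is a model object:

```r
fit <- fit_series(series)$fits[[10]]
fit
#> Gaussian resonance fit: 4 resonances, 68 iterations, converged
#>  resonance   area   freq_hz   ppm fwhm_hz phase_deg
#>      water 7.1573   -0.1704 4.696   17.50  -0.04912
#>    glucose 1.3461  -44.1139 3.735   21.93  -0.04912
#>        glx 0.7884 -114.2500 2.200   29.39  -0.04912
#>    lactate 1.4952 -156.4587 1.276   25.14  -0.04912
#> RSS 235.5 (residual fraction 0.0993)
```

Treatment response from published group means — a 48% lactate
reduction in the glycolytic A11 model:

```r
percent_change(1.08, 0.56)
#> [1] 48.14815
```

End-to-end orchestration (simulate → fit → quantify → report) is
available as `run_simulate()` / `run_fit_quantify()` / `run_csi()` /
`run_respond()`, or from a shell via the thin wrapper
`inst/scripts/dmi-pipeline.R` with subcommands `simulate`, `fit`,
`quantify`, `csi`, `respond`, `report`.

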