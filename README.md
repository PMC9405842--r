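# oculodex

Binocular disconjugacy analysis and oculomotor screening from
eye-tracking time series.

During fixation the two eyes are normally yoked. In dyslexic readers,
binocular coordination is frequently poorer: fixations are punctuated by
brief micro-movements in which the eyes drift in *opposite* directions.
`oculodex` detects these episodes in binocular horizontal gaze recordings
and turns their rate into a screening feature, alongside a classical
velocity-threshold saccade analysis. It is aimed at oculomotor and
reading-research groups working with 200 Hz binocular video-oculography.

## The index

Given left/right horizontal positions `xl`, `xr` (degrees) on timestamps
`t` (seconds), the package computes

* the disparity `d_i = xl_i − xr_i`, and
* the per-interval velocity product
  `dv_i = (Δxl_i / Δt_i) · (Δxr_i / Δt_i)`  in (deg/s)².

`dv < 0` marks an interval where the eyes moved in opposite directions
(left +10 deg/s with right −10 deg/s gives −100 (deg/s)²; +10 with +20
gives +200 and is conjugate). Maximal negative runs are split wherever
`sign(d)` changes, labelled micro-converging or micro-diverging by
whether `|d|` shrinks or grows, and filtered to a minimum dwell of three
samples. The **Disconjugacy Global Index** is

```
DGI = (number of retained segments) / (recording duration)   [segments/s]
```

reported with the mean segment duration (ms) and mean amplitude (deg).
A cross-validated SVM / ridge-logistic pipeline classifies dyslexic vs
control recordings from these features; a calibrated simulator generates
labelled cohorts with ground-truth events for validation.

## Worked example

```r
library(oculodex)

sim <- simulate_recording(dyslexic_profile(), sim_config(),
                          subject_seed = 2024)
res <- compute_dgi(sim$recording)
res
#> <dgi_result> 896 segments over 29.995 s: DGI = 29.872 /s
#>   mean duration 11.71 ms, mean amplitude 0.00253 deg

head(res$segments[, c("start_s", "duration_ms", "amplitude_deg", "direction")], 3)
#>  start_s duration_ms amplitude_deg  direction
#>    0.020          10   0.002210354  diverging
#>    0.045          10   0.001198393 converging
#>    0.075          10   0.001598972 converging
```

This simulated dyslexic subject produces 896 opposite-direction
micro-segments in 30 s — a DGI of 29.9 segments/s, in the dyslexic range
(the two packaged populations centre near 13.9 and 27.4 segments/s).
Segments last ~10–25 ms and mostly stay below 0.005 deg in amplitude.
The conventional saccade descriptors of the same recording:

```r
f <- extract_features(sim$recording)
round(unclass(f)[c("amplitude_n", "amplitude_mean", "peak_velocity_mean",
                   "fixation_duration_mean")], 3)
#>            amplitude_n         amplitude_mean     peak_velocity_mean
#>                 50.000                  5.395                166.623
#> fixation_duration_mean
#>                528.700
```

i.e. 50 saccades, mean amplitude 5.4 deg, mean peak velocity 167 deg/s,
fixations of ~530 ms. A labelled cohort and classifier:

```r
co  <- simulate_cohort(sim_config(seed = 42))     # 2 x 46 subjects x 7 paintings
dgi <- dgi_features(co$recordings)
ds  <- assemble(co$manifest, dgi, "combined")$combined
crossvalidate(ds$x, ds$y, "svm_rbf", seed = 42)
#> <cv_report> svm_rbf, n = 644, 5 folds
#>   mean accuracy 93.49%, sensitivity 93.50%, specificity 93.48%
```

A thin command-line wrapper is installed at `inst/cli/oculodex`
(`validate`, `dgi`, `features`, `simulate`, `classify` subcommands).

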