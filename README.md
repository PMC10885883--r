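# kidwatch

Early warning of parturition (kidding) in goats from leg-mounted triaxial
accelerometers.

Goats that kid in winter need prompt birth assistance — hypothermia in the
first hours drives neonatal mortality. Just before giving birth a doe lies
on her side with the legs stretched out, moving them continuously under
labor pains. A sensor strapped to the tibia sees this directly: upright
postures put the static 1-g gravity component on the sensor's X axis,
lateral recumbency rotates it onto Z, and labor adds sustained movement.
`kidwatch` is for researchers and precision-livestock engineers who want a
complete, testable implementation of the resulting detection pipeline —
including a behavior-level stream simulator, since no public labor
recordings exist.

## The method

Per-record classification feeds a windowed index, which is thresholded by
a three-sigma rule:

* a decision tree labels every record labor / non-labor from its
  `(x, z)` acceleration counts (support-vector machine kept as baseline);
* over each time window, **LPI = TA × TLP** — the activity-flagged record
  count times the labor-classified record count; only labor scores high
  on both factors;
* the window length `w ∈ {8, 10, 12, 14}` min is chosen to maximize
  **CRV = MSL − MSNL**, with `MSL = mean − sd` of per-goat parturition-day
  maximum LPIs and `MSNL = mean + sd` of the 110 highest non-labor LPIs;
* the alarm threshold is **TCKG = mean + 3 sd** of that non-labor pool;
* the first window with `LPI > TCKG` raises a detection at time DPT and
  predicts the first birth at **PPT = DPT + MDV**, where MDV is the
  calibrated mean detection-to-birth offset.

## Worked example

Simulate a 17-goat herd (36 h of dual-rate records per goat, labor
episodes ending in known birth times), train the classifier, calibrate,
and detect:

```r
library(kidwatch)
res <- run_study(seed = 1)

res$tree$metrics$accuracy
#> [1] 0.9941368

print(res$calibration)
#> Window selection by central range value (CRV = MSL - MSNL):
#>  window_min labor_mean labor_sd       msl nonlabor_mean nonlabor_sd    msnl
#>           8  172896.65  5173.48 167723.17       2559.77     1317.19 3876.96
#>          10  267724.94  6760.09 260964.85       3782.59     2024.76 5807.35
#>          12  381140.59 11964.55 369176.04       4722.03     2995.08 7717.11
#>          14  517683.47 13883.49 503799.98       5777.66     4181.12 9958.78
#>        crv
#>  163846.21
#>  255157.49
#>  361458.93
#>  493841.20
#> Chosen window: 14 min (CRV 493841.20)
#> Three-sigma threshold (non-labor mean + 3 sd): 18321.01
#> Mean detection-to-birth offset: 96.1 min (sd 4.10)

print(res$report)
#> Parturition detection: 17 of 17 goats (100.0%); missed 0 (0.0%)
#> False alarms: 0 on 17 non-parturition days
#> Detection lead time: mean 96.1 min (sd 4.10)
```

Reading the output: every simulated labor episode crossed the threshold
(the labor-window index, ~500,000, dwarfs the 18,321 threshold), no
goat's labor-free pre-parturition day raised an alarm, and alarms came
~96 min before the first kid — enough time to prepare birth assistance.
Simulated labor episodes are stereotyped, so the detection rate and lead
spread are tighter than any field deployment would see; the vignette
(`vignettes/kidwatch-methods.Rmd`) explains what the simulator does and
does not emulate.

Published field calibrations can be fed in directly as moments — the
four-window statistics table reproduces its printed selection:

```r
sel <- select_window(data.frame(
  window_min    = c(8, 10, 12, 14),
  labor_mean    = c(69359.59, 77780.06, 102674.63, 107822.07),
  labor_sd      = c(66253.97, 68137.81,  99319.32, 102600.46),
  nonlabor_mean = c(3550.65,   4807.18,   6248.59,   7547.88),
  nonlabor_sd   = c(1781.54,   3144.58,   3222.90,   4149.09)))
sel$chosen
#> [1] 10
tckg_from_moments(4807.18, 3144.58)
#> [1] 14240.92
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/kidwatch`
(subcommands `simulate`, `train`, `calibrate`, `detect`, `evaluate`,
`pipeline`):

```sh
Rscript inst/cli/kidwatch simulate --goats 17 --seed 7 --out herd/
Rscript inst/cli/kidwatch pipeline --seed 7 --out artifacts/
```

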