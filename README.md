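# takeoverstab

Measuring **post-takeover stabilization time** in conditionally automated
(SAE Level 3) driving: after the driver answers a takeover request (TOR) and
resumes manual control, how long until driving behavior and physiology settle?

The package implements the complete measurement chain as a tested pipeline:

* a **synthetic-data generator** emulating a two-study driving-simulator
  design (30 drivers x 4 trials x 4 takeovers + 28 x 2 x 4 = 704 takeover
  attempts; TOR lead time 5 s; driving and eye channels at 50 Hz, skin
  conductance at 4 Hz, heart rate at 1 Hz with missing samples), with
  analytic ground-truth stabilization times for every variable;
* **takeover-onset detection** (steering deviation > 2°, or brake/accelerator
  pedal > 10%, earliest crossing wins);
* **windowed feature extraction** for seven variables — winding (sd of
  steering angle), speed, deceleration, eyes-off-road ratio (E-OFF), pupil
  diameter (PD, baseline-shifted to zero at takeover), heart rate (HR), and
  phasic skin conductance (SC) — over 7 windows starting 0, 2, ..., 12 s
  after takeover onset, with lengths of 2 s (non-overlapping) and 5 s
  (overlapping);
* **electrodermal decomposition** of raw skin conductance into tonic +
  phasic + residual by convex optimization (sparse nonnegative SCR driver
  convolved with a biexponential Bateman kernel, spline tonic, solved by
  accelerated projected gradient);
* the **stabilization statistics**: per variable, one-factor repeated-measures
  ANOVA over the 7 windows with Mauchly's sphericity test and
  Greenhouse–Geisser correction, then all-pairs paired *t*-tests with
  Bonferroni adjustment (21 comparisons), and the criterion

  > a variable is stabilized in the first window that shows no significant
  > difference from all subsequent windows

  (α = 0.05; a variable whose candidates all fail is *not stabilized within
  the horizon*).

## Worked example

```r
library(takeoverstab)

cfg <- default_study_config()                      # 704-attempt two-study design
cfg$studies$n_drivers <- c(8L, 6L)                 # reduced demo: 176 attempts
report <- run_pipeline(cfg, seed = 3)
report[report$window_len_s == 5,
       c("variable", "F", "df1", "df2", "epsilon", "n_complete",
         "stabilized", "stabilized_at_s")]
```

```
       variable       F df1   df2 epsilon n_complete stabilized stabilized_at_s
2  deceleration  187.73 2.5  59.2    0.41         25       TRUE               2
4          eoff   62.05 3.3 584.5    0.56        176       TRUE               2
6            hr  480.40 3.4 564.4    0.57        167      FALSE              NA
8            pd  507.80 2.1 359.7    0.34        176       TRUE               6
10           sc   93.51 2.2 391.7    0.37        176      FALSE              NA
12        speed 4087.72 2.3 397.0    0.38        176       TRUE              10
14      winding 2089.81 3.5 618.9    0.59        176       TRUE               8
```

Reading the 5 s-window rows: every variable shows strong window effects
(Greenhouse–Geisser-corrected F tests, ε well below 1, so the correction is
active). Deceleration and gaze (E-OFF) settle in the window starting 2 s
after takeover — braking and visual reorientation are over almost
immediately. Pupil diameter (cognitive load) settles at 6 s, the
driving-control variables winding and speed at 8–10 s, while heart rate and
phasic skin conductance never pass the criterion inside the 12 s horizon:
the driver's body is still aroused after the vehicle is back under control.
`n_complete` shows the listwise attrition: only ~14% of attempts yield
deceleration data in every window (most drivers brake in one short pulse).

The analysis workflow scripts reproduce this at full scale and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # events, ground truth, example recording
Rscript analysis/02_features.R      # EDA decomposition + feature tables
Rscript analysis/03_stabilization.R # ANOVA / pairwise tests / stabilization
Rscript analysis/04_recovery.R      # parameter-recovery validation
```

## Package layout

```
R/                      generator, IO, features, EDA, statistics, pipeline
analysis/               numbered workflow drivers (simulate -> report)
scripts/acceptance.R    end-to-end reproduction script
tests/testthat/         unit, property and acceptance suites
vignettes/              methods vignette (model, assumptions, design choices)
```
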