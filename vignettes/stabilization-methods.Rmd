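---
title: "Measuring post-takeover stabilization time: model, procedure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring post-takeover stabilization time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When a conditionally automated (SAE Level 3) vehicle asks its driver to take
over, the takeover is not finished the moment the driver touches the wheel.
Steering is erratic for a while, speed dips and recovers, gaze patterns
reorganize, and the autonomic nervous system stays aroused well after the
vehicle is back under control. *Stabilization time* operationalizes "finished"
statistically: a variable has stabilized in the first analysis window that no
longer differs significantly from **any** later window.

`takeoverstab` implements that full measurement chain — windowed feature
extraction from multichannel recordings, electrodermal decomposition,
repeated-measures testing — together with a synthetic-data generator whose
ground-truth stabilization dynamics are known, so every stage of the chain can
be validated by parameter recovery rather than by eyeballing.

## The emulated study design

The default configuration reproduces a two-study driving-simulator design:
30 drivers x 4 trials x 4 takeovers plus 28 drivers x 2 trials x 4 takeovers,
704 takeover attempts in total. The takeover request (TOR) is issued 5 s
before automated driving becomes unavailable; the driver takes over by
turning the steering wheel (onset when the deviation from the angle at the
TOR exceeds 2 degrees) or pressing the brake or accelerator pedal (onset at
10% travel). Driving channels and the eye tracker are sampled at 50 Hz, skin
conductance at 4 Hz, heart rate once per second with missing samples (motion
artifacts). Each episode is recorded from 10 s before takeover onset to 20 s
after, which covers the last analysis window (start 12 s, length 5 s) with
margin and gives the tonic skin-conductance model 30 s of context.

## The seven variables and their windows

Windows start at 0, 2, 4, ..., 12 s after takeover onset (7 windows) and are
half-open `[start, start + length)`; lengths of 2 s (non-overlapping tiling)
and 5 s (overlapping) are analyzed separately. Per window:

* **winding** — sample standard deviation (n−1) of the steering angle;
  missing with fewer than 2 samples. A lateral-instability proxy.
* **speed** — mean speed (km/h).
* **deceleration** — mean deceleration magnitude over samples where
  longitudinal acceleration is negative *while the brake is pressed*; missing
  when no sample qualifies. Under the default generator only ~12% of attempts
  brake gradually enough to yield deceleration data in every window, which
  reproduces the sparsity this variable shows in practice.
* **E-OFF** — fraction of raw gaze samples off the road (no fixation
  filtering).
* **PD** — mean pupil diameter after subtracting the first unmasked pupil
  sample at or after onset, so every attempt starts at zero. Anchoring is
  per-attempt by default (a per-driver anchor is available as an option);
  per-attempt anchoring is the only reading under which "each trace starts at
  zero at the takeover" holds exactly.
* **HR** — mean over unmasked heart-rate samples; a 2 s window often contains
  no valid sample at 1 Hz with realistic missingness, which is why the 2 s
  analysis loses most of its attempts for HR.
* **SC** — mean phasic skin conductance from the convex decomposition below,
  clipped at zero.

A window with no eligible samples is *missing*, never zero.

## Electrodermal decomposition

Raw skin conductance is modelled as a sparse nonnegative driver convolved
with a biexponential (Bateman) response kernel, plus a smooth tonic level,
plus residual noise:

$$\min_{p \ge 0,\, \beta,\, d}\;
\tfrac12\lVert y - Kp - B\beta - Dd\rVert^2
+ \alpha\,\mathbf 1^\top p + \tfrac{\gamma}{2}\lVert\beta\rVert^2$$

with `K` the convolution matrix of the unit-peak kernel
`exp(-t/tau_decay) - exp(-t/tau_rise)` (defaults 2.0 s and 0.7 s), `B` a
cubic B-spline basis with 10 s knot spacing, `D` a linear drift, sparsity
penalty `alpha = 8e-4` and tonic ridge `gamma = 1e-2` — the conventional
defaults of convex EDA decomposition. The smooth coefficients are profiled
out analytically (a ridge solve), leaving a nonnegative quadratic program in
`p` alone that is solved by accelerated projected gradient (FISTA) with a
monotone restart; the closure `y = phasic + tonic + residual` holds exactly
by construction. Missing samples are linearly interpolated when the gap is at
most 2 s; longer gaps split the record into independently decomposed
segments. Decomposition runs on the full episode, not per window, because a
windowed tonic fit would be biased by whatever phasic activity the window
happens to contain.

## The statistical procedure

For one variable and one window length, the attempts-by-windows matrix is
analyzed as a one-factor repeated-measures design with the window start as
the factor and the individual takeover attempt as the unit of repeated
measures. (Driver-level aggregation is available, but attempt-level units are
the default: with ~600 complete attempts the error degrees of freedom land in
the thousands, which is the regime this procedure is meant for.)

1. **Sphericity.** Mauchly's W on the covariance of orthonormal contrasts,
   with the Box chi-square series (second order) for the p-value. The
   Greenhouse–Geisser epsilon is computed from the double-centered covariance,
   `eps = tr(S)^2 / ((k-1) tr(S^2))`, clipped to `[1/(k-1), 1]`.
2. **RM ANOVA.** Classical within-subject decomposition on listwise-complete
   attempts; when Mauchly rejects at alpha = 0.05, both degrees of freedom
   are scaled by epsilon. Both corrected and uncorrected p-values are kept.
3. **Pairwise tests.** Only if the ANOVA rejects: two-sided paired t-tests
   for all 21 window pairs on pairwise-complete attempts, Bonferroni-adjusted
   (`p_adj = min(1, 21 p)`). A pair with fewer than two complete attempts is
   untestable and counts as "no difference observed", with a flag.
4. **Stabilization rule.** The variable is stabilized in the smallest window
   start `w` with no significant pair `(w, w')` for any `w' > w`. The last
   window has no subsequent windows and would stabilize vacuously, so it is
   excluded from the candidate set; a variable for which no candidate
   qualifies is reported as *not stabilized within the horizon*. This
   exclusion is what makes "did not stabilize" a possible outcome at all.
   Maximal runs of windows with no internal significant pair are also
   reported as transient plateaus, because a dip-and-recover profile (speed)
   can stabilize, drift, and stabilize again — the strict rule alone cannot
   express that.

When the ANOVA gate does not reject, no differences between windows are
confirmed and the variable is stabilized from the first window on.

## What the generator emulates — and what it does not

Each channel relaxes from a post-takeover excursion toward its asymptote:
steering as a zero-mean noise process whose *standard deviation* decays
(winding is a windowed sd, so the dynamics must live on the sd, not the
mean); speed as a dip-and-recover profile; a braking pulse with matching
deceleration (or sustained gradual braking for a random 12% of attempts);
gaze as Bernoulli draws from a decaying off-road probability; pupil diameter
and heart rate as step-plus-exponential decays over slow AR(1) physiological
wander and driver-level offsets; skin conductance as tonic drift plus a
Poisson train of small SCRs whose rate decays slowly. Decay constants were
chosen once so that the *ground-truth* stabilization times (the time from
which the noise-free feature profile stays within 5% of its excursion
amplitude of its asymptote) fall in the qualitative order observed in
post-takeover studies: deceleration and gaze settle within ~2 s, pupil
diameter within ~5 s, winding and speed within ~6–9 s, heart rate around
15 s, and the SCR rate so slowly that phasic skin conductance does not
settle inside the 12 s horizon at all. Amplitude-to-noise ratios are set to
plausible sensor scales (steering sd ~1.5–3 degrees, speed dip ~10 km/h,
pupil excursion 0.8 mm over 0.1 mm wander, heart-rate excursion 10 bpm over
~2 bpm noise with 35% sample dropout).

The generator is a validation instrument, not a vehicle model: there is no
traffic, no lane geometry, no closed-loop driver control, and no attempt to
reproduce any particular study's signal traces or F statistics. Passing the
recovery suite therefore shows that the *measurement chain* is correct, not
that real drivers behave like the generator.

## Numerical and design choices

* **Detected vs. true stabilization.** The statistical criterion detects the
  time from which window differences fall below the detection threshold of
  the design (`~ t_crit * sd / sqrt(n)` under Bonferroni), so the detected
  window tracks the ground-truth band time only when effect sizes are
  calibrated to the design size. The recovery suite uses a steering-sd
  excursion of 1.0 degree over a 1.5 degree floor with 200 attempts, for
  which a band-edge difference sits near the detection threshold; recovery is
  asserted within one 2 s grid step, not exactly, because a sequential rule
  at a power boundary legitimately lands one window early or late.
* **Degenerate pairwise tests.** With zero-variance differences the t-test is
  undefined; all-zero differences give p = 1 (no evidence of difference), a
  nonzero constant difference gives p = 0. A literally noise-free dataset
  still never stabilizes under the strict rule (an exponential never reaches
  its asymptote exactly), which is why validation uses small-noise recovery
  rather than the noise-free limit.
* **Solver tolerances.** The EDA program is solved to a relative objective
  change of 1e-8 with a 3000-iteration cap; the design matrices and Lipschitz
  constant are cached per record geometry, so a 704-record study decomposes
  in well under a minute.
* **Problem sizes.** The validation suite runs the full 704-attempt default
  study once per window length, three 200-attempt recovery scenarios and a
  null at 20 seeds each, and 100 random-matrix oracle comparisons; the whole
  suite completes in a few minutes on one core.
* **Seeding.** One root seed; per-event substreams derive from a stable hash
  of (study, driver, trial, takeover index), so any single event can be
  regenerated bit-for-bit without generating the rest.

## Known limitations

* The Bonferroni-adjusted all-pairs scheme controls the family-wise error
  within one variable and window length; across 14 analyses a small number
  of spurious pairwise rejections is expected, which occasionally delays a
  detected stabilization window by one step (visible in the deceleration
  analysis at some seeds, where only ~82 attempts carry data).
* Attempt-level units treat repeated attempts by the same driver as
  exchangeable; the driver-level option trades that assumption for far fewer
  units. A mixed-effects formulation is out of scope.
* The 2 s heart-rate analysis is structurally fragile: at 1 Hz sampling with
  realistic dropout, most attempts lose at least one window, and listwise
  filtering keeps only a minority.

## A minimal session

```{r, eval = FALSE}
library(takeoverstab)

# a reduced design: 8 + 6 drivers
cfg <- default_study_config()
cfg$studies$n_drivers <- c(8L, 6L)
report <- run_pipeline(cfg, seed = 3)
report

# validation: recover a known 8 s stabilization time
rec <- recovery_simulation(recovery_params(8), seeds = 1:20)
rec$hit_rate
```
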