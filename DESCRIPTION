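Package: takeoverstab
Title: Post-Takeover Stabilization Time from Driving and Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how long a driver needs to
    stabilize after taking over from a conditionally automated (SAE Level 3)
    vehicle. Simulates takeover episodes with driving channels (steering,
    speed, acceleration, pedals) and physiological channels (gaze, pupil
    diameter, heart rate, skin conductance) with known ground-truth
    stabilization dynamics; extracts seven windowed variables (winding, speed,
    deceleration, eyes-off-road ratio, pupil diameter, heart rate, phasic skin
    conductance) over 2 s and 5 s analysis windows; decomposes electrodermal
    activity into tonic and phasic components by convex optimization; and
    determines per-variable stabilization time by repeated-measures ANOVA with
    Greenhouse-Geisser correction followed by Bonferroni-adjusted paired
    t-tests between all window pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
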