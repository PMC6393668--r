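Package: scenecue
Title: Cued Auditory-Scene Synthesis and Repetition-Detection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds diotic auditory scenes for object-based attention
    experiments and analyses the resulting behaviour. Two overlapping sound
    streams (quasi-rhythmic speech-like signals and stationary
    environment-like textures) are level-matched, optionally equalised by
    peak-spline envelope transfer, and seeded with seamless one-back
    repetition targets via linear-ramp cross-fading. The package generates
    Posner-style cue-validity trial designs (valid/invalid/neutral cues),
    simulates a signal-detection-theory observer with attention-dependent
    sensitivity and reaction times, and computes the standard behavioural
    analysis: per-condition accuracy, reaction time, d-prime and criterion
    with extreme-rate correction, planned paired contrasts, and
    repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
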