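---
title: "Methods: stimulus construction, observer model and behavioural analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus construction, observer model and behavioural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenecue)
```

## The paradigm this package computes

In object-based auditory attention experiments of the kind this package
supports, a listener hears two complete sound streams — for example a
foreign-language talker and a railway-station ambience — presented
*diotically* (identical signal at both ears, no spatial cues) for 5 s. One
stream may contain a **one-back repetition target**: a 750-ms epoch that is
seamlessly replayed immediately after it first occurs. Before the scene, a
cue points to one stream (valid on 70% of trials, invalid on 20%, absent on
10%), and the listener presses a button as soon as they notice any
repetition. The behavioural signature of attentional weighting is the cue
validity effect: faster, more accurate, more sensitive (d′) detection for
validly cued targets, and costs for invalidly cued ones.

The package implements everything around the human listener: stimulus
synthesis and annotation, trial-design generation, a simulated
signal-detection observer in place of participants, and the standard
analysis producing per-condition accuracy, reaction time, d′ and criterion
with repeated-measures ANOVA and planned contrasts.

## Source preparation

All audio is processed at 44.1 kHz in floating point. Each source is
converted to mono by averaging channels, cut to a fixed duration with a
centre anchor (ties broken toward the earlier start), and normalised to
−23 dB RMS. We interpret the −23 dB level relative to full-scale RMS
(RMS = $10^{-23/20} \approx 0.0708$ on the $[-1,1]$ scale): it is the
simplest testable convention, and close in spirit to −23 LUFS broadcast
practice. WAV files are written as 32-bit float by default so splice and
envelope identities survive a round-trip exactly; a PCM16 export is
available for player compatibility.

## Synthetic sources

Real speech and environmental recordings differ in their low-frequency
envelope statistics: speech carries prominent quasi-rhythmic envelope
modulation at roughly 4–8 Hz (the syllable rate), while ambient textures
are comparatively stationary. The generators emulate exactly these two
statistical signatures, not the semantics:

* `synth_speechlike()` multiplies a pink-noise carrier (Kellet's −3
  dB/octave filter approximation) by a positive modulator built as a
  DC-offset sum of three random-phase sinusoids with frequencies drawn
  uniformly in the modulation band. A raised — rather than rectified — sum
  is used deliberately: rectification would fold the modulator's spectral
  energy up to twice the drawn frequencies, whereas the raised sum keeps
  its spectral lines exactly at the drawn 4–8 Hz frequencies, so
  envelope-recovery and modulation-spectrum tests have an analytic ground
  truth.
* `synth_envlike()` is the same pink-noise texture without modulation.

Both are deterministic given a seed and peak-guarded to 0.9. What these
sources do **not** share with real recordings: harmonic structure,
formants, intelligibility, semantic content, or the heavy-tailed amplitude
statistics of natural scenes. Tests passing on them demonstrate the
correctness of the *pipeline arithmetic* (splicing, enveloping, levels,
design, analysis), not perceptual properties of any natural stimulus set.

## Peak-spline envelopes and envelope transfer

The amplitude envelope is a natural cubic spline through local maxima of
$|x|$ separated by at least 4410 samples (0.1 s at 44.1 kHz). The wide peak
separation is a feature, not a limitation: it deliberately captures only
the coarse temporal dynamics, so that an environment sound given a
speech envelope remains recognisable.

Numerical choices that the peak-spline method forces us to make:

* **Conflict resolution.** When two local maxima are closer than the
  minimum separation, the larger $|x|$ wins, ties going to the earlier
  index (greedy by descending magnitude).
* **Edges.** Virtual anchor knots are placed at the first and last sample
  carrying the local $|x|$ maximum of the edge half-window. A single edge
  sample is usually near a zero-crossing; using it directly drags the
  spline toward zero, and a near-zero knot a few samples from a tall peak
  makes the cubic oscillate violently (we observed excursions of 50×
  full scale before adopting this rule). Anchors are skipped when a real
  peak is already within half a separation of the edge, and the envelope
  is extended as a constant beyond the outermost knots.
* **Positivity floor.** The envelope is clamped below at
  $\varepsilon = 10^{-4} \cdot \max|x|$, guarding the division in envelope
  transfer.

`transfer_envelope()` divides the target by its own envelope and multiplies
by the donor envelope, then re-normalises to the configured level so that
enveloping never changes the overall presentation level. The target's fine
structure is untouched: the envelope-divided output equals the
envelope-divided input up to one positive scalar.

## One-back repetitions and cross-fade splicing

The target construction cuts the source at a (seeded) random sample, takes
the 750 ms immediately preceding the cut, and concatenates original
beginning, repetition, and original end with linear cross-fades of 220
samples (5 ms): in each overlap the down-ramped tail and the up-ramped head
are summed with weights that are linear, run 1→0 and 0→1 inclusive of both
endpoints, and sum to one at every sample — a constant input therefore
passes through a splice exactly unchanged, and there is no click transient.

The splice arithmetic gives `second_onset − first_onset = R − ramp`
(33075 − 220 = 32855 samples) and a pre-trim length of
`source + R − 2·ramp`. Source material is prepared at 5.75 s
(scene + repetition); after embedding, the stream is cut back to exactly
5.000 s. The played scene duration is stated explicitly in the paradigm
while source lengths are not, so we fix the presentation length and let the
sources absorb the inserted epoch. The trim window is chosen as central as
the constraint allows while keeping the whole repetition pair at least
250 ms away from stream onset and offset, so targets never sit flush
against an edge.

The **target onset** recorded in designs and used for scoring is the onset
of the *second* epoch — the earliest moment at which the repetition is
detectable in principle; any response before it is operationally a false
alarm.

A brute-force self-similarity scan (windowed normalised correlation at the
annotated lag) ships as an internal validation utility; it localises all
seeded repetitions to within one ramp of the annotation and is the oracle
used by the tests, not a detection feature.

## Scene assembly

Both streams are prepared to −23 dB RMS and summed sample-wise (the linear
superposition model of natural scenes); mixing at equal RMS amounts to a
0 dB target-to-masker ratio, which is the natural reading of "normalise
both streams, then overlay" with no further gain stated. If the sum clips,
the whole mix is rescaled by one scalar to peak 0.99 — applied to the mix
rather than per stream, so the linear-sum model is preserved. In the
speech-plus-environment mode the environment stream first receives the
speech stream's envelope via `transfer_envelope()`. Diotic presentation is
represented by a mono buffer; `write_trial_wav(channels = 2)` duplicates it
for stereo players.

## Trial designs

`generate_design()` produces exact condition counts — largest-remainder
apportionment of 70/20/10 over the session, never binomial draws — because
the design percentages are stated as exact and deterministic counts make
the validator and the tests sharp. The 70/20/10 split is made exact per
*session* and the trial order is shuffled across the whole session (all
conditions trial-wise intermixed); whether the original split was exact per
block is not stated, and the session-level choice is the weaker assumption.
Target stream is balanced 50/50 *within* each cue condition (again up to
largest remainder), which is the reading under which the published
per-cell analyses are balanced. Fixation (1.0–2.0 s) and cue-to-audio
(0.5–0.75 s; both 1.0–1.5 s in the two-speech variant) intervals are
uniform within their ranges. Each trial carries its own stimulus seed and a
target onset drawn from the embedder's admissible geometry, so designs can
drive either full audio rendering or annotation-only simulation.

## The simulated observer

The analysis of the paradigm is standard yes/no signal detection, so the
generative model is made to match the analysis model exactly — that is what
makes parameter recovery a meaningful end-to-end test. Per trial:

1. With probability `premature_rate · g(condition)` the observer responds
   uniformly before target onset (a false alarm by the task's operational
   definition). `g` scales with how liberal the condition's effective
   criterion is: `g = Φ(−k_cond)/Φ(−k_attended)` with
   `k = d′/2 + c` the absolute evidence cutoff. With the default
   `premature_rate = Φ(−k_attended)`, the per-condition false-alarm
   probability is exactly `Φ(−k)`, the value an equal-variance SDT observer
   with bias `c` produces — so the analysis pipeline recovers both the
   generative d′ and the generative c.
2. Otherwise, evidence `e ~ N(d′_eff, 1)` is drawn with `d′_eff` chosen by
   the cue–target relation (attended / neutral / unattended), and a
   response occurs iff `e > k_eff`.
3. Hits respond at `target_onset + lognormal(rt_mu, rt_sigma)`, shifted
   `rt_attention_shift` earlier when attended and later when invalidly
   cued (facilitation and cost treated symmetrically; a subtractive-only
   shift would leave neutral and invalid reaction times identical in
   expectation, contrary to the cueing literature the paradigm replicates),
   truncated to the stream duration.

The criterion parameters are SDT bias `c` (distance from the `d′/2`
midpoint), not absolute cutoffs: with absolute cutoffs the estimated
`ĉ = k − d′/2` would systematically disagree with the generative
parameter, breaking the generative/analysis correspondence.

Presets `observer_preset("exp1")` (d′ 3.3/2.4/1.9, c 0.55/0.50/0.74) and
`"exp2"` (d′ 3.05/1.98/1.57, c 0.50/0.77/1.15) sit near the published
group means of the two variants of the paradigm; they are simulation
presets, not ground-truth participant values. The lognormal RT parameters
(`rt_mu = log(0.85)`, `rt_sigma = 0.3`, shift 0.1 s) put median hit
latencies in the observed 750–950 ms range. The instruction "accuracy and
speed equally emphasised" has no unique generative translation; the
lognormal family is our choice and nothing downstream depends on it beyond
orderings.

## Scoring and SDT conventions

Each trial is scored **hit** (response in `[target_onset, stream_end]`),
**false alarm** (response before target onset) or **miss**. Conventions the
task statement leaves open, fixed here:

* The false-alarm *rate* denominator is the number of trials in the cell —
  each trial offers exactly one pre-target opportunity.
* The hit-rate denominator excludes trials terminated by a premature
  response: once the observer has responded, the target is never evaluated.
  This convention is also what makes the generative d′ recoverable.
* The hit window ends at stream end; no separate response deadline.
* Extreme rates are corrected by the 1/(2N) rule (0 → 1/(2N),
  1 → 1 − 1/(2N)) before the z-transform; then d′ = z(H) − z(FA) and
  c = −(z(H) + z(FA))/2.
* In the two-stream experiment, each (cue condition × target stream) cell
  uses only its own trials, and neutral cells are split by target stream,
  mirroring the published table layout.

## Inference

Cell means per participant feed a repeated-measures ANOVA (two-way cue
validity × target stream, or one-way cue validity), computed by
`stats::aov()` with subject error strata so each within factor is tested
against its factor-by-subject interaction. No sphericity correction is
applied — the reported layout uses uncorrected degrees of freedom, e.g.
F(2,18) for three conditions and ten participants. Planned contrasts are
two-tailed paired t tests. Participants with an empty cell for a measure
(no hits, hence no RT) are excluded from that measure's inference with a
warning. The test suite checks the ANOVA against a hand-written balanced
means/SS decomposition on random small layouts to 1e-8 relative, and the
F = t² identity on all two-level one-way layouts.

## Problem sizes, determinism, and what the tests show

Every stochastic component takes an explicit seed (`withr::with_seed`, so
the user's RNG state is never disturbed), and the full pipeline
(`run_experiment()`) is reproducible hash-for-hash, writing an MD5 manifest
of every artifact. The default verification sizes are: 100 seeded stimuli
for splice localisation, 10-s realisations for envelope recovery,
~10,000 trials per condition for parameter recovery, and 20 cohorts of
10 participants × 300 trials for the qualitative orderings (accuracy and
d′: valid > neutral > invalid; RT: valid < neutral < invalid) — sizes at
which sampling noise is far below the effects being checked, while a full
run of suite plus acceptance script stays in the minutes range.

Known limitations: the generators do not attempt naturalistic audio; the
observer has no learning, fatigue or drift-diffusion dynamics; criterion
and sensitivity are constant within condition; and the published group
means themselves come from human listeners, so the simulation reproduces
their qualitative structure, not their numerical cell values.
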