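---
title: "Methods: models, measurement and the synthetic colony"
author: "pupcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, measurement and the synthetic colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the measurement
chain, the match and similarity definitions, the statistical models, what
the synthetic colony does and does not emulate, and the numerical choices
that were genuinely open.

## The experiment the pipeline serves

Grey seal pups vocalize from birth to weaning (~19 days). In a playback
design, focal pups hear one of three stimulus sequences daily — a two-call
up step in frequency (`a`), a down step (`b`), or an up-then-down triple
(`ab`) — either while nursing ("feeding" condition) or regardless of their
own behaviour ("varied" condition); a separate cohort receives no
playbacks (controls). The analysis asks two questions. Did pups *use* the
pattern (a hard match rule on relative fundamental-frequency steps,
modelled as a binomial GLMM against age and condition)? And did the
*quality* of their copies improve (a multi-parameter similarity score,
modelled as a Gaussian LMM)?

## Measurement chain

- **High-pass filter, 100 Hz.** A 4th-order Butterworth magnitude response
  applied forward and backward in the frequency domain. Zero phase means
  call onsets are not displaced (important for the 1 s window rule);
  applying the squared magnitude doubles the roll-off to 48 dB/octave.
  The closed form of the bilinear-transform Butterworth response is used
  directly rather than time-domain recursion; on multi-minute sessions
  this is an order of magnitude faster and equals `filtfilt` away from
  the edges.
- **Segmentation.** Short-frame RMS (5 ms frames, 1 ms hop) against a
  threshold of -30 dB relative to the session's 95th-percentile frame RMS;
  supra-threshold runs separated by at most 5 ms are merged (the gap
  rule), runs shorter than 50 ms are dropped. The threshold and minimum
  duration are not fixed by the design; they are package defaults
  chosen to make segmentation deterministic on clean synthetic audio, and
  both are configurable (`spectroParams()`).
- **Features every 5 ms.** F0 by normalized autocorrelation with parabolic
  interpolation over a 60-800 Hz search band; frames whose autocorrelation
  peak quality falls below 0.5 are unvoiced and excluded from averages.
  Among near-maximal autocorrelation peaks (>= 90% of the maximum) the
  smallest lag wins, which suppresses octave errors on fully harmonic
  calls. Peak frequency is the parabolically interpolated argmax of the
  Hamming power spectrum; at the field settings (96 kHz, FFT 2048) the bin
  width is exactly 46.875 Hz. The feature-frame step (5 ms) is independent
  of the display-spectrogram hop (half a window), as when display and
  measurement are done by different tools.
- **Pitch shifting** is a phase-vocoder time stretch (Hann windows, 2048
  samples, quarter-window analysis hop, per-bin phase propagation with
  signed bin frequencies so the modified spectrum stays Hermitian)
  followed by spline resampling back to the original length: duration is
  preserved exactly, every frequency scales by the ratio, harmonics remain
  integer multiples of the shifted fundamental.

## Match rule and its edge cases

A window of k consecutive calls (k = template size) is a match when every
successive onset-to-onset gap is <= 1 s and every successive mean-F0
difference is >= 100 Hz in magnitude with the template's direction signs.
Decisions the rule statement leaves open, resolved as package behaviour
and tested:

- *Window timing* is onset-to-onset: stimulus calls are 0.75 s apart
  onset-to-onset while distinct sequences are >= 1 s apart, so this
  separates sequences as the design intends.
- *Call-level outcome*: all k calls of a matched window are flagged, since
  the model's unit is whether a call was part of a match.
- *Overlaps*: candidate windows are scanned greedily left to right,
  earliest window first, no call reuse; for control pups the templates are
  tried in the fixed order a, b, ab at each start. Equivalence with
  brute-force enumeration whenever windows do not overlap is part of the
  test suite.
- The stimulus peak-frequency step (153 - 119 = 34 Hz) is smaller than the
  100 Hz fundamental-frequency threshold; the two scales are simply not
  the same quantity. The rule is implemented exactly as stated, and the
  synthetic colony plants matches that satisfy the F0 criterion.

## Similarity: Gower + Mantel

Matched response calls in a pup x age-bin cell are described by duration,
mean/min/max F0, mean peak frequency, inter-call interval and sequence
position (the exact parameter list used in the field is not distributed;
this set is a documented stand-in and `sessionSimilarity(vars =)` accepts
any other). Matrix A is the Gower dissimilarity among the response
calls, matrix B the Gower dissimilarity among the template calls each
response is position-aligned to; both use normalization spans from the
pooled response + template table so they are commensurate. The Mantel
statistic (Pearson correlation over upper-triangle entries, one-sided
permutation test with joint row/column permutation) is the similarity
score. A Mantel test needs two matrices over one object set, and the
position-alignment construction is the minimal way to get one from a
template and its responses using only quantities the match rule already
defines; it is a package design choice.

Numerical details: Gower handles missing entries pairwise (first calls of
a window have no inter-call interval), drops zero-range variables with a
warning, and treats a span at rounding-noise level (<= 1e-9 relative) as
zero — otherwise a 2e-16 floating-point residue can masquerade as a real
variable and cap self-similarity below 1. An all-constant table yields an
all-zero matrix (identical objects). Mantel p is (1 + exceedances) /
(1 + permutations), so it can never be exactly zero and is super-uniform
under the null at resolution 1/(n_perm + 1).

## Mixed models

The match GLMM is `is_match ~ age_days * condition + (1 | pup_id)` with a
logistic link, fitted by maximum likelihood with the Laplace approximation;
age is continuous in days, condition reference level is control. The
similarity LMM is `r ~ age_bin * condition + sex + (1 | pup_id)` by REML,
with the age bin entered as ordered numeric 0-3; these estimators are the
field-standard defaults. Wald 95% intervals and
normal-approximation p-values are reported, and every estimate is also
exponentiated — for the Gaussian model this is kept for presentation
parity with the matching model even though an odds-ratio reading is
strained there. Sex enters only the LMM, matching the stated model
structures. Complete separation is detected by diverging estimates or
standard errors and aborts the fit with a diagnostic rather than returning
meaningless intervals.

## The synthetic colony

The generator exists so that every downstream stage has a testable ground
truth. Its defaults are the experiment's developmental conditions:

- Calls come in sequences of the pup's template size (controls: pairs).
  With an age-dependent probability the sequence is planted as a match
  (>= 115 Hz F0 steps in the template's directions, from a low anchor so
  every call stays inside the pup band); otherwise successive F0 steps are
  capped well below 100 Hz. Sequences are separated by enough silence that
  match windows cannot span sequences.
- The match probability is linear on the log-odds scale in age. The
  configured probabilities are anchored to the *first and last age bins*
  (means over days 0-4 and 15-19): a chance-match level of about 20% for
  pups aged 0 to 4 days is a statement about a bin mean, not about day 0,
  and the binned fractions are what the downstream analysis consumes. Anchors: control
  20% -> 2%; varied reaching 35%; feeding = varied / 1.5; weaning/birth
  ratio 2 for both playback conditions. The intercept and slope are solved
  numerically from the two bin means.
- Control chance matches are planted as two-call sequences with a random
  up/down direction, scored later against any template.
- For varied pups the spread of planted-match features (F0 anchor and
  step, duration, inter-call interval) shrinks linearly with age; the
  shrinkage rate is calibrated so that the measured Mantel r rises by the
  configured 25% from the first to the last age bin under the default
  roster (8 varied pups). That calibration constant (1.45 x gain/0.25) is
  part of the generator, fixed once; the realized gain at the defaults is
  23-26% across seeds.
- `calls_per_day` defaults to 25, consistent with per-pup recording
  totals of ~431 calls over ~19 days. Every simulation consumes one master seed;
  identical inputs give byte-identical annotations and audio.

What the generator does **not** emulate: background noise (wind, surf,
other animals), adult or seabird calls, amplitude variation with distance,
overlapping callers, or pitch tracking under low SNR. Passing round trips
therefore validate the pipeline's logic and numerics on clean signals —
the stated contract — not robustness to field recording conditions.

## Problem sizes and statistical checks

Colony round-trip checks run at 8 kHz audio with 256-point analysis
windows (32 ms): all synthetic energy lies below 1.2 kHz, so nothing about
the analysis changes except cost, and a full two-colony round trip
(~20 000 calls) fits in minutes. The 96 kHz / FFT 2048 field settings are
used wherever the spectrographic values themselves are asserted (bin
width, stimulus peak frequencies). Since all calls of a sequence share one
match outcome, the binomial unit for round-trip tolerances is the
sequence, not the call; tolerances are three binomial standard deviations
on sequence counts.

Parameter-recovery simulations for the GLMM draw call-level outcomes
directly from the logistic model (uniform ages 0-19, normal pup
intercepts, SD 0.3) at the default effect sizes (`matchModelDefaults()`);
the trajectory-based colony and the coefficient-based simulator are
deliberately two generator modes — the log-odds-linear trajectories
reproduce the target *fractions*, and the logistic-model simulation
reproduces the target *coefficients*; no single generator can do both at
once, because those fractions and coefficients are not mutually
consistent on the logistic scale.

## Known limitations

- The segmentation threshold assumes clean audio; on real recordings the
  -30 dB relative criterion would track noise floors, not calls.
- The feature set for similarity is a stand-in for the exact parameter
  list used in the field, though any list can be supplied.
- Wald intervals on 48 pup-bin observations are mildly anti-conservative;
  the power checks in the test suite account for this empirically.
- The formant estimator (LPC root picking) is provided as an optional
  feature and is tested on constructed resonators only; formant-based
  results are out of the package's validated scope.
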