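# pupcall

Analysis pipeline for playback experiments on vocal production learning in
grey seal (*Halichoerus grypus*) pups.

Grey seal pups produce a distinctive tonal, harmonic call during their
first 2-3 weeks of life. A field playback experiment can test whether the
acoustic environment shapes this call: broadcast short sequences of
pitch-shifted pup calls to focal pups, record their vocalizations daily
from birth to weaning, and ask whether the pups come to reproduce the
frequency-step pattern they heard. `pupcall` implements the full
computational side of such an experiment, plus a synthetic colony
simulator so every stage can be validated end to end without field
recordings (none are publicly deposited).

## What the package computes

**Stimuli.** Playback sequences are two- or three-call patterns built from
one source call: an up step (`a`, 119 -> 153 Hz average peak frequency), a
down step (`b`, 153 -> 119 Hz), and an up-then-down triple (`ab`), each
call 0.7 s long with 0.05 s inter-call intervals, played in blocks of 50
with 1 s between sequences. The pitch shifter is duration-preserving
(phase-vocoder time stretch followed by resampling), so the harmonic stack
scales as a whole: `synthesizeCall()`, `pitchShift()`, `buildStimulus()`,
`buildBlock()`.

**Measurement.** Recordings are high-pass filtered at 100 Hz (zero-phase
Butterworth), segmented into calls by an energy criterion with the 5 ms
gap rule (silent breaks up to 5 ms stay within one call), and measured
every 5 ms: fundamental frequency F0 by normalized autocorrelation with
parabolic interpolation (60-800 Hz search band), peak frequency as the
interpolated argmax of the Hamming power spectrum (FFT 2048 at 96 kHz =
46.875 Hz bins, displayed as 46.87): `highpassFilter()`, `segmentCalls()`,
`extractFeatures()`, `spectrogramMatrix()`, and optionally
`estimateFormants()`.

**Matching.** A pup "matches" its stimulus when 2 or 3 consecutive calls
(within 1 s of each other, onset to onset) step in mean F0 by at least
100 Hz per step, with the signs of the template's direction pattern.
Control pups, which heard no playbacks, are scored against all three
templates, giving the chance-match rate: `findMatches()`,
`controlChanceMatches()`, `buildMatchTable()`.

**Similarity.** How *good* a match is, is scored over multiple parameters
(duration, mean/min/max F0, mean peak frequency, inter-call interval,
sequence position): Gower dissimilarity matrices are computed among the
matched response calls and among the template calls they align to, and the
Mantel correlation r between the two matrices (with a one-sided
permutation test) is the similarity score per pup and age bin (0-4, 5-9,
10-14, 15-19 days): `gowerMatrix()`, `mantelTest()`,
`sessionSimilarity()`.

**Inference.** Two mixed-effects models with a random intercept per pup:
a binomial GLMM of the call-level match outcome on age x condition
(logistic link, Laplace ML), and a Gaussian LMM of the Mantel r on binned
age x condition plus sex (REML). Estimates are exponentiated with Wald 95%
CIs: `fitMatchGlmm()`, `fitSimilarityLmm()`, `summarizeFits()`.

**Synthetic colony.** `simulateColony()` generates call annotations (and,
via `renderSession()`/`writeColony()`, audio) whose match probability
follows a log-odds-linear trajectory in age with the experiment's
developmental structure: control chance matches fall from ~20% (ages 0-4) to
~2% at weaning, varied-condition pups reach ~35% at weaning, varied pups
match 1.5x as often as feeding pups, and playback pups double their rate
from birth to weaning; varied-condition matches also become more
stereotyped with age (+25% Mantel r from first to last bin).
`runExperiment()` chains everything and writes every intermediate table.

## Worked example

```r
library(pupcall)

# the stimulus pair: synthesize the 119 Hz source, shift to 153 Hz
src <- synthesizeCall(119, 0.7, rate = 96000)
extractFeatures(src, spectroParams())
#> Call features: 0.700 s, mean F0 119.3 Hz [119.0-120.8], mean peak 119.3 Hz (138/140 voiced frames)
extractFeatures(pitchShift(src, 153/119), spectroParams())
#> Call features: 0.700 s, mean F0 153.4 Hz [152.9-154.2], mean peak 154.0 Hz (139/140 voiced frames)

# a synthetic colony through the pipeline (ground-truth features path)
cfg <- devConfig(calls_per_day = 40, rate = 8000, seed = 20211025)
colony <- simulateColony(pupRoster(), cfg)
colony
#> Synthetic pup colony: 12 pups, 9560 calls, 17.4% planted matches
feats <- analyzeColony(colony, from_annotations = TRUE)
matches <- buildMatchTable(feats, colony$pups)
matches$age_bin <- findInterval(matches$age_days, c(0, 5, 10, 15)) - 1
xtabs(is_match ~ condition + age_bin,
      aggregate(is_match ~ condition + age_bin, matches, mean))
#>          age_bin
#> condition     0     1     2     3
#>   control 0.218 0.082 0.030 0.015
#>   feeding 0.127 0.167 0.187 0.224
#>   varied  0.216 0.226 0.257 0.337
fitMatchGlmm(matches)
#> Binomial GLMM of call matching: 9560 calls, 12 pups, pup variance 0.005
#>                       term exp_estimate ci_lower ci_upper   p_value
#>                (Intercept)       0.3891   0.3171   0.4774 1.450e-19
#>                   age_days       0.8159   0.7923   0.8401 3.114e-42
#>           conditionfeeding       0.3702   0.2778   0.4933 1.181e-11
#>            conditionvaried       0.6142   0.4690   0.8044 3.976e-04
#>  age_days:conditionfeeding       1.2755   1.2336   1.3188 2.693e-46
#>   age_days:conditionvaried       1.2740   1.2333   1.3160 1.659e-48
```

The match-rate table shows the simulated developmental pattern: control chance
matches decay from 22% to 1.5% while playback pups climb, the varied
condition ending near 35%. In the model, odds ratios below 1 for `age_days`
(control decline) and above 1 for the `age x condition` interactions
(playback pups gain matches with age relative to controls) carry the
experiment's conclusion. Replace `from_annotations = TRUE` with the default
audio path to run the same analysis through synthesis, filtering,
segmentation and frame-level measurement (minutes instead of seconds).

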