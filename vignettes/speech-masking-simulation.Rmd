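---
title: "Simulating speech-on-speech masking experiments with srtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating speech-on-speech masking experiments with srtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtsim)
```

## What the package simulates

`srtsim` is a desk-scale simulation of a closed-set competing-talker
listening experiment. A male target talker produces five-word matrix
sentences (Name–Verb–Number–Color–Object, 10 monosyllabic words per
category, the Name fixed as the listener's cue word); 1, 2 or 4 masker
talkers produce interfering sentences from the same closed set under a
word-exclusion rule. Six target–masker sex-cue conditions (TD, TS, TDD, TSS,
TSD, TSSDD; S = same-sex, D = different-sex masker) are each run with
intelligible (time-forward) and unintelligible (per-word time-reversed)
maskers. A 1-up/1-down adaptive staircase on the both-keywords-correct
event estimates the speech recognition threshold (SRT), and derived
contrasts quantify masking release (MR) and the multi-masker penalty (MMP).

Two pieces of the real experiment cannot be redistributed: the recorded
word corpus and the human listeners. Both are replaced by explicit,
seeded models — a parametric word synthesizer and logistic psychometric
listeners — so every result in the package is computable, reproducible and
testable. This vignette documents those models, their parameters, the
numerical conventions, and what conclusions the simulation does and does
not support.

## The synthetic word corpus

Each word token is a voiced harmonic complex:

* **Source**: the first $K$ harmonics of the talker's fundamental,
  $K = \min(20, \lfloor 5\,\mathrm{kHz}/F_0 \rfloor)$ — enough bandwidth to
  be speech-like at a 22 050 Hz sampling rate while staying cheap to
  resynthesize.
* **Talkers**: target male $F_0 = 106$ Hz; masker males 97 and 128 Hz;
  masker females 157 and 190 Hz. $F_0$ is the primary sex cue in the
  stimulus set, exactly as in the experimental design being emulated.
* **Per-word F0 jitter**: ±3 % (seeded, uniform) around the talker mean, so
  the talker *mean* F0 is a meaningful summary rather than a constant.
* **Word identity**: a seeded spectral envelope of three formant-like
  Gaussian resonances (centers drawn in 300–900, 1000–2200, 2300–3400 Hz)
  plus a gentle $-3$ dB/octave-style tilt, evaluated at the harmonic
  frequencies. The envelope seed is shared across talkers for the same
  (category, word), so the "same word" spoken by different talkers is
  spectrally related, as with real recordings. Random harmonic phases are
  per token.
* **Amplitude envelope**: a raised-cosine attack over the first 4 % of the
  word (≈ 12–20 ms), then exponential decay to 30 % of peak, with a short
  raised-cosine offset ramp (2.5 %). The asymmetry is deliberate:
  a stressed monosyllable rises fast and decays slowly, and it is exactly
  this asymmetry that makes *per-word time reversal* acoustically
  meaningful. With a symmetric envelope, a reversed word would have the
  same smoothed level trajectory as the forward word and the glimpsing
  contrast between forward and reversed maskers — a centerpiece of the
  design — would vanish by construction.
* **Durations**: each (category, word) has a base duration drawn uniformly
  from 0.3–0.5 s, shared across talkers with ±10 % seeded per-talker
  jitter, so word durations "vary slightly" across categories and talkers.
  The range itself is a modeling choice (real monosyllable durations in
  this style of test cluster in a few hundred milliseconds); no published
  duration statistics were available to fit.
* **Level**: every token is normalized to a long-term RMS of 0.05 linear
  full scale, leaving headroom for a target plus four maskers without
  clipping. All level handling downstream is dimensionless; the
  experiment's fixed presentation level is represented by the single
  `level_rms` constant, with no SPL calibration in software.

Determinism: every token's seed is derived by a stable string hash from the
corpus master seed and the token's identity, so any token can be
regenerated in isolation, bit-identically, on any platform.

### What the generator does *not* emulate

No phonetic structure, no consonant–vowel dynamics, no coarticulation, no
amplitude modulation inside a word beyond the attack–decay envelope, no
prosody across the sentence. Consequently the *absolute* glimpsing numbers
and simulated SRTs are not comparable to human data; only orderings and
arithmetic identities are. Tests in this package therefore assert
directions and exact bookkeeping, never human effect magnitudes.

## Stimulus assembly and mixing

Sentences are concatenations of five tokens in fixed category order, with
0-based half-open sample boundaries recorded for each word. Reversed
maskers reverse each word's samples individually *before* any further
processing; word order is preserved.

Masker sentences are duration-matched to the target by uniform
time-scaling of the whole sentence: each token is *resynthesized* at its
scaled length from its stored harmonic parameters, which leaves F0 and the
spectral envelope untouched — pitch preservation by construction rather
than by a time-scale-modification algorithm. Rounding is distributed over
words so the match is exact to the sample. Imported (non-parametric) audio
cannot be time-scaled this way; `match_duration()` refuses rather than
silently resampling, since naive resampling would shift pitch and corrupt
the sex cue.

Mixing follows the level policy of the emulated procedure: maskers are
summed sample-wise, the sum is scaled so the long-term target-to-combined-
masker RMS ratio equals the commanded SNR, and the final mixture is scaled
to the fixed overall RMS. SNR is defined over the entire sentence
(long-term RMS), not framewise. Commanded and measured SNR agree to
floating-point precision; the package's acceptance checks use a 0.01 dB
tolerance.

For conditions with a free same-sex slot (TS, TD, TSD) the specific masker
talker is drawn uniformly and held fixed within a staircase run,
mirroring a test block with a stable masker voice; TSS/TDD/TSSDD use both
or all four masker talkers. Word draws are fresh on every trial, with the
per-category exclusion applied sequentially (target first, then each
masker against everything already drawn) — the Name category included, so
a masker never repeats the cue word.

## The glimpsing analysis

Both the target and the combined masker are tracked with a sliding RMS
window of 300 ms advanced in 20 ms hops — the integration time of a
volume-unit meter, which is what the analysis emulates. Only full,
left-aligned windows are used (frame $i$ covers samples $[iH, iH+W)$),
giving $\lfloor (L-W)/H \rfloor + 1$ frames; partial end windows are
dropped to avoid edge bias. A frame is a **glimpse** when the target RMS
*strictly* exceeds the combined-masker RMS; ties are not glimpses. The
**mean glimpsing SNR** averages the framewise dB ratios over glimpsed
frames only. Averaging is done in dB (not linear power): the quantity
being summarized is "the SNR during glimpsing moments", which is a dB
quantity frame by frame. When no frame is glimpsed the result is `NA` —
an explicit undefined marker, never a sentinel value. The computation is
single-band (broadband); a multiband spectro-temporal variant is out of
scope.

Because masker words start quiet and end loud once reversed (the mirror
of the attack–decay envelope), and because target and masker word slots
are approximately aligned after duration matching, reversed maskers leave
the target's word onsets less masked. The package verifies this as a
directional property — mean glimpsing SNR with reversed maskers ≥ forward,
averaged over 100 seeded trials per condition — rather than as a fixed
magnitude, which would be a property of the synthetic envelope shape, not
of the method.

## Simulated listeners

Single-keyword identification follows a logistic psychometric function
with guess rate $\gamma = 0.1$ (closed set of 10 alternatives) and lapse
rate $\lambda = 0$ by default:

$$p_\text{kw}(x) = \gamma + (1-\gamma-\lambda)\,
  \sigma\!\left(\frac{x - \theta}{s}\right)$$

with threshold $\theta$ (dB SNR) and spread $s$ (dB). The tracked event is
*both* keywords correct, modeled as independent: $p_\text{both} =
p_\text{kw}^2$, floor $0.01$. Independence is the simplest defensible
choice; human keyword errors are plausibly correlated within trial, which
would raise the floor and flatten the tracked function slightly, but no
trial-level human data exist to fit a correlation. The analytic inverse
`snr_at_p_both()` gives the ground-truth 50 % point of the tracked
function in closed form, which is what the staircase is expected to
recover — and, notably, is *not* the per-keyword threshold $\theta$.

`glimpse_linked_profile()` ties $\theta$ to the condition acoustics
($\theta = \theta_0 - g \cdot$ mean glimpsing SNR at 0 dB), so a simulated
experiment reproduces the qualitative ordering "reversed maskers → easier"
from the stimulus physics alone. It is a demonstration device — the
coupling gain is not fitted to human data, and the resulting
between-condition spreads are much smaller than human effects.

## The adaptive staircase

The procedure is implemented exactly as specified for the emulated test:
initial SNR +10 dB; correct → SNR − step, incorrect → SNR + step; step
4 dB, dropping to 2 dB for every step commanded after the second reversal;
a run is always 20 trials (validity is defined at 20 trials and no other
stopping rule is given); a **reversal** is logged at the trial whose
commanded direction differs from the previous one, and the reversal SNR is
the SNR presented at that trial; the run SRT is the mean of the last six
reversal SNRs; runs with fewer than six reversals in 20 trials are
discarded and rerun; two (configurable to three) valid runs are averaged
per condition. The reversal convention is pinned by a hand-simulated
trace: the deterministic responder "correct iff SNR ≥ 0" must produce the
trial sequence 10, 6, 2, −2, 2, 0, −2, 0, … and an SRT of exactly
−1.0 dB, and the implementation is additionally cross-checked against an
independently coded simulator on random responders.

SNR clamping bounds (−60, +40 dB) are pure software plumbing — humans had
no such bounds — so clamped trials are flagged and reported but a clamped
run is not auto-discarded.

## Derived contrasts

All contrast orientations are fixed so published signs are reproduced:
MR(intelligibility) = forward − reversed; MR(sex cue) = same-sex −
different-sex; MMP = more − fewer maskers. TMR accounting adds
$10\log_{10}(n)$ per condition, so every doubling contrast gains exactly
$10\log_{10} 2 \approx 3.01$ dB over its SNR version — an identity the
test suite asserts on random tables. Group means follow the 1/2/4-talker
convention (1 = mean of TS, TD; 2 = mean of TDD, TSD, TSS; 4 = TSSDD).
Inferential statistics (repeated-measures ANOVA, post hoc tests) are
deliberately excluded: they are standard library calls, not part of this
pipeline's contribution; the package reports descriptive means and
standard errors only, and flags SE as `NA` rather than fabricating it for
a single listener.

## Numerical choices and problem sizes

* Sample indexing of word boundaries is 0-based half-open; word indices
  are 1-based (R convention).
* Seeds are derived by a DJB2-style string hash modulo $2^{31}-1$, so all
  derived seeds are valid 32-bit R seeds on any platform.
* Unit tests run most audio at 8 kHz — the code path is rate-agnostic —
  while the directional glimpsing checks and the acceptance script use the
  default 22 050 Hz corpus. Simulation sizes in the shipped checks
  (100–200 staircase replicates per profile, 50–100 glimpsing trials per
  condition, 1000 exclusion-audit trials per condition) were chosen to
  make binomial/SE noise small relative to the asserted margins.
* `NA` is the only undefined marker (no sentinel numbers); degenerate
  inputs (zero-energy masker sums, too-short signals, non-parametric
  time-scaling) raise errors rather than guessing.

## Known limitations

* Absolute simulated SRTs, MR and MMP magnitudes reflect the synthetic
  envelope model and the illustrative glimpse–threshold coupling, not
  human psychoacoustics; treat them as qualitative.
* The broadband glimpsing metric ignores spectral release; a multiband
  variant would glimpse in time–frequency tiles.
* Keyword independence overstates how often exactly one keyword is
  correct relative to human data.
* Informational masking (lexical interference) has no representation in
  the listener model beyond what the glimpse coupling inherits from the
  stimulus acoustics; only the energetic/envelope route is simulated
  mechanistically.
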