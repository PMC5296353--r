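---
title: "Modeling perceived emotion from timbre descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling perceived emotion from timbre descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timbral)
```

## The problem

Short, isolated instrument tones carry emotional tone: listeners rate a
bright trumpet note and a dull low piano note very differently on scales of
valence (negative--positive), tension arousal (relaxed--tense) and energy
arousal (tired--awake). The original listening study behind this package
collected 9-point ratings of 137 orchestral samples (pitch class D#,
octaves 1--7, four instrument families) from 40 listeners, summarized each
tone by 23 signal descriptors, and asked how well the mean ratings can be
predicted from the descriptors by (a) a linear partial least-squares
regression (PLSR) and (b) a small feedforward neural network.

Neither the commercial audio nor the participant ratings are
redistributable, so this package reimplements the entire computational
chain and validates it on synthetic data whose structure mirrors the
study design: a tone generator spanning the same registers and families,
and a rating simulator with a planted, known descriptor-to-emotion
mapping. Everything downstream of the audio — descriptor extraction,
collinearity pruning, both model families, cross-validation, and the
model-comparison arithmetic — is the same code a user would point at real
recordings and ratings.

## The descriptor set

Descriptors are computed in three stages.

**Input representations.** The temporal energy envelope is the modulus of
the analytic signal (Hilbert transform via the FFT), low-pass filtered
with a causal third-order Butterworth filter at 5 Hz (causal filtering
delays and smooths the onset by a few tens of milliseconds — consistently
across stimuli, so between-stimulus contrasts are preserved; the filter
settles within about half a second). The spectral
representation is an STFT with a 23.2 ms Hamming window and 5.8 ms hop
(1024 / 256 samples at 44.1 kHz), with bin centers mapped to the ERB-rate
scale `21.4 * log10(4.37 * f / 1000 + 1)`, an auditory frequency axis that
compresses high frequencies the way the cochlea does.

**Frame-level descriptors.** Per STFT frame, on the ERB axis: the four
normalized spectral moments (centroid, spread, skewness, kurtosis), the
regression slope of the sum-normalized magnitudes, the spectral decrease
(amplitude-weighted average slope from the first bin), the 95%-energy
rolloff, flatness (geometric/arithmetic mean ratio) and crest
(max/arithmetic mean). Spectral variation is one minus the normalized
correlation of successive frames. From the envelope: the attack segment is
found by the weakest-effort method — thresholds at 10%..90% of the
envelope maximum, first-crossing times, and an attack bounded by the
crossings whose inter-threshold "efforts" stay within 3 times the mean
effort — giving the log10 attack time, the mean attack slope, and the
temporal centroid of the whole envelope.

**Summaries.** Each spectral time series is summarized by its median and
interquartile range over the non-silent frames (frames whose peak
magnitude is at least -60 dB relative to the loudest frame; without this
floor the fade-out tail dominates both statistics). The centroid median is
reported as log10, and attack time as log10 seconds, the scales on which
they enter the models. 10 series x 2 summaries + 3 temporal scalars = 23.

Conventions worth stating explicitly, because oracles in the test suite
assert them: quantiles interpolate linearly between order statistics
(type 7); the spectral slope is computed on sum-normalized magnitudes, so
it is gain-invariant; rolloff uses squared magnitudes ("energy") while all
other spectral statistics use magnitudes; the DC bin is retained; a
single-bin frame returns slope and decrease of 0 and skewness/kurtosis of
0 by convention, flagged.

## The synthetic stimulus generator

Each tone is additive synthesis at 44.1 kHz, 500 ms, with a raised-cosine
fade over the final 50 ms: harmonic partials filling the band to Nyquist
with power-law amplitudes `k^-slope`, a linear attack ramp followed by an
exponential decay, high-passed Gaussian noise placed above the played
pitch (breath/bow/mallet analog), and five micro-dynamic processes —
spectral-tilt drift, per-partial shimmer, noise-level modulation,
cents-scale pitch instability (with deeper vibrato for strings), and a
static resonance bump (a formant analog at a random center frequency).
Brass/woodwind/string/percussion archetypes set parameter ranges (attack
times from 3 ms mallet hits to 150 ms weak brass attacks; impulsive decay
for percussion and pizzicato; flutter AM), and a seeded per-stimulus
jitter gives each "instrument" its own noise level, modulation depths and
formant.

The point of this design is not instrument realism — the non-goal section
of the package is explicit about that — but *covariance realism*: in real
orchestral tones the brightness-linked descriptors (centroid, slope,
spread, rolloff) move together across registers, the tail-shape pair
(skewness, kurtosis) moves together, and each descriptor's median and IQR
have partly independent drivers. The generator reproduces that structure:
on the default 137-tone set the pruning step (below) removes exactly six
descriptors, as in the original analysis. Four of the six match the
original removals (spectral slope median and IQR, rolloff median, kurtosis
median); the other two differ (variation IQR and decrease IQR here,
versus spread median and kurtosis IQR originally) because synthetic tones
couple the spectrotemporal variability measures more tightly than real
recordings do. This is a documented property of the emulation, not a
defect: the count, the cluster structure, and the decision rule are what
the downstream analysis depends on.

What passing tests on this generator do **not** show: that the descriptor
-> emotion mappings recovered from synthetic ratings say anything about
human listeners, or that the specific retained set would be identical on
real recordings. They show that the pipeline recovers known structure
when it exists, at realistic noise levels and sample sizes.

## Rating simulation

Ratings are 9-point integers. A planted effect maps range-normalized
stimulus features linearly to a latent mean in [0, 1] (clamped), each
participant gets a Gaussian random intercept, each rating Gaussian noise,
and `rating = clamp(round(1 + 8 * latent), 1, 9)`. The defaults (noise SD
0.05, intercept SD 0.05, 40 raters) give Cronbach's alpha in the
high-reliability range the study reported (0.90--0.99). The generator has
no claim to psychological realism — the original study collected real
data; this module exists so that recovery can be tested against ground
truth.

## Collinearity pruning and adequacy

The 137 x 23 descriptor table is correlated (Pearson), clustered with
average linkage on the distance `1 - |r|` (absolute value, so
anticorrelated duplicates also merge early), and pruned: while any
retained pair has `|r| > 0.905`, remove the lower-priority member of the
strongest such pair. The priority list prefers the centroid and skewness
medians over their habitual collinear partners and breaks remaining ties
alphabetically, making builds deterministic. Pruning is idempotent. The
Kaiser-Meyer-Olkin index of the retained block (computed from anti-image
partial correlations) is reported alongside.

## PLS regression

Single-response PLS (NIPALS-style deflation), predictors z-scored
internally — the eigenvalue-1 component-selection rule is only meaningful
on standardized variables — and the response centered. The number of
components is the count of leading components whose score variance is at
least 1 (minimum one). Fit is reported as R², predictive power as
`Q² = 1 - PRESS/TSS` with PRESS accumulated over five seeded random folds
and TSS about the whole-sample mean (a per-training-fold baseline is
available via a flag), and RMSE on the training fit. Per-component partial
R² is incremental explained variance in fitting order.

Descriptor importance for rank tables scales each component's weight
vector by its response relevance (response loading times score SD) and
takes each descriptor's largest absolute scaled weight. Multi-component
loading tables are conventionally read this way — dominant-component
coordinates shrink with component relevance — and the convention is
deliberately documented here because raw per-component loadings from
later, noise-amplified components would otherwise dominate rankings.

## The network

A 17-3-1 multilayer perceptron: sigmoid hidden and output units, targets
on [0, 1] (ratings mapped by `(rating - 1)/8`; forced by the error
magnitudes being on a unit scale), weights and biases initialized
uniformly in ±0.05. Training is full-batch backpropagation: per-pattern
gradient deltas are accumulated over an epoch and the summed delta applied
once, so presentation order is irrelevant (asserted in the tests). The
default learning rate is 0.2 with no momentum; a divergence guard stops
training if the MSE explodes. Valence and energy models train for 700
epochs, tension for 1000; on a noiseless planted mapping with 108 training
stimuli the network reaches a training MSE below 0.008 within 1000 epochs
at the default rate.

Cross-validation partitions 135 of 137 stimuli into five folds of 27; the
two left-over stimuli join every test set (29 test items per fold, 108
training items). Per-fold test RMSE and its mean are the headline
performance numbers. For comparison with the PLS report, R² is the
training-set R² averaged over folds and Q² uses the held-out predictions
of the five disjoint folds (each stimulus predicted exactly once; the
shared extras are excluded from PRESS).

Feature contributions follow the connection-weight method: contribution
of input i is `sum_j W1[i,j] / sum_i' |W1[i',j]| * W2[j]`, expressed as a
signed percentage of the total absolute contribution and averaged across
the five fold models. The per-hidden-unit absolute-sum normalization is
the documented default; contributions are re-expressed as percentages
after averaging.

## The recovery experiment

`recovery_experiment()` is the package's strongest validation: a known
linear effect of three descriptors is planted on the unit scale (noise SD
0.05 per stimulus), and both model families must place exactly those
three at the top of their importance rankings, replicated across 20
seeds. The planted trio — crest median, flatness median, temporal
centroid — takes one descriptor from each class (spectral, noisiness,
temporal) with low mutual correlation. One subtlety is worth recording:
because descriptors are correlated, a planted effect induces indirect
"shadow" correlations on non-planted descriptors, and a descriptor like
attack slope, which correlates with both the crest and the temporal
centroid, can accumulate shadows from several planted effects at once.
The default coefficient signs are chosen so those shadows cancel rather
than add; an experiment whose planted effects are not linearly
identifiable would test nothing. The nonlinear network tolerates either
choice.

## Model comparison

Percent improvement of the network over the PLS model is
`round(100 * (nn - plsr) / plsr)` with halves rounded away from zero —
the convention that reproduces all nine published comparison integers
from the published metric values, which ship with the package as a CSV
input. Rank tables list the top six descriptors per dimension and method
by absolute importance, ties broken by canonical descriptor order.

## Numerical choices and degenerate inputs

RMSE and the R² baseline use the population variance convention. An
all-zero clip yields a zero envelope (no error) but descriptor extraction
on silence errors. A pathological envelope with degenerate crossings
falls back to direct 10%/90% crossings, flagged. Range normalization
stores training minima/maxima so held-out folds can be mapped with
training statistics; values outside [0, 1] are allowed there. Reported
WAV audio is 16-bit PCM; all processing is double precision.

## Problem sizes

The test suite runs most model-level checks on a 42-stimulus subset and a
reduced-epoch network; the end-to-end checks use the full 137-stimulus
set, 20-seed recovery replication, and the 700/1000-epoch schedules, the
same sizes the acceptance script uses. These sizes were chosen so the
full validation completes comfortably on a laptop-class single core.

## Known limitations

- The generator's collinearity structure, while deliberately shaped, is
  not identical to the original stimulus set's (two of six pruned
  descriptors differ), so retained-set membership downstream differs
  accordingly.
- The network is trained exactly as specified (full-batch, fixed epochs,
  no early stopping or regularization); it can underfit hard synthetic
  mappings that a longer schedule would fit. Fidelity to the paradigm is
  preferred over training efficiency.
- Published loading values use an unstated scaling; only sign patterns
  and ranks are comparable, and this package's importance convention is
  its own, documented above.
- Linear mixed-effects analyses of the rating data (register, family,
  training effects) are out of scope; standard tools cover them.
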