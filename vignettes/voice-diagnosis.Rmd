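---
title: "Frame-level voice diagnosis of Sasang constitution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-level voice diagnosis of Sasang constitution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvoice)
```

## The diagnostic problem

Sasang constitutional medicine classifies people into constitution types
that guide individualized treatment; the three common types — Tae-Eum
(TE), So-Eum (SE) and So-Yang (SY) — are the targets here. Voice
quality is a traditional diagnostic cue (TE voices are described as low
and baritone, SY voices as clear and high-pitched), and this package
implements a text-dependent statistical model of it: every subject
speaks the *same* sentence under a controlled recording protocol (mono
16-bit PCM at 44.1 kHz), and the model compares how the spectral
content of each part of that sentence varies between constitution
classes.

The design goal is *stability* as much as accuracy. A diagnosis that
flips between visits is clinically useless even if it is right on
average, so alongside the classifier the package implements a
repeated-measurement protocol that quantifies how consistently a
subject is diagnosed.

## Feature model

A recording is cut into frames of 2048 samples (46.4 ms at 44.1 kHz)
with 50% overlap, i.e. a hop of 1024 samples. Trailing partial frames
are discarded, never zero-padded, so no synthetic silence enters the
spectral analysis.

Speech frames are selected by an energy gate: a frame is valid when its
RMS amplitude clears both

* half the 10% quantile of all frame RMS values in the recording, and
* an absolute floor of $10^{-4}$ of 16-bit full scale.

The quantile term adapts to recording level; the factor of one half
leaves a margin below the quantile so that a recording with uniform
energy is entirely valid (a hard quantile cut would always discard the
quietest tenth of the frames, even when every frame contains speech),
while silent stretches — whose RMS is orders of magnitude lower — are
still rejected. Fewer than two valid frames is treated as an error
("insufficient speech") rather than producing a vacuous feature set.

Each valid frame yields 12 mel-frequency cepstral coefficients through
a conventional HTK-style recipe: pre-emphasis with coefficient 0.97,
Hamming window, magnitude FFT, 26 triangular mel filters from 0 Hz to
Nyquist applied to the power spectrum, log energies floored at
$10^{-10}$, and an orthonormal DCT-II of which coefficients 1–12 are
kept. The energy coefficient $c_0$ is dropped, which makes the retained
coefficients exactly invariant to a uniform gain on the waveform — the
model should respond to spectral shape, not microphone level.

The defining feature of the method is the 13th coordinate. The $i$-th
of $N$ valid frames (0-indexed) is tagged with its relative position

$$ts_i = \frac{i}{N-1} \in [0, 1],$$

so the first valid frame of the sentence sits at 0 and the last at 1.
The frame feature vector is $y_i = [x_i, ts_i]$ with $x_i$ the 12
MFCCs. Because every subject reads the same sentence, $ts$ aligns
corresponding parts of the utterance across speakers, and a mixture
component that concentrates near some $ts$ value specializes in that
part of the sentence. This is what lets frame-level features be used
directly instead of averaging them over the utterance — averaging is
appropriate for a sustained vowel but discards most of the information
in a sentence.

### Age standardization

Voice spectra drift with age, which would confound constitution with
age. Every MFCC is therefore z-scored against statistics local to the
speaker's age: for each gender, coefficient, and integer age $a$, the
mean and standard deviation are computed over all frames pooled across
training subjects aged within $a \pm 5$ years. Frames (not subject
averages) are pooled because frames are the analysis unit everywhere
else in the pipeline. At classification time a recording uses the
window of its own (rounded) age; ages outside the trained range clamp
to the nearest covered age, so boundary ages degrade gracefully instead
of failing. A window with fewer than two subjects or zero variance is a
fit error that names the gender, age and coefficient.

## Classification model

For each gender and class $\lambda$ a Gaussian mixture model over the
13-dimensional feature vectors is fitted:

$$p(y \mid \lambda) = \sum_{j=1}^{M} w_j \, g(y \mid \mu_j, \Sigma_j),
\qquad M = 15 .$$

$ts$ enters as an ordinary 13th dimension, so each component acquires a
mean time position $\mu_j[13]$ — the component's location along the
sentence. Covariances are diagonal by default, the standard choice for
MFCC mixtures (a full-covariance mode exists as a configuration
option).

**Initialization.** EM is seeded by a hard time partition: with $M$
components, frames from the first $1/M$ of the sentence (by $ts$) seed
component 1, and so on; $ts = 1$ lands in component $M$. Each
component's initial weight, mean and variance are the empirical moments
of its slice. This is deterministic — the whole training procedure has
no random element — and it anchors each component to one stretch of the
sentence, which the fitted models retain: the per-component mean $ts$
values come out approximately increasing from near 0 to near 1.

**EM.** Standard alternation of responsibilities and weighted moment
updates, stopping when the mean log-likelihood per frame changes by
less than $10^{-6}$ or after 200 iterations. Variances are floored at
$10^{-6}$. A component whose responsibility mass collapses (below
$10^{-10}$ of the data) is re-seeded from the initial time partition
with the largest total variance, with a message; in practice this path
is exercised only by pathological inputs. With $M = 1$ the fit reduces
exactly to the pooled sample moments, which the tests exploit as a
closed-form oracle.

**Decision rule.** A recording with frames $y_1 \dots y_N$ gets a
per-class total log-likelihood $L_k = \sum_i \log p(y_i \mid
\lambda_k)$, and normalized class probabilities

$$\pi_k = \frac{e^{L_k}}{\sum_{l} e^{L_l}}$$

computed from shifted log-likelihoods (log-sum-exp). The product form
of the recording likelihood underflows double precision after a few
dozen frames, so all scoring is in the log domain; the tests verify
agreement with the literal product on short sequences where it exists.
The diagnosis is $h = \arg\max_k \pi_k$, with exact ties broken by the
fixed class order TE, SE, SY (with a warning); the maximum $\pi_k$ is
the decision confidence and is at least $1/3$ for three classes.

A trained model bank stores the six (gender, class) models, the age
standardizer, and a fingerprint of every feature-affecting setting;
classification refuses a bank whose fingerprint does not match the
active configuration, since features and models are only meaningful as
a pair.

## Stability evaluation

For a subject with $R$ repeated recordings classified against one
bank:

* the **majority class** is the modal decision (ties broken by class
  order, with a warning);
* **repeatability** is the percentage of decisions equal to the
  majority class — for three classes it is bounded below by
  $\lceil R/3 \rceil / R$, not by $1/3$ of tests;
* the **probability mean / SD** are the mean and sample standard
  deviation (denominator $R - 1$) of the per-test confidences.

Sample rather than population SD is used: this is the standard
convention for repeated measurements, and at the protocol's $R = 50$
the difference is negligible. Reports aggregate subjects with an
unweighted average row; display rounding (one decimal for percent,
three for probabilities) is applied only at formatting time. The
package ships the published per-subject stability table for this method
and for an earlier baseline built on averaged vowel-and-sentence
features (`referenceStabilityTable()`); the baseline method itself is
out of scope and never recomputed — its column exists so stability
reports can be compared against it, and so the aggregation arithmetic
can be checked against published averages.

A second, classifier-free view is the feature-level stability table:
the SD across repeated recordings of each per-recording mean
standardized coefficient, per subject.

## The synthetic data generators

Expert-labelled clinical recordings of this kind are not publicly
available, so the package carries two generator levels that emulate the
statistical structure the method assumes; they are first-class, tested
code, not throwaway fixtures.

**Feature level** (`makeClassGenerators()`,
`sampleRecordingFeatures()`): each (gender, class) is a known
13-dimensional mixture — 5 components with time centers evenly spaced
over $[0,1]$ (SD $0.12$ in $ts$), equal weights, unit feature
variances, and mild component-specific structure. Class means are
displaced from a common base by a `separation` parameter along mutually
orthogonal directions, so `separation = 0` yields statistically
identical classes (classification must sit at chance) and a separation
of several feature SDs yields essential separability. Subjects receive
a Gaussian mean offset (SD 0.5) and recordings within-subject noise
(SD 0.3) — the offset makes speakers differ more between than within,
the noise creates the intra-subject variation the repeatability
protocol measures. Frame counts are drawn from 100–300 per recording,
matching the "well over a hundred valid frames" a read sentence
produces, and ages are spread evenly over 15–60 years, interleaved
across classes so that age never confounds class (the age-window
standardizer would otherwise absorb the class signal — and in a
designed clinical collection, age balance across classes is exactly
what one would require).

**Waveform level** (`synthSentenceWav()`, `simulateCohort()`): mono
16-bit 44.1 kHz files built from voiced segments (sawtooth source at a
class-dependent fundamental — 110/150/210 Hz for male TE/SE/SY, 1.6×
for female, echoing the traditional low-TE / high-SY description — with
declination and jitter, a spectral-tilt filter, two formant resonators
and a raised-cosine envelope) separated by true silences. These
exercise the full audio path: WAV parsing, framing, the energy gate
(pauses must come out invalid), and MFCC extraction. They are abstract
voiced/pause sequences, not Korean speech — the method is
language-agnostic at the feature level, and no clinical realism is
claimed. Consequently, closed-loop results on synthetic cohorts
demonstrate the correctness and stability of the machinery under the
model's own assumptions; they say nothing about clinical accuracy on
real patients, which depends on how strongly real voice features carry
constitutional signal.

Every generator output is a pure function of its parameters and seed.

## Problem sizes and numerical choices

The test suite and the acceptance script run closed-loop experiments at
desk scale, chosen to exercise every code path while keeping a full run
in tens of seconds: 10 training subjects per class (single gender,
100–300 frames each) for the separable and chance-level worlds, 30–300
held-out recordings for accuracy, $R = 50$ with zero within-subject
variation for the repeatability limit, and $n = 5000$ frames per
component for EM parameter recovery. At these sizes the well-separated
world classifies held-out recordings at 100%, the `separation = 0`
world stays within a few points of 33.3%, and zero-variation
repeatability is exactly 100%.

Other numerical decisions, collected: log-domain scoring everywhere
(log-sum-exp for mixtures and for the class normalization); variance
floor $10^{-6}$; mel log floor $10^{-10}$; deterministic EM with
partition re-seeding for collapsed components; ties in the decision and
in the majority vote broken by the fixed class order with warnings;
out-of-range ages clamped; non-44.1 kHz input rejected rather than
resampled; stereo or non-PCM WAV input rejected rather than converted.

## Known limitations

* Text-dependent by construction: train and test must use the same
  sentence; a different sentence invalidates the $ts$ alignment.
* The rare Tae-Yang type is not modelled (three-class decision only).
* Diagonal covariances ignore within-component correlation between
  coefficients; the full-covariance option trades robustness for it.
* The age standardizer requires at least two training subjects in
  every ±5-year window per gender; sparse cohorts fail the fit (by
  design, loudly).
* Synthetic cohorts validate the machinery, not clinical performance.
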