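# scvoice

Voice-based diagnosis of Sasang constitution types from sentence
recordings, with a stability (repeatability) evaluation protocol.

Sasang constitutional medicine, a tailored-medicine tradition in Korean
medicine, assigns individuals to constitution types — the three common
ones being Tae-Eum (TE), So-Eum (SE) and So-Yang (SY) — and voice
quality is one of its traditional diagnostic cues. `scvoice`
implements a text-dependent statistical version of that cue: every
subject reads the same sentence (recorded mono, 16-bit PCM, 44.1 kHz),
and the model learns how the spectral content of each *part* of that
sentence differs between constitution classes. Because a clinically
useful diagnosis must be stable across repeated visits, the package
puts equal weight on a repeated-measurement protocol that quantifies
how consistently a subject is diagnosed.

## The model

Each recording is reduced to a sequence of frame feature vectors

$$y_i = [x_i,\; ts_i], \qquad ts_i = \tfrac{i}{N-1} \in [0,1],$$

where $x_i$ holds 12 MFCCs of the $i$-th valid (speech) frame
(2048-sample windows, 46.4 ms at 44.1 kHz, 50% overlap, energy-gated)
and $ts_i$ is the frame's relative position in the sentence. MFCCs are
z-scored against per-gender moving age windows (±5 years). For every
(gender, class) pair a Gaussian mixture model

$$p(y \mid \lambda) = \sum_{j=1}^{M} w_j\, g(y \mid \mu_j, \Sigma_j),
\qquad M = 15,$$

is fitted by EM over the 13 dimensions, initialized by partitioning
frames uniformly along $ts$ — so each component starts anchored to one
stretch of the sentence, and the fitted components keep that temporal
ordering. A recording is classified by its per-class total
log-likelihood $L_k = \sum_i \log p(y_i \mid \lambda_k)$, normalized
across classes in the log domain:

$$\pi_k = \frac{e^{L_k}}{\sum_l e^{L_l}}, \qquad
h = \arg\max_k \pi_k .$$

Stability of the diagnosis is measured by classifying $R$ repeated
recordings of one subject: *repeatability* is the percentage agreeing
with the majority decision, and the mean and sample SD of the per-test
confidence $\max_k \pi_k$ complete the picture.

Since the clinical recordings behind such studies are not public, the
package includes synthetic generators (feature-level mixtures with
controllable class separation and subject variation, and waveform-level
sentence-like WAVs with class-dependent pitch) so the entire pipeline
is testable end to end. See the methods vignette
(`vignettes/voice-diagnosis.Rmd`) for the full model description and
design rationale.

## Worked example

Train a bank on a synthetic cohort and run the repeatability protocol
on one synthetic subject:

```r
library(scvoice)

gens  <- makeClassGenerators(separation = 5, seed = 11)
train <- sampleCohortFeatures(gens, n_subjects = 10, genders = "male", seed = 12)
bank  <- fitModelBank(train$recordings, train$labels, pipelineConfig())

gen   <- gens$male$SE
tests <- makeRepeatabilityTestSet(gen, sampleSubjectOffset(gen, 5),
                                  R = 50, intra_sd = 0.3, seed = 7)
res   <- lapply(tests, classifyRecording, bank = bank)
subjectStability(res)
#> SubjectStability synthetic: SE in 100.0% of 50 tests, confidence 1.000 +/- 0.000

round(tsSummary(bank$models$male$SE), 2)
#>  [1] 0.02 0.10 0.30 0.22 0.29 0.45 0.40 0.49 0.51 0.71 0.82 0.72 0.86 0.94 0.99
```

All 50 repeats of this well-separated subject land on SE with full
confidence — repeatability 100%, confidence SD 0 — and the 15 component
mean time positions climb from ~0 to ~1, showing the mixture covering
the sentence from start to end.

The same flow is available from the shell, through waveform-level
synthesis:

```sh
Rscript exec/scvoice simulate --out demo --seed 1
Rscript exec/scvoice train --metadata demo/metadata.csv --out demo/bank.json
Rscript exec/scvoice classify --bank demo/bank.json \
    --wav demo/female_SY_02_take1.wav --gender female --age 35
#> {"pi":{"TE":0,"SE":0,"SY":1},"h":"SY","confidence":1,"n_frames":84}
```

`evaluate-repeatability`, `evaluate-accuracy` and `summarize-ts`
complete the command set.

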