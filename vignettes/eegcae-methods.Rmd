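---
title: "Decoding emotion from EEG with differential-entropy cubes and a convolutional autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding emotion from EEG with differential-entropy cubes and a convolutional autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcae)
```

## The problem

Affective state is commonly described on two continuous axes — valence
(negative to positive) and arousal (calm to excited) — and EEG is the
physiological signal of choice for decoding it, because cortical rhythms react
to emotional state within milliseconds and cannot be consciously masked.
`eegcae` implements a complete subject-dependent decoding pipeline for
DEAP-style recordings: 40 one-minute music-video trials per subject, 32 EEG
channels at 128 Hz, each trial preceded by a 3-s pre-stimulus baseline, each
trial self-rated 1-9 on valence and arousal. Ratings are binarised into
low/high classes at the conventional cut of 5 (a rating of exactly 5 counts as
low; the threshold is an argument everywhere it matters).

## From raw trials to feature cubes

**Band decomposition.** Each channel's time series is decomposed with
3rd-order Butterworth band-passes into the theta (4-8 Hz), alpha (8-12 Hz),
beta (12-30 Hz) and gamma rhythms. Delta (0.5-4 Hz) is excluded: it dominates
unconscious states and carries no emotion signal. The textbook gamma band
extends to 100 Hz, but preprocessed DEAP data is sampled at 128 Hz and was
band-limited to 4-45 Hz upstream, so the package's default gamma edge is
45 Hz; the 100 Hz edge is available through `eeg_bands(gamma_high_hz = 100)`
and is clipped at design time if infeasible. Filtering is zero-phase
(forward-backward, `signal::filtfilt`), applied to whole trials before any
segmentation, so that group delay cannot shift window boundaries and edge
transients stay at the trial ends; a causal mode is available by flag. The
zero-phase choice and the filter-before-segment order are not dictated by the
protocol the pipeline reproduces — they are this package's resolution of that
ambiguity, chosen to avoid phase distortion inside 1-s windows.

**Differential entropy.** Every trial is cut into non-overlapping 1-s windows
(128 samples). Each window, band and channel is summarised by the Gaussian
differential entropy

$$h = \tfrac12 \log\!\left(2\pi e\,\hat\sigma^2\right),$$

with $\hat\sigma^2$ the population-form variance (divide by $N$) of the
de-meaned window — for a band-limited signal this is log band power up to
constants. Natural logarithm by default (nats); a `base` flag rescales.
Windows are de-meaned before computing power: the underlying Gaussian model
has a free mean, and band-passed signals are zero-mean anyway, so the choice
is numerically inconsequential but principled. A window whose variance falls
below `1e-12` raises an error naming the trial/window/channel — a
zero-variance EEG window means broken input, and silently clamping it would
poison every downstream z-score.

**Baseline subtraction.** The three 1-s baseline windows of each trial give
three DE values per band and channel; their arithmetic mean is that trial's
resting reference, subtracted from every stimulus window of the same trial,
band and channel. This removes subject- and trial-level offsets (electrode
impedance, amplifier gain, tonic state) and leaves the stimulus-driven change.

**Spatial fusion.** The 32 per-channel DE values of one window are placed on
a 9×9 grid following the international 10-20 electrode geometry (row 0
anterior, column 0 left; 49 cells stay exactly 0), and the four band matrices
are stacked depth-wise like colour channels of an image: one
9×9×4 cube per 1-s segment, 2400 cubes per subject. The exact cell
coordinates are shipped as an editable tab-separated file
(`extdata/layout_10_20_9x9.tsv`), not hard-coded, because grid placements are
a convention that users may need to correct for other montages.

## The classifier

The cube is classified by a convolutional autoencoder — here a hybrid
classifier, not an image-reconstructing autoencoder: a convolutional encoder,
a stacked autoencoder (SAE), and a softmax head.

* **Encoder** — four convolution layers (64, 128, 256 kernels of 4×4 and a
  fusing 64-kernel 1×1 layer), stride 1, zero `same` padding, ReLU, no
  pooling (the grid is too small to survive pooling). Output 9·9·64 = 5184
  features regardless of input content.
* **Dropout** 0.2 on the flattened encoder output.
* **SAE** — two sigmoid hidden layers of 400 and 100 units. Each
  autoencoder's input is batch-normalised. Pretraining is greedy and
  layer-wise: autoencoder 1 (5184→400→5184, linear decoder, mean squared
  reconstruction error) is trained and frozen; autoencoder 2 (400→100→400)
  is trained on its codes; decoders are then discarded. A sigmoid decoder
  cannot reproduce the negative values of standardised inputs, hence the
  linear decoder. "Sparse" autoencoders are named in the source protocol
  without a penalty or coefficient; the default here is plain reconstruction,
  with an optional KL-sparsity term (target activation 0.05, weight 1)
  behind the `sparsity` flag.
* **Softmax head** with cross-entropy loss; a probability floor of `1e-12`
  inside the logarithm keeps confidently wrong predictions finite without
  affecting optimisation. Exact probability ties predict the lower class
  index, for determinism.

**Batch normalisation is load-bearing.** The SAE input statistics are not
fixed: during training each minibatch is standardised by its own statistics
(with the exact batch-norm gradient), and exponentially weighted running
averages — fitted on training data only — are used at inference. An earlier
design with standardisation statistics frozen at pretraining time was
abandoned after it proved unstable: as fine-tuning moves the encoder, frozen
statistics drift off-scale, the sigmoid layers saturate, gradients die, and
the classifier collapses to the majority class. Per-minibatch statistics keep
the sigmoids in range no matter how far the encoder travels.

**Optimisation.** AdaDelta (decay 0.95, conditioning `1e-6`) with an
accuracy-gated learning-rate schedule re-evaluated each epoch from the
previous epoch's training accuracy: rate 1 below 0.70 accuracy, rate 2 up to
0.85, rate 3 above. The printed rates (1e-4, 5e-5, 1e-6) are treated as the
*shape* of the schedule rather than literal AdaDelta multipliers: AdaDelta's
update is self-normalising, with step size roughly `lr * sqrt(eps)` while its
accumulators are empty, so a literal 1e-4 multiplier yields ~1e-7 steps and
no learning at all. In the default `lr_mode = "relative"` the step multiplier
is `base_step` (default 0.1) scaled by 1, 1/2 and 1/100 across the three
branches — the schedule still slows learning a hundredfold once training
accuracy exceeds 0.85, which in practice freezes the features once the head
has converged. `lr_mode = "absolute"` restores the literal reading for
comparison. The L2 penalty (default `1e-4`) applies to weights, not biases.

**Staging.** Training runs in three phases: a short supervised warm-up of the
whole randomly initialised network (default 5 epochs), so that the encoder
the SAE reconstructs is not pure noise; greedy SAE pretraining on the
warmed-up encoder's outputs; then end-to-end supervised fine-tuning. Whether
pretraining should see a warmed-up or random encoder is ambiguous in the
source protocol; warm-up first is this package's default and
`warmup_epochs = 0` disables it. Per-epoch training accuracy is accumulated
from the minibatch forward passes (dropout active), so it slightly
understates true training accuracy; only the schedule consumes it, and the
bias is conservative (it delays, never hastens, the step-size cuts).

## Evaluation protocol

`run_cv()` implements shuffled k-fold cross-validation (leave-one-out is
`k = n`): folds are disjoint, jointly exhaustive, sizes differing by at most
one; a fresh model is trained per fold; nothing fitted on a test fold —
including batch-norm running statistics — ever touches its training.
Training folds that contain a single class are recorded as failed folds with
an explicit status rather than aborting the scheme. With 2400 segments and
`k = 10` each test fold has 240 segments and each training set 2160.

Segments of one trial may land on both sides of a split, which matches the
segment-level protocol being reproduced but is optimistic whenever segments
of a trial are correlated — in this package's own synthetic data the shared
baseline-estimation noise gives each trial a 128-dimensional fingerprint that
a flexible classifier can exploit, which is why a class-neutral subject
evaluated segment-wise scores well above 0.5 even though its labels are
unlearnable from the class structure alone. Label shuffling destroys exactly
this trial-coherence and drops accuracy to chance, which is the null check
used in the tests. A trial-grouped splitting mode (`group_by_trial = TRUE`)
is provided and announces itself when used.

`band_combination_grid()` re-runs the whole fuse-and-classify pipeline for
any of the 15 non-empty subsets of {theta, alpha, beta, gamma} and both
rating dimensions; `aggregate_subjects()` averages per-subject mean
accuracies (subject-dependent protocol).

## The synthetic-data generator

`generate_subject()` emulates exactly the DEAP geometry: 40 trials × 32
channels × 8064 samples at 128 Hz, 3-s baseline, ratings in [1, 9]. Each
(trial, channel) series is a sum of four band-limited noise carriers (white
noise filtered into each rhythm, normalised to unit standard deviation) plus
a broadband noise floor (sd 0.1). During the stimulus period each carrier is
scaled by the trial class's gain for that band; the baseline always uses unit
gains, so baseline statistics are class-independent by construction. The
default gain matrix is all ones except gamma gain 3 for the high class — a
single informative rhythm that shifts class-1 baseline-corrected gamma DE by
about `log 3` ≈ 1.1 nats, i.e. a strongly separable two-class problem.
Band-passed white noise is the natural carrier here because DE measures
exactly per-band variance, which the gains control directly. Ratings are
drawn uniformly from [1, 5) for class 0 and (5, 9] for class 1, so
binarisation at 5 recovers the generating classes exactly. One master seed
fans out to per-trial substreams, making any prefix of trials reproducible.

What the generator does *not* emulate: 1/f spectral shape, eye-blink and
muscle artifacts, volume-conduction correlation between neighbouring
electrodes, non-stationarity within trials, peripheral channels. Passing
tests on this data therefore demonstrates that the pipeline recovers planted
band-power class structure through the full feature-and-classifier stack —
not that it reaches any particular accuracy on real EEG.

## Problem sizes and numerical choices

The studies run by the test suite and by `scripts/acceptance.R` use the full
DEAP-shaped subject (2400 cubes, 10-fold cross-validation with 2160/240
splits) but a reduced model — convolution layers (4 kernels 3×3; 4 kernels
1×1), SAE 16/8, 2 warm-up, 3 pretraining and 60 fine-tuning epochs, batch
128 — the package's chosen configuration for studies at this scale. On the
strongly separable default generator this configuration reaches held-out
accuracy above 0.95 across seeds; the published-size architecture trains with
the same code path. Elsewhere: variance floor `1e-12` (hard error),
batch-norm sd floor `1e-6`, probability floor `1e-12`, He initialisation for
convolution kernels, Xavier for dense layers, zero biases, batch-norm running
average momentum 0.9.

## Known limitations

* Accuracies obtained on the synthetic generator say nothing quantitative
  about DEAP itself; the headline numbers of the reproduced protocol require
  the access-restricted dataset.
* The segment-level splitting protocol is optimistic under within-trial
  correlation (see above); use `group_by_trial = TRUE` for a conservative
  estimate.
* Training is pure R (BLAS-backed matrix algebra); the published-size
  architecture is practical for inference and short trainings but slow for
  large-scale fine-tuning.
* The pickle-based serialization of the original distribution is not parsed;
  subjects arrive either through the portable container or through any
  converter that writes the documented `deap_native` logical layout.
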