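---
title: "Measuring shared representations in bimodal autoencoders"
author: "sharedrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring shared representations in bimodal autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the measurement

When a network learns from paired inputs of two modalities — an image of a
digit and a spectrogram of the same digit spoken aloud — some hidden units
may come to respond to the digit's *category* regardless of which modality
carried it. Such modality-invariant units are called *shared
representations*, and their number is a direct, interpretable measure of
how well the network has fused its modalities. `sharedrep` implements an
end-to-end pipeline for producing and quantifying them in dense bimodal
autoencoders.

The core measurement is the binned, stimulus-specific single-cell
information, a tool from sensory neuroscience. For a unit with response
$r$ (its activation, divided into equally spaced bins) and a stimulus
category $s$,

$$I(s, R) = \sum_{r \in R} P(r \mid s)\, \log_2 \frac{P(r \mid s)}{P(r)},$$

the Kullback–Leibler divergence between the unit's response distribution
given $s$ and its marginal response distribution, in bits. A unit that
fires in a response range reserved for one digit carries up to
$\log_2(n_\mathrm{Cat})$ bits about it (≈ 3.32 bits for 10 digits); a unit
whose response distribution ignores the stimulus carries none.
Probabilities are plug-in (empirical) frequencies with no bias
correction, as in the reference analysis; the finite-sampling bias floor
is made visible through a label-shuffle null instead
(`infoMatrix` + shuffled labels), which the test suite uses as the
detection threshold for genuine selectivity.

Two estimation choices deserve note. Bins are equally spaced over the
fixed sigmoid output range $[0, 1]$ (10 bins by default), not over each
unit's observed range; a per-unit range option exists
(`binResponses(range=)`) but the fixed range is the default because it
keeps the bin geometry identical across units, layers and conditions.
Bin intervals are left-closed and right-open with the last bin closed, so
an exact upper-edge activation of 1 is counted. Terms with
$P(r\mid s) = 0$ contribute zero by convention.

## The networks

Both architectures encode a 28×28 visual array and a 14×56 auditory
(spectrogram-shaped) array, each flattened row-major to 784 values in
$[0, 1]$:

* **Mixed-input framework** — the two modalities are concatenated into a
  1,568-value input and encoded through 1–4 dense sigmoid layers of 64
  units; all encoding layers are modality-combined.
* **Two-stage framework** — each modality is encoded separately through 3
  sigmoid layers of 64 units; a fourth, modality-combined layer of 64
  units merges them. This is the classical arrangement in which feature
  learning precedes correlation learning. The package trains it end to
  end with this topology (the alternative of freezing per-modality stages
  first is deliberately not implemented; end-to-end training keeps the
  comparison with the mixed framework purely architectural).

Both decode through two parallel paths of 3 dense sigmoid layers (64, 64,
then the modality's dimension), one per modality. Training minimises the
binary cross-entropy of both reconstructions against the *original*
(never the zeroed) arrays, summed over the two branches — per branch the
loss is summed over output dimensions and averaged over the batch, the
same structure as the squared-error objective
$\lVert x_v - x_v' \rVert^2 + \lVert x_a - x_a' \rVert^2$, which is
additionally logged per epoch as a monitoring metric. The optimizer is
AdaDelta with its standard parameters ($\rho = 0.95$, $\epsilon = 10^{-6}$,
no learning-rate scaling). Weights are initialised with seeded fan-based
uniform draws; sample order is reshuffled every epoch from a seed derived
deterministically from the model seed, so a `(seed, data, epochs)` triple
reproduces a model bit-identically. Output activations are sigmoids,
required for cross-entropy on $[0, 1]$ targets. The inner loop runs in
compiled code (RcppArmadillo) with the shuffle stream generated in R.

## The data

The reference experiments use handwritten-digit images and spoken-digit
spectrograms. `sharedrep` replaces both with a synthetic generator so the
full pipeline is testable without downloads: each class is a smoothed
random field pushed through a logistic squashing (`protoSep` controls how
saturated and distinct the class patterns are), auditory classes have two
sub-prototypes mimicking two speakers, and samples are the prototype plus
additive Gaussian pixel noise (`noiseSd`), clipped to $[0, 1]$.

The sampling design mirrors the reference study: 500 visual training and
50 visual test variations per digit; an auditory pool of 100 variations
per digit (50 per speaker) halved at random into train and test;
consistent training sets pair every visual sample of digit $d$ with a
uniformly drawn (with replacement) auditory sample of the same digit,
inconsistent sets with a uniformly drawn sample of a *different* digit.
Modality-dropout augmentation then triples each set — unchanged,
visual-zeroed, audio-zeroed — while reconstruction targets keep both
original arrays, giving 15,000 training pairs (10 × 500 × 3) and 1,500
test pairs (10 × 50 × 3) in exact thirds.

Generator defaults (`noiseSd = 0.3`, `protoSep = 1.2`) were fixed once so
that trained-network information values form a graded distribution well
below the $\log_2 10$ ceiling — the regime in which a percentile
threshold is meaningful, as it is for the real data, where the 80th
percentile sits near 1 bit. What the generator does *not* emulate:
structural within-class variation (stroke styles, speaker prosody),
class imbalance, or any nonlinear correlation between the modalities
beyond the shared label. Passing tests therefore demonstrate the
pipeline's correctness and the direction of the architectural effects at
this reduced difficulty, not the reference study's exact counts.

## Unit typology

Per-unit information is computed separately on the visual-only and
audio-only thirds of the test set, because a unit responding to only one
modality's digits still scores on the full set. A unit is *selective* for
a digit when its information strictly exceeds a threshold; the threshold
is the 80th percentile of the pooled unit × digit information values of
the final encoding layer of the consistent-trained reference network,
computed per modality, then applied unchanged to every other condition.
Pooling over the full unit × digit matrix (rather than per-unit maxima)
was chosen because the reference description — the information each cell
carries about each digit — enumerates all pairs; the thresholds are
recorded in every typology for audit. Units selective in one modality are
*visual* or *auditory* cells; in both modalities, *consistent* cells when
the digit sets intersect (the shared representations) and *inconsistent*
cells otherwise; units selective in neither are reported as a fifth
`non_selective` category excluded from the four-type counts.

## Transfer evaluation

Shared representations should be usable: a classifier trained on the
frozen final encoding layer with *one* modality's examples should decode
digits from the *other*. `trainHead` fits two 64-unit rectified-linear
layers with 20% (inverted) dropout and a 10-way softmax by AdaDelta with
categorical cross-entropy — the optimizer family of the autoencoder; the
head's epochs and batch size are package defaults (60 and 32 at desk
scale) since the reference leaves them unspecified. The encoder is never
updated, and the test suite asserts its weights are bit-identical before
and after. `evaluateCrossModal` reports top-1 categorical accuracy
separately on the visual-only and audio-only test thirds; the
cross-modality figure is compared against a label-shuffle null (heads
trained on permuted labels) rather than against nominal chance, which
absorbs any optimistic bias from the head training itself.

## Experiments, profiles, statistics

`runDepthSweep` and `runFrameworkComparison` orchestrate the two
experiments over seeded replicates; each replicate regenerates fresh
pools and pairings from a derived seed, so every reported number is a
deterministic function of the master seed and the configuration.
Replicate outcomes are compared with a Welch two-sample t-test
(consistent vs inconsistent, mixed vs two-stage) and a classic one-way
analysis of variance across depths; with fewer than two replicates the
statistics are omitted. No multiple-comparison correction is applied,
matching the reference analysis. The t-tests are unpaired: the pairing
structure across replicates is not specified in the reference, and
unpaired Welch is the conservative default.

Two profiles bundle the problem sizes:

* `fullProfile()` — the reference conditions (500/50/50 per class, 5,000
  epochs). Expect hours per condition on one CPU.
* `deskProfile()` — the package's reduced configuration used by the test
  suite and all examples: 10 visual training and 25 test variations per
  class, 10 auditory variations per class per half, 80 epochs with
  minibatches of 32, 60 head epochs. These sizes were fixed once, before
  the directional checks were first run, at the point where the
  reconstruction loss reliably leaves its initial plateau across seeds
  and depths (roughly 500–800 optimizer steps at this data size).

At desk scale the quantitative outcomes of the reference experiments —
exact consistent-cell counts, accuracy curves, the 0.96/0.94-bit
thresholds, the printed t/F statistics — are not reproducible: they are
outcomes of full-scale stochastic training. The test suite therefore
asserts the *directional* findings over ≥ 5 seeds: more consistent cells
under consistent than inconsistent training at every depth, more under
the mixed-input than the two-stage framework, cross-modal transfer above
the shuffle null only for consistent-trained encoders, and near-zero
information before training.

## Numerical and degenerate-case choices

* Percentiles use the linear-interpolation definition
  (`quantile(type = 7)`).
* $0 \cdot \log 0 = 0$; a marginal bin probability of zero can only occur
  together with a zero conditional, so the ratio is never evaluated there.
* Binary cross-entropy pads probabilities with $10^{-12}$ inside the
  logarithm; sigmoid outputs keep encoder activations strictly inside
  $(0, 1)$.
* An inconsistent pairing enforces `label_v != label_a` per pair only —
  no derangement structure across a batch.
* Zero-variance groups in `compareGroups` return statistic 0 and p 1
  rather than NaN.
* A non-finite training loss aborts with the epoch index.
* `augmentModalityDropout` refuses already-augmented input; single-class
  pools cannot be paired inconsistently.

## Known limitations

The generator's iid pixel noise makes classes easier to separate than
real images or spectrograms, so absolute information values and cell
counts at desk scale are optimistic relative to real data. The
information estimator is uncorrected plug-in; with 10 bins and few
presentations per class the bias floor is visible (the shuffle null
quantifies it, and the untrained-network baseline stays well below the
trained values). Only two modalities and balanced classes are supported,
and population-level (multi-cell) information is out of scope.
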