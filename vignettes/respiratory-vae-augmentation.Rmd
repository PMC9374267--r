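---
title: "Generative augmentation of imbalanced respiratory-sound corpora"
author: "respaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative augmentation of imbalanced respiratory-sound corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Public lung-sound corpora annotated per respiratory cycle are heavily
imbalanced: in the ICBHI-style setting this package models, roughly 82% of
all cycles carry a COPD diagnosis, while classes such as LRTI contribute a
few dozen cycles. Deep multi-class classifiers trained on such data collapse
onto the majority class. `respaug` implements and evaluates one remedy:
train variational autoencoders (VAEs) on mel spectrograms of the minority
classes, sample synthetic spectrograms, invert them to audio, and add their
MFCCs to the training set.

## Pipeline and its assumptions

1. **Ingest** (`readCorpus()`): WAV recordings with per-cycle annotation
   text files (start s, end s, crackle, wheeze) and a patient-diagnosis
   CSV. Audio becomes mono float in [-1, 1] at 22050 Hz; small annotation
   overruns past the waveform end are clamped with a warning. Asthma
   recordings are dropped before classification (`dropAsthma()`): the
   classifiers have seven outputs and Asthma is too rare to learn; the
   count is logged.
2. **Segment and pad** (`segmentRecording()`, `padOrDiscard()`): one
   segment per annotated cycle; cycles strictly longer than 6 s are
   discarded, shorter ones are zero-padded at the end to exactly 132300
   samples. A cycle of exactly 6 s is kept — the discard rule excludes only
   durations above six seconds.
3. **Split** (`stratifiedSplit()`): 70% of segments per class to training,
   seeded per-class shuffling. The split is made *before* any VAE sees
   data, and only training-set spectrograms reach the VAEs; the test set
   contains real segments only. A recording-level split mode
   (`unit = "recording"`) is available because segment-level splitting can
   place cycles of one patient on both sides; segment-level remains the
   default as it mirrors the class-wise split protocol.
4. **Mel front end** (`melSpectrogram()`): 2048-point Hann STFT hopped by
   512, 128 mel bins, floored log power, min-max normalized to [0, 1] with
   dataset-level bounds fitted on the VAE training set only
   (`fitMelNormalization()`). A 6-s segment gives 259 frames; the trailing
   three are trimmed so that 128 x 256 is divisible by 8, which the
   stride-2 convolutional stacks require. Decoders end in a sigmoid, which
   forces the [0, 1] target — this is why min-max normalization (rather
   than z-scoring) is used.
5. **VAEs** (`trainVae()`, `generateSamples()`): three variants.
   *Dense (mlp)*: two 512-wide ReLU layers to a 2-d latent Gaussian and a
   mirrored decoder, Adam. *Convolutional (cnn)*: two stride-2 convolutions
   (16, 32 filters, kernel 3), a dense stack to the heads; the decoder maps
   the latent draw to a (mels/8, frames/8, 32) grid and applies three
   stride-2 fractionally-strided convolutions (32, 16, 1), RMSprop.
   *Conditional*: the convolutional topology with a one-hot class appended
   as constant channels at the encoder input and concatenated to the latent
   vector at the decoder. Unconditional variants are trained once per
   minority class and a guard rejects majority-class input; the conditional
   variant trains on all six minority classes jointly. The objective is
   squared reconstruction error summed over pixels plus `beta` times the
   KL divergence to the standard-normal prior (`beta = 1` by default);
   summing rather than averaging over pixels keeps the KL term from
   becoming negligible at 128 x 256 resolution, and `beta` is exposed to
   compensate if a different resolution is used.
6. **Inversion** (`invertMelSpecSet()`): de-normalize, exponentiate, map
   back through the mel-filterbank pseudo-inverse (clipped at zero), and
   estimate phase with Griffin-Lim. Inverted audio covers
   `frames x hop` samples and is zero-padded back to 6 s, consistent with
   the padding convention of real segments.
7. **MFCCs** (`mfcc()`): 13 coefficients per frame with a 1024-sample hop,
   so every 6-s segment yields a 13 x 130 matrix. The published front end
   (hop 512, 259 frames) is numerically inconsistent with the printed
   classifier input shape (13, 130, 1); the 1024 hop is the unique choice
   that reproduces that shape, so it is adopted here.
8. **Classifiers** (`trainClassifier()`): five architectures (deep MLP,
   small CNN, two-layer LSTM, and two frozen-backbone models with dense
   heads), softmax over seven classes, categorical cross-entropy, Adam.
   Each configuration is trained three times (seeds `seed + trial`).
9. **Evaluation**: Frechet audio distance per class (`fadPerClass()`),
   normalized cross-correlation at lag zero with a max-over-real protocol
   (`ccMatrix()`), DTW-aligned mel cepstral distortion (`mcdSummary()`),
   PCA of 39-d MFCC summary features (`pcaProject()`), one-vs-rest
   precision/recall/specificity/F1 (`perClassMetrics()`), and a balanced
   two-way ANOVA with replication over training sets x classifiers
   (`anovaTwoWay()`).

## Design choices where the design was open

- **Input standardization for classifiers.** MFCC coefficients span orders
  of magnitude (the energy coefficient dominates). All five classifiers
  therefore standardize each coefficient with training-set statistics
  before the first layer; the two backbone models additionally standardize
  their frozen features. This plays the role of the batch-normalization
  layers in the reference architectures and is fitted on training data
  only.
- **Frozen random backbones.** Pretrained ResNet-50 / EfficientNet-B0
  weights require a download; the package instead initialises backbones of
  the same topology family randomly (deterministically from the seed) and
  keeps them frozen as random-feature extractors, training only the dense
  heads. The efficient-style backbone downsamples by 2^5, so a 13 x 130
  input flattens to 1 x 5 x 1280 = 6400 features, matching the published
  head input. Classification results for these two architectures are
  therefore not comparable to runs with pretrained weights.
- **Frechet form.** The printed FAD formula contains a mean vector inside
  the trace; the standard Frechet/2-Wasserstein form
  `||mu_r - mu_g||^2 + tr(S_r + S_g - 2 (S_r S_g)^{1/2})` is implemented,
  treating the printed version as a typo. The matrix square root uses a
  symmetric eigendecomposition with small negative eigenvalues clipped.
- **Pluggable embedder.** FAD conventionally uses a pretrained VGGish
  network. The default embedder here is self-contained and deterministic —
  per-mel-band log-energy mean and standard deviation over 0.96-s windows —
  so everything runs offline; other embedders can be registered behind the
  same interface (`registerEmbedder()`). Absolute FAD values are therefore
  on a different scale from VGGish-based numbers; comparisons are only
  meaningful within one embedder.
- **Cross-correlation normalization.** The published correlation values lie
  in [0, 1] although the printed formula is unnormalized; Pearson
  correlation at lag zero (mean removal, energy normalization) is used.
- **MCD convention.** The energy coefficient c0 is excluded from the mel
  cepstral distortion by default (`excludeC0 = FALSE` restores it); the
  scale constant is `10 * sqrt(2) / ln 10`. DTW uses full-window dynamic
  programming with the symmetric step pattern — at 130 frames no band
  constraint is needed.
- **ANOVA replicate structure.** Each (training set, classifier) cell
  holds the per-class metric values of all trials: 7 classes x 3 trials =
  21 replicates, giving the 4 x 5 design 3 and 400 degrees of freedom and
  a 0.05 critical F of 2.63. The training-set factor's F is reported, as
  the tested hypothesis concerns differences across training sets.
- **Macro statistics** use the population (n-denominator) standard
  deviation; metrics with zero denominators are set to 0 and flagged.

## The synthetic corpus

`generateCorpus()` writes an ICBHI-format corpus (WAV + annotation TXT +
diagnosis CSV + manifest) that is a pure function of its configuration,
emulating the statistical structure the pipeline assumes:

- **Imbalance**: `imbalancedPreset()` scales the real per-class cycle
  counts down 20-fold, keeping the majority fraction at about 82%.
- **Durations**: log-normal with mode 2.5 s and log-sd 0.35, clipped to
  [0.5, 10] s — about 2% of cycles exceed 6 s, exercising the discard
  rule.
- **Acoustics**: every cycle carries band-limited breath noise modulated
  by an inhale/exhale envelope; wheezes are 1-3 vibrato harmonics drawn
  from a class-specific band inside 250-800 Hz; crackles are 5-15 ms
  exponentially decaying noise bursts at a class-specific rate. Classes
  differ in tonal band, burst rate, noise band and envelope shape, so they
  are statistically distinguishable in spectral-envelope features.

The generator makes no claim of clinical realism. Passing tests on this
corpus show that the pipeline's machinery behaves as specified under the
assumed statistical structure — they do not show that the same
augmentation gains would be obtained on real auscultation recordings,
where inter-patient variability, recording equipment and noise sources
are far richer.

## Numerical choices

- Log floor `1e-10` before all logarithms (zero-padding produces exact
  zeros).
- Griffin-Lim phase is initialised uniformly at random from the R RNG;
  all sampling (latent draws, shuffling, dropout) flows through seeds, so
  every training and generation run is exactly reproducible.
- Mel-filterbank inversion clips negative pseudo-inverse outputs at zero
  before the square root.
- Degenerate cases: a zero-range normalization errors; zero-energy signals
  correlate as 0 with a warning; zero within-cell ANOVA variance flags the
  result as degenerate.
- Band-limited noise is synthesised by FFT masking at a power-of-two
  length (odd-length FFTs can be quadratic).

## Problem sizes

Two presets bundle the configuration (`experimentConfig()`):

- `"desk"` — the package's own reduced study, used by the test suite:
  the 20x scaled-down corpus (~345 cycles), VAEs trained 30 epochs on
  64 x 64 block-averaged spectrograms (batch 16, learning rate 1e-3),
  4 Griffin-Lim iterations (MFCCs depend on the magnitude spectrum, which
  stabilises after a few iterations), augmentation to 40 training segments
  per minority class, classifiers with reduced layer widths trained 15
  epochs at the study's learning rate of 1e-4, three trials, and
  10-15-sample evaluation protocols.
- `"paper"` — full-scale settings: full-resolution spectrograms, 100-epoch
  VAEs and classifiers, augmentation up to the majority-class count,
  32 Griffin-Lim iterations and 50-sample evaluation protocols. This preset is provided for users with the real
  corpus and a compute budget to match.

## Known limitations

- The headline tables of the original study were computed on the real
  ICBHI recordings; without that corpus absolute metric values are not
  reproducible here. What the package reproduces is the arithmetic that
  aggregates published per-class values, the closed-form behaviour of the
  metrics, and the directional effect of augmentation on a corpus with the
  same imbalance structure.
- FAD values from the built-in embedder are not comparable to published
  VGGish-based FAD scores.
- With random frozen backbones, the two transfer-learning classifiers
  measure what random convolutional features can do, not what ImageNet
  pretraining can do.
- Minority-class test sets are tiny at desk scale (2-5 segments), so
  per-class F1 values are coarse; conclusions should rest on the
  aggregate direction, which is what the tests assert.
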