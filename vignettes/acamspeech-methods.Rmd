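---
title: "Severity-aware keyword classification and aphasia-specific CAM: methods and design"
author: "acamspeech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-aware keyword classification and aphasia-specific CAM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`acamspeech` is a desk-scale, fully synthetic re-creation of an
explanation framework for keyword classification in aphasic speech. It has
five working parts:

1. **synthio** — a generator of BNT-style keyword utterances with planted,
   ground-truth-annotated anomalies (pauses, phoneme
   substitutions/deletions/insertions, word-boundary shifts) whose rates are
   coupled to a continuous severity score (the Aphasia Quotient, AQ; lower =
   more severe).
2. **model** — a small spectrogram keyword classifier with FiLM severity
   conditioning, exposing the feature-tap and class-gradient contract the
   attribution core needs.
3. **afilter** — the multimodal aphasia filter: pause detection by energy
   VAD, mispronunciation spans by edit-distance phoneme alignment,
   word-boundary gaps from the word tier, combined into the weighted
   composite mask `AF[t]`.
4. **acam** — the dual-stream attribution core: adaptive-perturbation
   gradient accumulation, mean-square normalization, dual positive
   filtering, AF gating (impairment branch), segment-wise CAM aggregation.
5. **metrics** — deletion/insertion AUPC, ADCC, binarization, IoU/Dice,
   Mann-Whitney U, Cohen's *d*, Spearman rho, and the energy/random
   baselines.

Everything runs on one CPU with no external data or pretrained weights.
That is a deliberate trade: the original system fine-tunes a large
self-supervised speech encoder on a membership-gated clinical corpus, and
none of its absolute headline numbers are reproducible at this scale. What *is* reproducible —
and what the test suite asserts — are the exact operation-level formulas,
the pipeline's algebraic identities, and the *directions* of every reported
effect (severity correlations, correct/incorrect contrasts, A-CAM versus
baselines).

# The synthetic cohort

## What the generator emulates

Each utterance is a two-word carrier phrase ("a *keyword*") over 15 keyword
classes taken from a confrontation-naming item set (beaver, bench, cactus,
canoe, comb, hammock, house, octopus, palette, sphinx, stethoscope,
toothbrush, tripod, unicorn, volcano). Phoneme acoustics are stylized
spectral recipes — per-band center frequency, bandwidth and relative
amplitude, rendered as harmonic tone stacks plus narrow-band noise — not
naturalistic speech. The classifier only needs separable, phoneme-structured
classes; the explanation machinery needs exact ground truth, which this
representation provides by construction.

A *speaker surrogate* is a fixed ±5% multiplicative perturbation of all
recipe center frequencies plus one severity draw; surrogates never span
train/validation/test splits, mirroring a speaker-disjoint protocol.
Severity is a per-speaker property, as AQ is clinically.

The default severity sampler draws AQ from a Beta(3.4, 1.6) rescaled to
[20.5, 94.8]. This matches the published summary of the cohort the package
emulates — range 20.5–94.8, mean 71.0, roughly a third of speakers mild
(AQ ≥ 76) and about one in ten severe (AQ < 50). A uniform sampler would
make half the cohort moderate-to-severe, which is far more corrupted than
the reference population.

## Severity-anomaly coupling

All anomaly rates interpolate linearly in `(94.8 − AQ)` between a floor at
the mildest severity and a ceiling at the most severe (`couplingDefaults()`):

| parameter            | floor (AQ 94.8) | ceiling (AQ 20.5) | unit |
|----------------------|------|------|------|
| pause rate           | 0    | 1.5  | expected pauses/utterance |
| pause duration       | —    | —    | drawn U(0.5, 0.9) s |
| substitution prob.   | 0    | 0.35 | per phoneme |
| deletion prob.       | 0    | 0.10 | per phoneme |
| insertion prob.      | 0    | 0.10 | per phoneme |
| boundary-shift prob. | 0    | 0.6  | per word junction |
| boundary shift       | —    | —    | drawn U(0.35, 0.65) s |

No per-type anomaly-rate statistics are published for the reference corpus,
so these ceilings are the package's own choice of "clinically plausible but
clearly visible"; the linear-in-AQ form was chosen for monotonicity and easy
inversion in tests. At AQ = 94.8 every rate sits at its zero floor, which
makes the mildest-severity dataset provably clean — a property the tests
use.

Two placement decisions matter for detector coherence:

* **Pauses are planted word-internally** (between phonemes of one word), as
  −60 dBFS Gaussian noise rather than digital zero. Word-internal placement
  keeps a planted pause from opening a word-tier gap that the *boundary*
  detector would also flag; non-zero noise keeps energy VAD non-trivial.
* **Boundary shifts stretch the pre-junction phoneme** into the gap
  (linear resampling), so the audio in the gap is voiced. The word tier
  keeps the canonical word end, the produced phoneme tier follows the
  audio; the disagreement between the two tiers *is* the anomaly. Pause
  detection stays quiet there (the gap is not silent), so each planted
  anomaly type is recovered by exactly one detector.

Deleted phonemes leave a nominal 10 ms truth span at the cut point — a
zero-width interval would vanish under any rasterization.

## What passing tests do not show

The generator does not model prosody, coarticulation, semantic paraphasia,
neologisms, or apraxia-like distortions; a real forced aligner's errors on
disordered speech are also out of scope (tiers are consumed as given).
Green tests therefore demonstrate correctness of the *machinery* and
direction-level consistency with the reference findings on separable
synthetic classes — not clinical performance on real aphasic speech.

# The classifier

Input is a log-mel spectrogram: 16 kHz mono, 25 ms Hann window, 10 ms hop,
128 mel bins, natural log with a 1e-6 floor. A time-frequency input (rather
than a raw-waveform foundation encoder) is the central fidelity deviation:
it keeps bin-level deletion/insertion perturbation and heatmap overlays
well-defined at desk scale.

The architecture is one strided 2-D convolution block (12 channels, 16×5
kernel, stride 8×3, ReLU) whose output is the **prediction tap** — the
frequency axis survives as 15 blocks of channels with a recorded
block-to-mel map; then a linear projection with additive sinusoidal
positions and two residual encoder blocks (single-head self-attention +
position-wise FFN, width H = 40), whose output is the **impairment tap**;
then FiLM modulation, global average pooling over time, and a 2-layer MLP
head over 15 classes.

FiLM: a 2-layer MLP maps the *raw* AQ score (no normalization — the first
layer absorbs scale) to a 2H vector split into gamma and beta;
`out[t,h] = gamma[h]·x[t,h] + beta[h]` broadcast over time. The generator's
output layer initializes at zero with gamma bias 1, so an untrained model
is an exact FiLM identity — the conditioning ablation is exact, not
approximate.

There is no autodiff framework in this stack, so forward and backward
passes are hand-written; correctness is pinned by central-finite-difference
tests at relative error < 1e-3 (observed ~1e-9) on both taps and on
parameters. There are no normalization layers, dropout, or stochastic
kernels: evaluation-mode determinism is structural.

Training is minibatch Adam (lr 2e-3 with half-cosine decay, batch 16, 36
epochs by default) on cross-entropy, with one seeded RNG stream per epoch
covering batch order and augmentation (small mel-axis shifts of ±2 bins —
matching the ±5% speaker-surrogate frequency spread — plus mild Gaussian
input noise; SpecAugment-style masking is available but off by default, as
it hurt held-out accuracy here). An auxiliary frame-level phoneme
classification loss (weight 0.5) on the transformer tap, supervised by the
produced phoneme tier that annotated training data carries anyway, grounds
the encoder in phoneme identity; the keyword head, pooling and taps are
untouched by it.

On the default synthetic cohort this classifier plateaus at roughly 90%
held-out accuracy (the acceptance script prints the exact value for its
seed). The gap to a perfect score is informative: a privileged symbol-level
oracle — edit distance between the produced phoneme tier and the 15
canonical sequences — resolves about 98% of the same held-out utterances,
so the information survives the planted corruption, but recovering it
requires sequence alignment, which a globally-pooled classifier head (the
architecture pattern this package deliberately mirrors) cannot express for
heavily corrupted productions. Capacity, depth, schedule, augmentation and
data-size variations all land on the same plateau.

# The aphasia filter

* **Pauses**: short-time log-energy VAD (25 ms/10 ms frames), silence
  threshold −40 dBFS, minimum pause duration `T_P` = 0.25 s. The reference
  names VAD without a method; energy thresholding is transparent,
  parameterized, and consistent with the energy baselines used for
  comparison. Thresholds are config keys, not inferences.
* **Mispronunciations**: unit-cost minimal edit distance between the
  canonical phoneme sequence and the produced tier's symbols, replacing
  acoustic forced alignment (out of scope). The backtrace is deterministic:
  prefer the diagonal, then the canonical-advancing deletion, then
  insertion among equal-cost moves. Deletion spans borrow the midpoint gap
  between flanking produced segments, widened to at least one 10 ms frame.
* **Boundary errors**: inter-word gaps above `T_B` = 0.30 s from the word
  tier.
* **Masks**: rasterized by frame-center containment — frame `t` (0-based)
  is set iff `(t + 0.5)/fps` lies in a half-open `[start, end)` interval —
  stated once here, used everywhere.
* **Composition**: `AF[t] = 1.0·M_P[t] + 1.2·M_M[t] + 1.5·M_WB[t]`, the
  reference weighting (boundary disruptions highest, then phoneme
  mismatches, baseline weight for pauses). The all-overlap value is
  therefore exactly 3.7, which the oracle tests assert.
* **Resampling** to the transformer tap's frame grid (unspecified in the
  reference) is nearest-frame-center with values carried unchanged, so mask
  weights never interpolate across anomaly borders by more than one frame.

# The attribution core

Per branch: the base class-logit gradient at the tap, plus N = 8 gradients
at Gaussian-perturbed inputs. The noise magnitude starts at sigma = 0.01
(model-input units), grows by `step·mean(|G|)` after each perturbation and
is capped at 0.1; one sigma track per branch keeps the branches
independent. The accumulated gradient is divided by `mean(G²) + 1e-5` — the
mean *square*, as printed in the reference formulation, not the
root-mean-square; the unusual scaling is intentional and tested. Dual
filtering keeps only cells where both the activation and the normalized
gradient are positive; the impairment branch is then gated per frame by
`AF[t]`.

Segmentation: starts `j_m = round(m·t_seg·(1−O))` with `t_seg` = 25 tap
frames and O = 0.5 by default (unstated in the reference; both are config
keys surfaced in provenance hashes). Per segment, channel weights are the
gradient means over the segment's true (clipped) length and the segment CAM
is the weighted channel sum — computed per frequency block on the
prediction branch, whose tap keeps a frequency axis.

A plain mean over segments is ill-posed when segments overlap in time, so
aggregation places each (rectified, Gaussian-smoothed, kernel width 5
frames) segment CAM on a full-length canvas and averages overlapping frames
by coverage count — which reduces to the plain mean when all segments share
one support, and to the unsegmented CAM when there is a single full-span
segment (both identities are tested). Rectification happens at aggregation
because the transformer tap can be negative, and the weighted channel sum
alone does not guarantee the non-negative maps the framework promises;
positive scaling commutes with rectification, so the gating-linearity
identity (AF ≡ c scales the raw map by c) survives exactly.

Raw and display (min-max) copies are kept separate: all metrics consume raw
maps, except where a metric's definition requires [0, 1] (ADCC's coherency
and complexity use the display copy). A constant raw map min-max-normalizes
to zeros by convention.

# Metrics

Deletion/insertion: bins ranked by raw relevance, ties broken by grid order
(ascending time, then frequency) so uniform maps are handled
bit-reproducibly; K = 20 steps of 5% (the reference says "fixed ratios"
without a count); baseline B is the per-mel-bin input mean (spectrally
neutral), with the log-floor "silence" and literal zeros as alternatives;
the curve includes step 0 and AUPC is its trapezoidal area over the
fraction axis.

ADCC combines average confidence drop, complexity (mean |display map|) and
coherency (Pearson correlation between the display map and the display map
recomputed on the masked input, clipped to [0, 1]) through the harmonic
mean. Masking is the baseline blend `map·x + (1−map)·B` by default: on a
log-mel input a literal product does not mean "remove evidence" (zero in
log space is not silence), and the blend matches the deletion/insertion
baseline semantics; the literal product is available as `masking =
"multiply"`.

Group statistics go through `stats::wilcox.test` (two-sided); Cohen's *d*
uses the pooled standard deviation; Spearman rho uses average ranks with
the two-sided t-approximation p-value. All p-values are reported
uncorrected, as in the reference analyses.

The localization score for a relevance map is the frame-level IoU between
the binarized (utterance-mean threshold) temporal profile and the union of
the utterance's ground-truth anomaly intervals — all three types, since the
impairment stream is gated by a filter that responds to all three.

# Acceptance study sizes

The self-contained study run by the test suite and the acceptance script
uses: 15 classes × 56 utterances (40 train / 8 validation / 8 test per
class), 45 speaker surrogates (27/9/9 across splits), 36 training epochs;
filter statistics on all 120 held-out utterances; attribution comparison
(deletion/insertion versus the shuffled-map random baseline, impairment-map
versus base-CAM IoU) on 60 held-out utterances; planted-anomaly recovery on
50 single-anomaly utterances. These sizes were chosen as the smallest at
which the group statistics are stable; everything regenerates from seeds at
run time.

# Known limitations

* Synthetic phoneme acoustics are far cleaner than real speech; absolute
  accuracies and IoUs here say nothing about clinical performance.
* The edit-distance aligner sees the produced tier as ground truth; real
  forced-alignment noise (which the reference acknowledges for severe
  speakers) is not modelled.
* Semantic errors — the dominant error mode in anomic aphasia — are
  invisible to an acoustic-phonological filter by design, in the synthetic
  cohort as in the reference's own stated limitation.
* The FiLM generator consumes severity as an oracle input; estimating
  severity from audio is out of scope.
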