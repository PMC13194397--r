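# acamspeech

Explainable keyword classification for aphasic speech, at desk scale.

People with aphasia produce spoken words with phoneme substitutions,
deletions and insertions, hesitation pauses, and disrupted word-boundary
timing — and the frequency of these anomalies grows with clinical severity
(the Western Aphasia Battery's Aphasia Quotient, AQ; lower is more severe).
Classifying which target word was attempted (as in Boston Naming Test
scoring) is therefore hard, and clinicians additionally want to know *where*
in the production the impairment shows. `acamspeech` implements, end to end
and fully synthetically, a framework for that problem:

* a **severity-conditioned keyword classifier**: log-mel spectrogram front
  end, CNN block, transformer encoder, and FiLM conditioning that maps the
  raw AQ score to per-channel affine parameters
  (`h'[t,k] = γ_k(AQ)·h[t,k] + β_k(AQ)`), pooled into a 15-way softmax;
* a **multimodal aphasia filter**: energy-VAD pause intervals, edit-distance
  phoneme-alignment mismatch spans, and word-boundary gaps, rasterized to
  binary masks and combined per frame as
  `AF[t] = 1.0·M_P[t] + 1.2·M_M[t] + 1.5·M_WB[t]`;
* a dual-stream **A-CAM attribution core**: per-branch class-logit gradients
  `G = ∂y_c/∂F` accumulated under adaptive Gaussian input perturbation
  (`σ' = min(P_max, σ + step·mean(|G(p)|))`), normalized by
  `mean(G²) + 1e-5`, dual-filtered to doubly-positive cells
  (`G·1(F>0)·1(G>0)`), gated by `AF[t]` on the impairment branch, and
  aggregated over overlapping segments (`j_m = round(m·t_seg·(1−O))`,
  channel weights = segment-mean gradients, CAM = weighted channel sum) into
  a prediction map and an impairment map on the spectrogram grid;
* **faithfulness and validation metrics**: deletion/insertion perturbation
  curves with trapezoidal AUPC, ADCC (harmonic mean of coherency,
  1−complexity, 1−average drop), mean/Otsu binarization, frame-level
  IoU/Dice, Mann–Whitney U, Cohen's *d*, Spearman ρ, and
  energy/inverted-energy/shuffled-map baselines;
* a **synthetic disordered-speech generator** that plants all three anomaly
  types with exact ground-truth intervals, coupled to AQ, over 15
  naming-test keywords, with speaker-disjoint splits — so every stage above
  is testable without any external data.

The real system this emulates fine-tunes a large speech foundation model on
a gated clinical corpus; its absolute numbers are not reproducible at desk
scale and are not claimed. What this package reproduces is the machinery —
exactly — and the reported effect *directions* under its own synthetic
cohort.

## Worked example

```r
library(acamspeech)

# a moderate-severity speaker attempting "a stethoscope"
spec  <- keywordInventory()[["stethoscope"]]
clean <- genKeywordWaveform(spec, severity = 55, seed = 42)
utt   <- plantAnomalies(clean, severityToAnomaly(55), seed = 7)
utt
#> Utterance: keyword 10, 2.53 s, AQ 55.0, incorrect, 10 phonemes, 5 truth anomalies

af <- buildAphasiaFilter(utt)
af
#> CompositeFilter: 252 frames @ 100 fps, mean AF 0.762, weights (P=1, M=1.2, WB=1.5)
```

At AQ 55 the generator planted five anomalies (pauses, substituted
phonemes, a boundary shift), and each detected anomaly contributes its
weight on its frames — a frame inside all three anomaly types would score
1.0 + 1.2 + 1.5 = 3.7; this utterance averages 0.76. A mild production
(AQ ≥ 90) gives a filter near 0.

Train the classifier and explain the same utterance:

```r
man  <- genDataset(nPerClass = 56, seed = 11, nSpeakers = 45,
                   writeFiles = FALSE,
                   splitFractions = c(train = 40/56, val = 8/56, test = 8/56))
fit  <- trainToy(initKeywordModel(modelConfig(seed = 5)), man,
                 utterances = attr(man, "utterances"))
expl <- acamExplain(fit$model, utt)
expl
#> DualExplanation: class 10 (p = 0.693); grids 128 x 251; mean AF 0.762
```

Despite five planted anomalies the classifier recovers class 10
("stethoscope"), at reduced confidence. The prediction map highlights the
spectro-temporal evidence for that decision; the impairment map is nonzero
only inside filter-flagged frames, localizing the planted anomalies. `exportExplanation(expl, "out/", utt)`
writes both maps (`.rds`), PNG overlays, the filter CSV and a provenance
JSON. A command-line wrapper covering `synth`, `train`, `filter`,
`explain`, `evaluate` and `validate-filter` ships in `inst/cli/acamspeech.R`.

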