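# Dataset-level validation drivers: aphasia-filter statistics against
# labels and severity, and explanation-method comparison (faithfulness and
# truth-region localization). These are the loops behind the `evaluate` and
# `validate-filter` subcommands and the package's own acceptance study.

#' Validate the aphasia filter against labels, severity and truth regions
#'
#' For every manifest entry, builds the composite filter and records its
#' mean activation and its binarized-mask IoU against the utterance's truth
#' anomaly regions; then compares mean activation between incorrect and
#' correct productions (Mann-Whitney U, Cohen's d, ratio) and against
#' severity (Spearman rho).
#'
#' @param manifest a [DatasetManifest-class].
#' @param utterances optional in-memory utterances.
#' @param split restrict to one split tag (`NULL` = all).
#' @param weights,vad,boundary filter configuration.
#' @return list with `perUtterance` (data.frame) and `stats`.
#' @export
validateFilter <- function(manifest, utterances = NULL, split = NULL,
                           weights = filterWeights(), vad = vadConfig(),
                           boundary = boundaryConfig()) {
  e <- manifestEntries(manifest)
  idx <- if (is.null(split)) seq_len(NROW(e)) else which(e$split == split)
  rows <- lapply(idx, function(i) {
    utt <- loadUtterance(e[i, ], utterances, i)
    af <- buildAphasiaFilter(utt, weights, vad, boundary, fps = 100)
    v <- filterValues(af)
    truth <- truthMask(utt, framesPerSecond(af), length(v))
    ib <- frameIouDice(binarizeMap(v, "utterance-mean"), truth)
    data.frame(index = i, severity = e$severity[i],
               correctness = e$correctness[i], meanAF = mean(v),
               iou = ib$iou, dice = ib$dice)
  })
  per <- do.call(rbind, rows)
  inc <- per$meanAF[!per$correctness]
  cor_ <- per$meanAF[per$correctness]
  stats <- list(
    group = if (length(inc) >= 2 && length(cor_) >= 2)
      groupStats(inc, cor_) else NULL,
    severity = spearmanStat(per$meanAF, per$severity),
    meanIoU = mean(per$iou))
  list(perUtterance = per, stats = stats)
}

#' Compare explanation methods on a dataset split
#'
#' For each utterance: the dual A-CAM explanation, the plain Grad-CAM
#' baseline and a temporally shuffled random baseline of the A-CAM
#' prediction map. Records deletion/insertion AUPC (prediction branch,
#' predicted class), ADCC of the A-CAM prediction map, and truth-region IoU
#' of the impairment map versus the base CAM.
#'
#' @param model a trained [KeywordModel-class].
#' @param manifest a [DatasetManifest-class].
#' @param utterances optional in-memory utterances.
#' @param split split tag to evaluate.
#' @param nMax cap on the number of utterances.
#' @param perturbation,segments,weights,vad,boundary pipeline configuration.
#' @param faithfulness a [faithfulnessConfig()].
#' @param withAdcc also compute ADCC (adds model evaluations).
#' @param seed seed for the random baseline shuffles.
#' @return list with `perUtterance` (data.frame) and `summary`.
#' @export
evaluateExplanations <- function(model, manifest, utterances = NULL,
                                 split = "test", nMax = Inf,
                                 perturbation = perturbationConfig(),
                                 segments = segmentConfig(),
                                 weights = filterWeights(),
                                 vad = vadConfig(),
                                 boundary = boundaryConfig(),
                                 faithfulness = faithfulnessConfig(),
                                 withAdcc = TRUE, seed = 1L) {
  e <- manifestEntries(manifest)
  idx <- which(e$split == split)
  if (length(idx) > nMax) idx <- idx[seq_len(nMax)]
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    utt <- loadUtterance(e[i, ], utterances, i)
    S <- logMelSpectrogram(waveform(utt), sampleRate(utt))
    expl <- acamExplain(model, utt, perturbation = perturbation,
                        segments = segments, weights = weights, vad = vad,
                        boundary = boundary)
    cls <- expl@predictedClass
    predMap <- predictionMap(expl)
    rnd <- baselineMaps(S, "random", refMap = predMap,
                        seed = deriveSeed(seed, i))
    diA <- deletionInsertion(model, S, severity(utt), predMap, cls,
                             faithfulness)
    diR <- deletionInsertion(model, S, severity(utt), rnd, cls, faithfulness)
    gcImp <- gradcamBaseline(model, S, severity(utt), cls, "impairment")
    iouA <- mapTruthIoU(impairmentMap(expl), utt)
    iouG <- mapTruthIoU(gcImp, utt)
    ad <- if (withAdcc)
      adcc(model, S, severity(utt), predMap, cls)$adcc else NA_real_
    nTruth <- sum(vapply(truthIntervals(utt), NROW, integer(1)))
    rows[[j]] <- data.frame(
      index = i, severity = severity(utt), correctness = correctness(utt),
      predicted = cls, label = keywordId(utt),
      meanAF = mean(filterValues(explanationFilter(expl))),
      delAcam = diA$deletion$aupc, insAcam = diA$insertion$aupc,
      delRandom = diR$deletion$aupc, insRandom = diR$insertion$aupc,
      adcc = ad, iouImpair = iouA$iou, iouGradcam = iouG$iou,
      nTruthAnomalies = nTruth)
  }
  per <- do.call(rbind, rows)
  hasErr <- per$nTruthAnomalies > 0
  summary <- list(
    accuracy = mean(per$predicted == per$label),
    delAcam = mean(per$delAcam), insAcam = mean(per$insAcam),
    delRandom = mean(per$delRandom), insRandom = mean(per$insRandom),
    adcc = mean(per$adcc),
    iouImpair = mean(per$iouImpair[hasErr]),
    iouGradcam = mean(per$iouGradcam[hasErr]),
    n = NROW(per))
  list(perUtterance = per, summary = summary)
}
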