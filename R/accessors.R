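#' @rdname accessors
setMethod("waveform", "Utterance", function(x) x@waveform)
#' @rdname accessors
setMethod("sampleRate", "Utterance", function(x) x@sampleRate)
#' @rdname accessors
setMethod("producedTier", "Utterance", function(x) x@producedTier)
#' @rdname accessors
setMethod("wordTier", "Utterance", function(x) x@wordTier)
#' @rdname accessors
setMethod("canonicalPhonemes", "Utterance", function(x) x@canonicalPhonemes)
#' @rdname accessors
setMethod("severity", "Utterance", function(x) x@severity)
#' @rdname accessors
setMethod("keywordId", "Utterance", function(x) x@keywordId)
#' @rdname accessors
setMethod("correctness", "Utterance", function(x) x@correctness)
#' @rdname accessors
setMethod("truthIntervals", "Utterance", function(x) x@truthIntervals)

#' @rdname accessors
setMethod("filterValues", "CompositeFilter", function(x) x@values)
#' @rdname accessors
setMethod("framesPerSecond", "CompositeFilter", function(x) x@fps)
#' @rdname accessors
setMethod("componentMasks", "CompositeFilter", function(x) x@masks)
#' @rdname accessors
setMethod("maskValues", "AnomalyMask", function(x) x@values)
#' @rdname accessors
setMethod("framesPerSecond", "AnomalyMask", function(x) x@fps)
#' @rdname accessors
setMethod("tapValues", "FeatureTap", function(x) x@values)
#' @rdname accessors
setMethod("framesPerSecond", "FeatureTap", function(x) x@fps)
#' @rdname accessors
setMethod("branch", "FeatureTap", function(x) x@branch)
#' @rdname accessors
setMethod("branch", "GradientMap", function(x) x@branch)
#' @rdname accessors
setMethod("branch", "RelevanceMap", function(x) x@branch)
#' @rdname accessors
setMethod("relevanceRaw", "RelevanceMap", function(x) x@raw)
#' @rdname accessors
setMethod("relevanceDisplay", "RelevanceMap", function(x) x@display)
#' @rdname accessors
setMethod("framesPerSecond", "RelevanceMap", function(x) x@fps)
#' @rdname accessors
setMethod("predictionMap", "DualExplanation", function(x) x@prediction)
#' @rdname accessors
setMethod("impairmentMap", "DualExplanation", function(x) x@impairment)
#' @rdname accessors
setMethod("explanationFilter", "DualExplanation", function(x) x@filter)
#' @rdname accessors
setMethod("manifestEntries", "DatasetManifest", function(x) x@entries)

setMethod("show", "Utterance", function(object) {
  dur <- length(object@waveform) / object@sampleRate
  nAnom <- sum(vapply(object@truthIntervals, NROW, integer(1)))
  cat(sprintf(
    "Utterance: keyword %d, %.2f s, AQ %.1f, %s, %d phonemes, %d truth anomalies\n",
    object@keywordId, dur, object@severity,
    if (object@correctness) "correct" else "incorrect",
    NROW(object@producedTier), nAnom))
})

setMethod("show", "CompositeFilter", function(object) {
  cat(sprintf(
    "CompositeFilter: %d frames @ %g fps, mean AF %.3f, weights (P=%g, M=%g, WB=%g)\n",
    length(object@values), object@fps, mean(object@values),
    object@weights[1], object@weights[2], object@weights[3]))
})

setMethod("show", "FeatureTap", function(object) {
  cat(sprintf("FeatureTap [%s]: %d frames x %d channels @ %g fps%s\n",
              object@branch, nrow(object@values), ncol(object@values),
              object@fps,
              if (length(object@freqAxis)) " (frequency axis retained)" else ""))
})

setMethod("show", "RelevanceMap", function(object) {
  cat(sprintf("RelevanceMap [%s]: %d mel x %d frames, class %d, max raw %.3g\n",
              object@branch, nrow(object@raw), ncol(object@raw),
              object@targetClass, max(object@raw)))
})

setMethod("show", "DualExplanation", function(object) {
  cat(sprintf(
    "DualExplanation: class %d (p = %.3f); grids %d x %d; mean AF %.3f\n",
    object@predictedClass, object@probability,
    nrow(object@prediction@raw), ncol(object@prediction@raw),
    mean(object@filter@values)))
})

setMethod("show", "KeywordModel", function(object) {
  cat(sprintf(
    "KeywordModel: %d classes, H = %d, %s (seed %d), %d parameter tensors\n",
    object@config$nClasses, object@config$hiddenDim,
    if (object@trained) "trained" else "untrained",
    object@trainSeed, length(object@params)))
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d entries, %d speakers, splits {%s}, seed %d\n",
              NROW(object@entries),
              length(unique(object@entries$speaker)),
              paste(names(table(object@entries$split)), collapse = ", "),
              object@seed))
})
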