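# Central S4 data objects. Configuration bundles are plain validated lists
# (see their constructors); the classes here carry data between modules and
# enforce the structural invariants the pipeline relies on.

checkTier <- function(tier, what, duration, tol = 1e-6) {
  if (NROW(tier) == 0) return(NULL)
  if (!all(c("start", "end") %in% names(tier)))
    return(sprintf("%s tier needs 'start' and 'end' columns", what))
  if (any(tier$end < tier$start - tol))
    return(sprintf("%s tier has negative-length interval", what))
  if (any(tier$start < -tol) || any(tier$end > duration + tol))
    return(sprintf("%s tier exceeds waveform span [0, %.4f]", what, duration))
  if (NROW(tier) > 1) {
    if (is.unsorted(tier$start))
      return(sprintf("%s tier is not time-sorted", what))
    if (any(tier$start[-1] < tier$end[-NROW(tier)] - tol))
      return(sprintf("%s tier has overlapping intervals", what))
  }
  NULL
}

#' Utterance: waveform plus annotation tiers
#'
#' The unit of analysis: a mono waveform with its canonical phoneme sequence,
#' produced phoneme tier, word tier, severity score (Aphasia Quotient, AQ;
#' lower = more severe), keyword class, correctness label and, for synthetic
#' utterances, the ground-truth intervals of every planted anomaly.
#'
#' Validity enforces: tiers time-sorted and non-overlapping, all endpoints
#' within the waveform span, and `correctness == TRUE` exactly when the
#' mispronunciation and boundary truth-interval lists are empty.
#'
#' @slot waveform numeric samples in `[-1, 1]`.
#' @slot sampleRate sampling rate in Hz.
#' @slot canonicalPhonemes character vector of target phoneme symbols.
#' @slot producedTier data.frame `(symbol, start, end)` in seconds.
#' @slot wordTier data.frame `(word, start, end)` in seconds.
#' @slot severity AQ score.
#' @slot keywordId integer class id in `[0, 14]`.
#' @slot correctness logical production-correctness label.
#' @slot truthIntervals named list of data.frames `(start, end)` per anomaly
#'   type (`pause`, `mispronunciation`, `boundary`).
#' @export
setClass("Utterance", representation(
  waveform = "numeric", sampleRate = "numeric",
  canonicalPhonemes = "character",
  producedTier = "data.frame", wordTier = "data.frame",
  severity = "numeric", keywordId = "integer", correctness = "logical",
  truthIntervals = "list"),
  validity = function(object) {
    dur <- length(object@waveform) / object@sampleRate
    errs <- c(
      checkTier(object@producedTier, "produced-phoneme", dur),
      checkTier(object@wordTier, "word", dur))
    for (ty in names(object@truthIntervals)) {
      iv <- object@truthIntervals[[ty]]
      if (NROW(iv) > 0 && (any(iv$start < -1e-6) || any(iv$end > dur + 1e-6)))
        errs <- c(errs, sprintf("truth intervals of type '%s' outside span", ty))
    }
    expected <- NROW(object@truthIntervals$mispronunciation) == 0 &&
      NROW(object@truthIntervals$boundary) == 0
    if (!identical(object@correctness, expected))
      errs <- c(errs, "correctness flag inconsistent with truth intervals")
    if (length(errs)) errs else TRUE
  })

#' AnomalyMask: binary per-frame indicator of one anomaly type
#'
#' @slot type one of `"pause"`, `"mispronunciation"`, `"boundary"`.
#' @slot values numeric 0/1 vector on a frame grid.
#' @slot fps frames per second of the grid.
#' @export
setClass("AnomalyMask", representation(
  type = "character", values = "numeric", fps = "numeric"),
  validity = function(object) {
    errs <- character(0)
    if (!object@type %in% c("pause", "mispronunciation", "boundary"))
      errs <- c(errs, "unknown anomaly type")
    if (!all(object@values %in% c(0, 1)))
      errs <- c(errs, "mask values must be binary")
    if (object@fps <= 0) errs <- c(errs, "fps must be positive")
    if (length(errs)) errs else TRUE
  })

#' CompositeFilter: the weighted aphasia filter AF over time
#'
#' Per frame, the exact weighted sum of the three binary anomaly masks; the
#' component masks and weights are retained for reporting.
#'
#' @slot values non-negative numeric vector on a frame grid.
#' @slot fps frames per second.
#' @slot masks named list of [AnomalyMask-class] objects.
#' @slot weights named numeric `(pause, mispronunciation, boundary)`.
#' @export
setClass("CompositeFilter", representation(
  values = "numeric", fps = "numeric", masks = "list", weights = "numeric"),
  validity = function(object) {
    errs <- character(0)
    if (any(object@values < -1e-12)) errs <- c(errs, "AF values must be >= 0")
    if (length(object@weights) == 3 &&
        any(object@values > sum(object@weights) + 1e-9))
      errs <- c(errs, "AF values exceed the sum of weights")
    if (length(errs)) errs else TRUE
  })

#' FeatureTap: an intermediate feature map exposed by the classifier
#'
#' @slot branch `"prediction"` (CNN block output, frequency axis retained via
#'   `freqAxis`) or `"impairment"` (transformer block output, temporal only).
#' @slot values `T x K` matrix (time frames by channels).
#' @slot fps frames per second of the tap's time axis.
#' @slot freqAxis integer vector of length K mapping each channel to its
#'   frequency-block index (empty when no frequency axis is retained).
#' @slot freqCenters numeric mel-bin centers of the frequency blocks.
#' @export
setClass("FeatureTap", representation(
  branch = "character", values = "matrix", fps = "numeric",
  freqAxis = "integer", freqCenters = "numeric"),
  validity = function(object) {
    errs <- character(0)
    if (!object@branch %in% c("prediction", "impairment"))
      errs <- c(errs, "branch must be 'prediction' or 'impairment'")
    if (nrow(object@values) < 1 || ncol(object@values) < 1)
      errs <- c(errs, "tap must have at least one frame and one channel")
    if (object@fps <= 0) errs <- c(errs, "fps must be positive")
    if (length(object@freqAxis) &&
        length(object@freqAxis) != ncol(object@values))
      errs <- c(errs, "freqAxis length must equal channel count")
    if (length(errs)) errs else TRUE
  })

#' GradientMap: class-score gradient with respect to a feature tap
#'
#' @slot branch branch tag, matching its tap.
#' @slot values matrix shaped like the tap's values.
#' @export
setClass("GradientMap", representation(branch = "character", values = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@values))) "gradient values must be finite" else TRUE
  })

#' ModelOutputs: logits, probabilities and both feature taps
#'
#' @slot logits numeric vector of class scores.
#' @slot probabilities softmax of the logits.
#' @slot taps named list of [FeatureTap-class] (`prediction`, `impairment`).
#' @export
setClass("ModelOutputs", representation(
  logits = "numeric", probabilities = "numeric", taps = "list"),
  validity = function(object) {
    errs <- character(0)
    if (abs(sum(object@probabilities) - 1) > 1e-6)
      errs <- c(errs, "probabilities must sum to 1")
    if (which.max(object@logits) != which.max(object@probabilities))
      errs <- c(errs, "argmax of logits and probabilities disagree")
    if (length(errs)) errs else TRUE
  })

#' RelevanceMap: a time-frequency attribution map
#'
#' Raw values drive all metrics; the display copy is a min-max normalized
#' twin used only where a metric's definition requires `[0, 1]`.
#'
#' @slot branch branch tag.
#' @slot raw `nMel x T` matrix on the spectrogram grid.
#' @slot display min-max normalized copy of `raw` in `[0, 1]`.
#' @slot fps frames per second of the time axis.
#' @slot targetClass integer class the map explains (0-based).
#' @slot provenance list with the configuration hash and method tag.
#' @export
setClass("RelevanceMap", representation(
  branch = "character", raw = "matrix", display = "matrix", fps = "numeric",
  targetClass = "integer", provenance = "list"),
  validity = function(object) {
    errs <- character(0)
    if (!identical(dim(object@raw), dim(object@display)))
      errs <- c(errs, "raw and display grids differ")
    if (any(object@display < -1e-12) || any(object@display > 1 + 1e-12))
      errs <- c(errs, "display values must lie in [0, 1]")
    if (which.max(object@raw) != which.max(object@display))
      errs <- c(errs, "raw and display argmax differ")
    if (length(errs)) errs else TRUE
  })

#' DualExplanation: the two complementary A-CAM maps for one utterance
#'
#' @slot prediction CNN-branch [RelevanceMap-class] (no aphasia filter).
#' @slot impairment transformer-branch [RelevanceMap-class], gated by the
#'   aphasia filter.
#' @slot filter the [CompositeFilter-class] used for gating.
#' @slot predictedClass 0-based argmax class of the classifier.
#' @slot probability predicted-class probability.
#' @export
setClass("DualExplanation", representation(
  prediction = "RelevanceMap", impairment = "RelevanceMap",
  filter = "CompositeFilter", predictedClass = "integer",
  probability = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@prediction@raw), dim(object@impairment@raw)))
      "prediction and impairment maps must share the output grid" else TRUE
  })

#' KeywordModel: the FiLM-conditioned spectrogram keyword classifier
#'
#' A compact CNN front-end, single-block transformer encoder, severity-driven
#' FiLM modulation, and MLP head, with hand-written forward/backward passes
#' exposing the feature-tap and class-gradient contract of the attribution
#' core.
#'
#' @slot config model configuration list (see [modelConfig()]).
#' @slot params named list of weight matrices/vectors.
#' @slot trainSeed seed used for initialization/training.
#' @slot trained logical.
#' @export
setClass("KeywordModel", representation(
  config = "list", params = "list", trainSeed = "integer",
  trained = "logical"))

#' DatasetManifest: index of a generated synthetic dataset
#'
#' @slot entries data.frame with one row per utterance (paths, keyword id,
#'   severity, correctness, speaker surrogate, split tag).
#' @slot seed generator seed.
#' @slot parameters generator parameter snapshot.
#' @export
setClass("DatasetManifest", representation(
  entries = "data.frame", seed = "integer", parameters = "list"),
  validity = function(object) {
    e <- object@entries
    if (NROW(e) == 0) return(TRUE)
    bad <- vapply(split(e$split, e$speaker),
                  function(s) length(unique(s)) > 1, logical(1))
    if (any(bad)) "speaker surrogates must not span splits" else TRUE
  })
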