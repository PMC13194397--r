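# Accessor generics. Slots are never reached into from user code or other
# modules; everything goes through these.

#' @name accessors
#' @title Accessors for acamspeech S4 objects
#' @description Small accessor family: `waveform()`, `sampleRate()`,
#'   `producedTier()`, `wordTier()`, `canonicalPhonemes()`, `severity()`,
#'   `keywordId()`, `correctness()`, `truthIntervals()`, `filterValues()`,
#'   `framesPerSecond()`, `maskValues()`, `componentMasks()`, `tapValues()`,
#'   `branch()`, `relevanceRaw()`, `relevanceDisplay()`, `predictionMap()`,
#'   `impairmentMap()`, `explanationFilter()`, `manifestEntries()`.
#' @param x an acamspeech S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("producedTier", function(x) standardGeneric("producedTier"))
#' @rdname accessors
#' @export
setGeneric("wordTier", function(x) standardGeneric("wordTier"))
#' @rdname accessors
#' @export
setGeneric("canonicalPhonemes", function(x) standardGeneric("canonicalPhonemes"))
#' @rdname accessors
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))
#' @rdname accessors
#' @export
setGeneric("keywordId", function(x) standardGeneric("keywordId"))
#' @rdname accessors
#' @export
setGeneric("correctness", function(x) standardGeneric("correctness"))
#' @rdname accessors
#' @export
setGeneric("truthIntervals", function(x) standardGeneric("truthIntervals"))
#' @rdname accessors
#' @export
setGeneric("filterValues", function(x) standardGeneric("filterValues"))
#' @rdname accessors
#' @export
setGeneric("framesPerSecond", function(x) standardGeneric("framesPerSecond"))
#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname accessors
#' @export
setGeneric("componentMasks", function(x) standardGeneric("componentMasks"))
#' @rdname accessors
#' @export
setGeneric("tapValues", function(x) standardGeneric("tapValues"))
#' @rdname accessors
#' @export
setGeneric("branch", function(x) standardGeneric("branch"))
#' @rdname accessors
#' @export
setGeneric("relevanceRaw", function(x) standardGeneric("relevanceRaw"))
#' @rdname accessors
#' @export
setGeneric("relevanceDisplay", function(x) standardGeneric("relevanceDisplay"))
#' @rdname accessors
#' @export
setGeneric("predictionMap", function(x) standardGeneric("predictionMap"))
#' @rdname accessors
#' @export
setGeneric("impairmentMap", function(x) standardGeneric("impairmentMap"))
#' @rdname accessors
#' @export
setGeneric("explanationFilter", function(x) standardGeneric("explanationFilter"))
#' @rdname accessors
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))
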