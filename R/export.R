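# Artifact export: relevance-map archives, PNG overlays, provenance.

# viridis-like ramp without extra dependencies
heatColors <- function(n = 256) {
  grDevices::colorRamp(c("#440154", "#31688E", "#35B779", "#FDE725"))(
    seq(0, 1, length.out = n)) / 255
}

# spectrogram (grayscale) with the display map blended on top
renderOverlay <- function(S, display, alpha = 0.45) {
  gs <- (S - min(S)) / max(1e-12, diff(range(S)))
  ramp <- heatColors(256)
  idx <- pmin(255L, pmax(0L, as.integer(round(display * 255)))) + 1L
  h <- nrow(S); w <- ncol(S)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    heat <- matrix(ramp[idx, ch], h, w)
    img[, , ch] <- (1 - alpha * display) * gs + alpha * display * heat
  }
  # flip so low frequencies sit at the bottom of the image
  img[rev(seq_len(h)), , , drop = FALSE]
}

#' Export a dual explanation to disk
#'
#' Writes, per branch, an `.rds` archive of the raw and display maps with
#' their grid metadata, a PNG overlay of the display map on the utterance's
#' mel spectrogram, plus a provenance JSON (tool version, configuration
#' hash, input digests, timestamp) and the aphasia-filter values as CSV.
#' @param expl a [DualExplanation-class].
#' @param outDir output directory (created if needed).
#' @param utt the explained [Utterance-class] (for the spectrogram
#'   background; optional).
#' @param stem file-name stem.
#' @param inputFiles optional named character vector of input paths whose
#'   digests go into the provenance record.
#' @return named character vector of the written paths, invisibly.
#' @export
exportExplanation <- function(expl, outDir, utt = NULL, stem = "explanation",
                              inputFiles = character(0)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ok <- dir.exists(outDir)
  stopifnot2(ok, paste("cannot create output directory:", outDir))
  paths <- character(0)
  S <- if (!is.null(utt))
    logMelSpectrogram(waveform(utt), sampleRate(utt)) else NULL
  for (br in c("prediction", "impairment")) {
    map <- if (br == "prediction") predictionMap(expl) else impairmentMap(expl)
    arr <- list(raw = relevanceRaw(map), display = relevanceDisplay(map),
                fps = framesPerSecond(map), branch = br,
                targetClass = map@targetClass, provenance = map@provenance)
    p <- file.path(outDir, sprintf("%s_%s.rds", stem, br))
    saveRDS(arr, p, version = 2)
    paths[paste0("map_", br)] <- p
    bg <- if (is.null(S)) relevanceDisplay(map) * 0 else S
    png_ <- file.path(outDir, sprintf("%s_%s.png", stem, br))
    png::writePNG(renderOverlay(bg, relevanceDisplay(map)), png_)
    paths[paste0("png_", br)] <- png_
  }
  afPath <- file.path(outDir, paste0(stem, "_filter.csv"))
  af <- explanationFilter(expl)
  masks <- componentMasks(af)
  utils::write.csv(data.frame(
    frame = seq_along(filterValues(af)) - 1L, af = filterValues(af),
    pause = maskValues(masks$pause),
    mispronunciation = maskValues(masks$mispronunciation),
    boundary = maskValues(masks$boundary)), afPath, row.names = FALSE)
  paths["filter"] <- afPath
  prov <- list(
    tool = "acamspeech",
    version = as.character(utils::packageVersion("acamspeech")),
    configHash = predictionMap(expl)@provenance$configHash %||% NA,
    predictedClass = expl@predictedClass,
    probability = expl@probability,
    inputDigests = if (length(inputFiles))
      as.list(tools::md5sum(inputFiles)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  provPath <- file.path(outDir, paste0(stem, "_provenance.json"))
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA)
  paths["provenance"] <- provPath
  invisible(paths)
}
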