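# Multimodal aphasia filter: pause detection by short-time energy VAD,
# phoneme mispronunciation spans by unit-cost edit-distance alignment of the
# canonical sequence against the produced tier, word-boundary deviations by
# tier-gap analysis; binary masks rasterized by frame-center containment and
# combined into the weighted composite filter AF.

#' Voice-activity-detection configuration
#'
#' Short-time log-energy thresholding: frames below `thresholdDb` (dBFS,
#' full scale = 1) are silence; maximal silent runs at least `minPause`
#' seconds long are reported as pauses.
#' @param frameLength analysis frame in seconds.
#' @param hop hop in seconds (must not exceed `frameLength`).
#' @param thresholdDb energy threshold in dBFS.
#' @param minPause minimum pause duration in seconds (the pause threshold).
#' @return validated config list.
#' @export
vadConfig <- function(frameLength = 0.025, hop = 0.010, thresholdDb = -40,
                      minPause = 0.25) {
  stopifnot2(minPause > 0, "minPause must be positive")
  stopifnot2(hop <= frameLength, "hop must not exceed frameLength")
  list(frameLength = frameLength, hop = hop, thresholdDb = thresholdDb,
       minPause = minPause)
}

#' Word-boundary configuration
#' @param maxGap largest tolerated inter-word gap in seconds.
#' @return validated config list.
#' @export
boundaryConfig <- function(maxGap = 0.30) {
  stopifnot2(maxGap > 0, "maxGap must be positive")
  list(maxGap = maxGap)
}

#' Aphasia-filter weights
#'
#' Non-negative weights of the pause, mispronunciation and word-boundary
#' masks in the composite filter. Defaults follow the reference weighting
#' (1.0, 1.2, 1.5): boundary disruptions weighted highest, then phoneme
#' mismatches, with a baseline weight for pauses.
#' @param pause,mispronunciation,boundary non-negative weights.
#' @return named numeric vector of length 3.
#' @export
filterWeights <- function(pause = 1.0, mispronunciation = 1.2,
                          boundary = 1.5) {
  w <- c(pause = pause, mispronunciation = mispronunciation,
         boundary = boundary)
  stopifnot2(all(w >= 0), "filter weights must be non-negative")
  w
}

#' Detect pauses with energy-based voice-activity detection
#'
#' @param samples waveform in `[-1, 1]`.
#' @param config a [vadConfig()].
#' @param sampleRate sampling rate in Hz.
#' @return data.frame `(start, end)` of pause intervals in seconds, sorted
#'   and non-overlapping (possibly empty).
#' @export
detectPauses <- function(samples, config = vadConfig(),
                         sampleRate = SAMPLE_RATE) {
  stopifnot2(length(samples) > 0, "empty waveform")
  win <- as.integer(round(config$frameLength * sampleRate))
  hop <- as.integer(round(config$hop * sampleRate))
  e <- frameEnergyDb(samples, win, hop)
  if (!length(e)) {
    # shorter than one frame: judge the whole signal at once
    db <- 10 * log10(mean(samples^2) + 1e-12)
    if (db < config$thresholdDb &&
        length(samples) / sampleRate >= config$minPause)
      return(data.frame(start = 0, end = length(samples) / sampleRate))
    return(emptyIntervals())
  }
  silent <- e < config$thresholdDb
  runs <- rle(silent)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    t0 <- (starts[i] - 1L) * hop / sampleRate
    t1 <- ((ends[i] - 1L) * hop + win) / sampleRate
    if (t1 - t0 >= config$minPause)
      out[[length(out) + 1L]] <- c(t0, t1)
  }
  if (!length(out)) return(emptyIntervals())
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# independent of alignment: minimal-edit-distance DP with deterministic
# backtrace (prefer diagonal, then canonical-advancing deletion, then
# insertion among equal-cost moves)
#' Align canonical phonemes against the produced tier
#'
#' Unit-cost minimal edit distance between the canonical symbol sequence and
#' the produced tier's symbols. Each non-match operation carries the time
#' span of the produced segment involved; deletions (canonical phoneme with
#' no produced segment) borrow the midpoint gap between flanking produced
#' segments, widened to at least one 10 ms frame.
#'
#' @param canonical character vector of canonical phoneme symbols.
#' @param produced data.frame `(symbol, start, end)` produced tier (may have
#'   zero rows).
#' @return data.frame of edit operations `(kind, canonicalIndex,
#'   producedIndex, start, end)` with `kind` in
#'   `match/substitution/insertion/deletion`.
#' @export
alignPhonemes <- function(canonical, produced) {
  stopifnot2(length(canonical) > 0, "canonical sequence must be non-empty")
  prodSym <- if (NROW(produced)) as.character(produced$symbol) else character(0)
  n <- length(canonical); m <- length(prodSym)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cost <- if (canonical[i] == prodSym[j]) 0L else 1L
    D[i + 1L, j + 1L] <- min(D[i, j] + cost, D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L)
  }
  ops <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i + 1L, j + 1L] ==
          D[i, j] + (canonical[i] != prodSym[j])) {
      kind <- if (canonical[i] == prodSym[j]) "match" else "substitution"
      ops[[length(ops) + 1L]] <- list(kind = kind, ci = i, pi = j)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ops[[length(ops) + 1L]] <- list(kind = "deletion", ci = i, pi = NA_integer_)
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- list(kind = "insertion", ci = NA_integer_, pi = j)
      j <- j - 1L
    }
  }
  ops <- rev(ops)
  minSpan <- 0.010
  # spans: walk ops tracking the last produced index for deletion gaps
  out <- data.frame(kind = character(0), canonicalIndex = integer(0),
                    producedIndex = integer(0), start = numeric(0),
                    end = numeric(0))
  lastProd <- 0L
  for (op in ops) {
    if (op$kind %in% c("match", "substitution", "insertion")) {
      s <- produced$start[op$pi]; e <- produced$end[op$pi]
      if (op$kind != "match" && e - s < minSpan) e <- s + minSpan
      lastProd <- op$pi
    } else {
      leftEnd <- if (lastProd >= 1L) produced$end[lastProd] else 0
      rightStart <- if (lastProd < m) produced$start[lastProd + 1L]
                    else if (m > 0) produced$end[m] else 0
      mid <- (leftEnd + rightStart) / 2
      s <- mid - minSpan / 2; e <- mid + minSpan / 2
      if (s < 0) { e <- e - s; s <- 0 }
    }
    out <- rbind(out, data.frame(
      kind = op$kind, canonicalIndex = op$ci %||% NA_integer_,
      producedIndex = op$pi %||% NA_integer_, start = s, end = e))
  }
  attr(out, "distance") <- D[n + 1L, m + 1L]
  out
}

#' Detect word-boundary errors from the word tier
#'
#' Flags the gap between each pair of consecutive words whose separation
#' exceeds `config$maxGap`.
#' @param words data.frame `(word, start, end)` word tier, time-sorted.
#' @param config a [boundaryConfig()].
#' @return data.frame `(start, end)` of flagged gap intervals.
#' @export
detectBoundaryErrors <- function(words, config = boundaryConfig()) {
  if (NROW(words) < 2) return(emptyIntervals())
  stopifnot2(!is.unsorted(words$start), "word tier must be time-sorted")
  gaps <- words$start[-1] - words$end[-NROW(words)]
  hit <- which(gaps > config$maxGap)
  if (!length(hit)) return(emptyIntervals())
  data.frame(start = words$end[hit], end = words$start[hit + 1])
}

#' Rasterize intervals into a binary frame mask
#'
#' Frame `t` (0-based) is set to 1 iff its center `(t + 0.5) / fps` falls
#' inside any half-open interval `[start, end)`.
#' @param intervals data.frame `(start, end)` in seconds.
#' @param fps frames per second of the target grid.
#' @param nFrames number of frames.
#' @param type anomaly type tag (`pause`, `mispronunciation`, `boundary`).
#' @return an [AnomalyMask-class].
#' @export
intervalsToMask <- function(intervals, fps, nFrames, type) {
  intervals <- asIntervals(intervals)
  stopifnot2(all(intervals$start >= 0) && all(intervals$end >= 0),
             "negative interval endpoints")
  v <- numeric(nFrames)
  if (NROW(intervals)) {
    centers <- ((seq_len(nFrames) - 1) + 0.5) / fps
    for (i in seq_len(NROW(intervals)))
      v[centers >= intervals$start[i] & centers < intervals$end[i]] <- 1
  }
  methods::new("AnomalyMask", type = type, values = v, fps = fps)
}

#' Build the weighted composite aphasia filter
#'
#' Per frame, exactly `AF[t] = w_P M_P[t] + w_M M_M[t] + w_WB M_WB[t]`.
#' @param masks named list of the three [AnomalyMask-class] objects (`pause`,
#'   `mispronunciation`, `boundary`) on a shared frame grid.
#' @param weights a [filterWeights()] vector.
#' @return a [CompositeFilter-class].
#' @export
buildCompositeFilter <- function(masks, weights = filterWeights()) {
  need <- c("pause", "mispronunciation", "boundary")
  stopifnot2(all(need %in% names(masks)), "need pause/mispronunciation/boundary masks")
  masks <- masks[need]
  lens <- vapply(masks, function(m) length(maskValues(m)), integer(1))
  fpss <- vapply(masks, framesPerSecond, numeric(1))
  stopifnot2(length(unique(lens)) == 1 && length(unique(fpss)) == 1,
             "masks must share one frame grid")
  af <- weights[["pause"]] * maskValues(masks$pause) +
    weights[["mispronunciation"]] * maskValues(masks$mispronunciation) +
    weights[["boundary"]] * maskValues(masks$boundary)
  methods::new("CompositeFilter", values = af, fps = fpss[[1]],
               masks = masks, weights = weights)
}

#' Resample a composite filter onto a feature tap's frame grid
#'
#' Nearest-frame-center mapping; mask weights are carried over unchanged
#' (no interpolation across anomaly borders).
#' @param filter a [CompositeFilter-class].
#' @param nFrames target frame count.
#' @param fps target frames per second.
#' @return a [CompositeFilter-class] on the target grid.
#' @export
resampleFilter <- function(filter, nFrames, fps) {
  stopifnot2(nFrames >= 1, "zero-length resample target")
  if (nFrames == length(filterValues(filter)) &&
      isTRUE(all.equal(fps, framesPerSecond(filter)))) return(filter)
  masks <- lapply(componentMasks(filter), function(m)
    methods::new("AnomalyMask", type = m@type,
                 values = nearestResample(maskValues(m), nFrames), fps = fps))
  methods::new("CompositeFilter",
               values = nearestResample(filterValues(filter), nFrames),
               fps = fps, masks = masks, weights = filter@weights)
}

#' Build the aphasia filter for an annotated utterance
#'
#' Runs pause, mispronunciation and boundary detection on the utterance's
#' waveform and tiers and combines the rasterized masks into the weighted
#' composite filter.
#' @param utt an [Utterance-class].
#' @param weights [filterWeights()].
#' @param vad [vadConfig()].
#' @param boundary [boundaryConfig()].
#' @param fps frame rate of the filter grid (default 100, matching the
#'   spectrogram hop).
#' @return a [CompositeFilter-class].
#' @export
buildAphasiaFilter <- function(utt, weights = filterWeights(),
                               vad = vadConfig(), boundary = boundaryConfig(),
                               fps = 100) {
  dur <- length(waveform(utt)) / sampleRate(utt)
  nFrames <- max(1L, as.integer(floor(dur * fps)))
  pauses <- detectPauses(waveform(utt), vad, sampleRate(utt))
  ops <- alignPhonemes(canonicalPhonemes(utt), producedTier(utt))
  mis <- ops[ops$kind != "match", c("start", "end"), drop = FALSE]
  gaps <- detectBoundaryErrors(wordTier(utt), boundary)
  masks <- list(
    pause = intervalsToMask(pauses, fps, nFrames, "pause"),
    mispronunciation = intervalsToMask(mis, fps, nFrames, "mispronunciation"),
    boundary = intervalsToMask(gaps, fps, nFrames, "boundary"))
  buildCompositeFilter(masks, weights)
}
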