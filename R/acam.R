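# A-CAM attribution core: adaptive perturbation with per-branch gradient
# accumulation, mean-square normalization, dual positive filtering, aphasia-
# filter gating (impairment branch only), segment-wise CAM computation and
# overlap-aware aggregation into the final dual relevance maps; plus a plain
# Grad-CAM baseline for comparison.

#' Adaptive-perturbation configuration
#'
#' Gaussian input noise of standard deviation `sigma` is added to the model
#' input; after each perturbation the magnitude grows by
#' `stepSize * mean(|G|)` of that perturbation's gradient, capped at `pMax`.
#' One sigma track per branch keeps the branches independent.
#' @param n number of perturbations N (0 disables).
#' @param sigma0 initial noise standard deviation.
#' @param pMax magnitude cap.
#' @param stepSize magnitude growth factor.
#' @param epsilon normalization constant of the gradient normalizer.
#' @param seed RNG seed for the noise draws.
#' @return validated config list.
#' @export
perturbationConfig <- function(n = 8L, sigma0 = 0.01, pMax = 0.1,
                               stepSize = 0.01, epsilon = 1e-5, seed = 1L) {
  stopifnot2(n >= 0, "n must be >= 0")
  stopifnot2(sigma0 >= 0 && sigma0 <= pMax, "need 0 <= sigma0 <= pMax")
  stopifnot2(stepSize >= 0, "stepSize must be >= 0")
  stopifnot2(epsilon > 0, "epsilon must be positive")
  list(n = as.integer(n), sigma0 = sigma0, pMax = pMax, stepSize = stepSize,
       epsilon = epsilon, seed = as.integer(seed))
}

#' Segment-aggregation configuration
#'
#' @param tseg segment length in tap frames.
#' @param overlap overlap ratio O in `[0, 1)`.
#' @param smoothWidth Gaussian smoothing kernel width in frames (0 disables).
#' @param outMel frequency bins of the output grid.
#' @return validated config list.
#' @export
segmentConfig <- function(tseg = 25L, overlap = 0.5, smoothWidth = 5,
                          outMel = 128L) {
  stopifnot2(tseg >= 1, "tseg must be >= 1")
  stopifnot2(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  list(tseg = as.integer(tseg), overlap = overlap,
       smoothWidth = smoothWidth, outMel = as.integer(outMel))
}

#' Accumulate class gradients under adaptive input perturbation
#'
#' Per branch: the base gradient plus the sum of `n` gradients at noisy
#' inputs `S + noise(sigma_p)`, with `sigma` updated after each perturbation
#' from the mean absolute gradient of that branch. Deterministic given the
#' config seed.
#' @param model a [KeywordModel-class].
#' @param S log-mel spectrogram.
#' @param severity AQ score.
#' @param targetClass 0-based class index.
#' @param config a [perturbationConfig()].
#' @return list with `gradients` (named list of accumulated matrices per
#'   branch) and `trace` (per-branch data.frame of `sigma` used and mean
#'   absolute gradient per step).
#' @export
accumulateGradients <- function(model, S, severity, targetClass,
                                config = perturbationConfig()) {
  if (config$n > 0 && config$sigma0 == 0 && config$stepSize == 0)
    warning("n > 0 with sigma0 = 0 and stepSize = 0: perturbations are no-ops")
  base <- classGradient(model, S, severity, targetClass)
  run <- function() {
    out <- list(); trace <- list()
    for (br in c("prediction", "impairment")) {
      G <- base[[br]]@values
      sigma <- config$sigma0
      sigmas <- numeric(0); gm <- numeric(0)
      if (config$n > 0) for (p in seq_len(config$n)) {
        noise <- matrix(rnorm(length(S)) * sigma, nrow(S))
        gp <- classGradient(model, S + noise, severity, targetClass)[[br]]@values
        G <- G + gp
        mAbs <- mean(abs(gp))
        sigmas <- c(sigmas, sigma); gm <- c(gm, mAbs)
        sigma <- min(config$pMax, sigma + config$stepSize * mAbs)
      }
      out[[br]] <- G
      trace[[br]] <- data.frame(sigma = sigmas, meanAbsGrad = gm)
    }
    list(gradients = out, trace = trace)
  }
  withSeed(config$seed, run())
}

#' Normalize accumulated gradients
#'
#' Divides by the scalar `mean(G^2) + epsilon` (mean square, as printed in
#' the reference formulation — not root-mean-square).
#' @param G gradient matrix.
#' @param epsilon stabilizing constant.
#' @return matrix of the same shape.
#' @export
normalizeGradients <- function(G, epsilon = 1e-5) {
  G / (mean(G^2) + epsilon)
}

#' Dual positive filtering of gradients
#'
#' Retains a cell only where both the feature activation and the normalized
#' gradient are positive: `G[t,k] * 1(F[t,k] > 0) * 1(G[t,k] > 0)`.
#' The result is non-negative everywhere.
#' @param G normalized gradient matrix.
#' @param F feature matrix of the same shape (tap values).
#' @return filtered gradient matrix.
#' @export
dualFilter <- function(G, F) {
  stopifnot2(identical(dim(G), dim(F)),
             "gradient and feature shapes must match")
  G * (F > 0) * (G > 0)
}

#' Gate a gradient map with the aphasia filter
#'
#' Per-frame multiplication of the filter values, broadcast over channels;
#' relevance is zero wherever the filter is zero.
#' @param G filtered gradient matrix (`T x K`).
#' @param af numeric filter values of length `T` (a resampled
#'   [CompositeFilter-class]'s values).
#' @return gated gradient matrix.
#' @export
gateWithFilter <- function(G, af) {
  stopifnot2(length(af) == nrow(G),
             sprintf("filter length %d does not match %d tap frames",
                     length(af), nrow(G)))
  G * af
}

#' Overlapping segment start/end indices
#'
#' Starts follow `j_m = round(m * tseg * (1 - O))` for `m = 0, 1, ...` until
#' the segments cover the last frame; the final segment is clipped at `T`.
#' A segment longer than the sequence degenerates to one full-span segment.
#' @param nFrames sequence length T.
#' @param config a [segmentConfig()].
#' @return data.frame `(start, end)` of 0-based, end-exclusive frame spans.
#' @export
segmentIndices <- function(nFrames, config = segmentConfig()) {
  stopifnot2(nFrames >= 1, "need at least one frame")
  tseg <- config$tseg
  if (tseg >= nFrames)
    return(data.frame(start = 0L, end = as.integer(nFrames)))
  stride <- tseg * (1 - config$overlap)
  starts <- integer(0); m <- 0L
  repeat {
    j <- as.integer(round(m * stride))
    if (j >= nFrames) break
    if (!length(starts) || j > starts[length(starts)])
      starts <- c(starts, j)
    m <- m + 1L
    stopifnot2(m < 10 * nFrames + 10L,
               "segment stride too small to make progress")
  }
  data.frame(start = starts,
             end = pmin(starts + tseg, as.integer(nFrames)))
}

#' Per-channel segment weights
#'
#' The channel weight is the mean of the (filtered, possibly gated) gradient
#' over the segment's frames, using the clipped segment's true length.
#' @param Gseg `t x K` gradient segment.
#' @return numeric weight vector of length K.
#' @export
segmentWeights <- function(Gseg) {
  colMeans(Gseg)
}

#' Segment-level class activation map
#'
#' `CAM[t] = sum_k alpha_k F[t, k]`. With a retained frequency axis the sum
#' runs within each frequency block, yielding a `t x nBlocks` map instead of
#' collapsing frequency.
#' @param alpha channel weights (length K).
#' @param Fseg `t x K` feature segment.
#' @param freqAxis optional integer channel-to-block map of length K.
#' @return numeric vector of length `t`, or a `t x nBlocks` matrix.
#' @export
segmentCam <- function(alpha, Fseg, freqAxis = NULL) {
  stopifnot2(length(alpha) == ncol(Fseg),
             "alpha length must equal the channel count")
  if (is.null(freqAxis) || !length(freqAxis))
    return(as.vector(Fseg %*% alpha))
  nb <- max(freqAxis)
  out <- matrix(0, nrow(Fseg), nb)
  for (f in seq_len(nb)) {
    k <- which(freqAxis == f)
    out[, f] <- Fseg[, k, drop = FALSE] %*% alpha[k]
  }
  out
}

# min-max display copy; a constant map maps to all zeros
displayCopy <- function(raw) {
  rng <- range(raw)
  if (rng[2] - rng[1] <= 0) return(raw * 0)
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Aggregate segment CAMs into a full relevance map
#'
#' Each segment CAM is rectified, Gaussian-smoothed along time, and placed on
#' a full-length canvas at its span; frames covered by several segments are
#' averaged by coverage count (which reduces to the plain mean over segments
#' when all segments share one support). The canvas is then linearly
#' resampled to the output time grid and expanded to the output frequency
#' axis: broadcast for temporal-only maps, interpolation over the retained
#' frequency-block centers otherwise.
#'
#' @param cams list of segment CAMs (vectors, or `t x nBlocks` matrices).
#' @param spans data.frame from [segmentIndices()] (0-based, end-exclusive).
#' @param nFrames tap-grid length T.
#' @param config a [segmentConfig()].
#' @param outFrames time frames of the output grid.
#' @param freqCenters mel-bin centers of frequency blocks (`NULL` for
#'   broadcast).
#' @param branch branch tag for the resulting map.
#' @param targetClass explained class (0-based).
#' @param fps output frames per second.
#' @param provenance provenance list stored in the map.
#' @return a [RelevanceMap-class].
#' @export
aggregateCams <- function(cams, spans, nFrames, config = segmentConfig(),
                          outFrames = nFrames, freqCenters = NULL,
                          branch = "impairment", targetClass = 0L,
                          fps = 100, provenance = list()) {
  stopifnot2(length(cams) >= 1, "empty CAM list")
  stopifnot2(length(cams) == NROW(spans), "one span per CAM required")
  stopifnot2(all(spans$start >= 0) && all(spans$end <= nFrames),
             "segment spans must lie within [0, nFrames)")
  nb <- if (is.matrix(cams[[1]])) ncol(cams[[1]]) else 1L
  canvas <- matrix(0, nFrames, nb)
  cover <- numeric(nFrames)
  for (i in seq_along(cams)) {
    cam <- cams[[i]]
    if (!is.matrix(cam)) cam <- matrix(cam, ncol = 1L)
    cam <- pmax(cam, 0)
    if (config$smoothWidth > 0)
      cam <- apply(cam, 2, gaussianSmooth1d, width = config$smoothWidth)
    if (!is.matrix(cam)) cam <- matrix(cam, ncol = nb)
    rows <- (spans$start[i] + 1L):spans$end[i]
    canvas[rows, ] <- canvas[rows, , drop = FALSE] + cam
    cover[rows] <- cover[rows] + 1
  }
  cover[cover == 0] <- 1
  canvas <- canvas / cover
  # time resize, then frequency expansion to the output grid
  timeRes <- apply(canvas, 2, linResample, nOut = outFrames)
  if (!is.matrix(timeRes)) timeRes <- matrix(timeRes, nrow = outFrames)
  raw <- if (nb == 1L || is.null(freqCenters)) {
    matrix(rep(rowMeans(timeRes), each = config$outMel), config$outMel)
  } else {
    # rows of timeRes are frames: expand each frame's block profile to the
    # mel axis, giving an outMel x outFrames grid
    apply(timeRes, 1, function(v)
      approx(freqCenters, v, xout = seq_len(config$outMel), rule = 2)$y)
  }
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = config$outMel)
  methods::new("RelevanceMap", branch = branch, raw = unname(raw),
               display = unname(displayCopy(raw)), fps = fps,
               targetClass = as.integer(targetClass),
               provenance = provenance)
}

branchCam <- function(Ggd, tap, segcfg, outFrames, branch, targetClass,
                      provenance) {
  Tn <- nrow(Ggd)
  spans <- segmentIndices(Tn, segcfg)
  freqAxis <- if (length(tap@freqAxis)) tap@freqAxis else NULL
  cams <- lapply(seq_len(NROW(spans)), function(i) {
    rows <- (spans$start[i] + 1L):spans$end[i]
    alpha <- segmentWeights(Ggd[rows, , drop = FALSE])
    segmentCam(alpha, tapValues(tap)[rows, , drop = FALSE], freqAxis)
  })
  aggregateCams(cams, spans, Tn, segcfg, outFrames = outFrames,
                freqCenters = if (!is.null(freqAxis)) tap@freqCenters,
                branch = branch, targetClass = targetClass, fps = 100,
                provenance = provenance)
}

#' Dual A-CAM explanation of one utterance
#'
#' Runs the full attribution pipeline per branch: adaptive-perturbation
#' gradient accumulation, mean-square normalization, dual positive
#' filtering, aphasia-filter gating (impairment branch only), segment-wise
#' CAM computation and overlap-aware aggregation. Deterministic given the
#' perturbation seed.
#'
#' @param model a trained [KeywordModel-class].
#' @param utt an [Utterance-class] with annotation tiers (required for the
#'   impairment branch).
#' @param targetClass 0-based class to explain (`NULL` = predicted class).
#' @param perturbation a [perturbationConfig()].
#' @param segments a [segmentConfig()].
#' @param weights aphasia-filter [filterWeights()].
#' @param vad a [vadConfig()].
#' @param boundary a [boundaryConfig()].
#' @param filter optional pre-built [CompositeFilter-class] overriding the
#'   utterance-derived aphasia filter (any fps; resampled to the tap grid).
#' @param dualFiltering apply the positive dual filter (disable for
#'   ablation).
#' @return a [DualExplanation-class].
#' @export
acamExplain <- function(model, utt, targetClass = NULL,
                        perturbation = perturbationConfig(),
                        segments = segmentConfig(),
                        weights = filterWeights(), vad = vadConfig(),
                        boundary = boundaryConfig(), filter = NULL,
                        dualFiltering = TRUE) {
  S <- logMelSpectrogram(waveform(utt), sampleRate(utt))
  out <- forwardWithTaps(model, S, severity(utt))
  if (is.null(targetClass)) targetClass <- which.max(out@logits) - 1L
  if (is.null(filter)) {
    stopifnot2(NROW(producedTier(utt)) > 0,
               "impairment branch needs the produced phoneme tier")
    stopifnot2(NROW(wordTier(utt)) > 0,
               "impairment branch needs the word tier")
    filter <- buildAphasiaFilter(utt, weights, vad, boundary, fps = 100)
  }
  acc <- accumulateGradients(model, S, severity(utt), targetClass,
                             perturbation)
  prov <- list(configHash = hashObject(list(perturbation = perturbation,
                                            segments = segments,
                                            weights = as.list(weights))),
               targetClass = targetClass)
  maps <- list()
  for (br in c("prediction", "impairment")) {
    tap <- out@taps[[br]]
    Gn <- normalizeGradients(acc$gradients[[br]], perturbation$epsilon)
    Ggd <- if (dualFiltering) dualFilter(Gn, tapValues(tap)) else pmax(Gn, 0)
    if (br == "impairment") {
      afTap <- resampleFilter(filter, nrow(tapValues(tap)), tap@fps)
      Ggd <- gateWithFilter(Ggd, filterValues(afTap))
    }
    maps[[br]] <- branchCam(Ggd, tap, segments, ncol(S), br, targetClass,
                            c(prov, list(method = paste0("acam-", br))))
  }
  methods::new("DualExplanation", prediction = maps$prediction,
               impairment = maps$impairment, filter = filter,
               predictedClass = which.max(out@logits) - 1L,
               probability = max(out@probabilities))
}

#' Plain Grad-CAM baseline
#'
#' Global-average-pooled gradient weights times the feature map, rectified
#' and resized to the output grid; no perturbation, no dual filtering, no
#' aphasia filter.
#' @param model a [KeywordModel-class].
#' @param S log-mel spectrogram.
#' @param severity AQ score.
#' @param targetClass 0-based class index.
#' @param branch `"prediction"` or `"impairment"` tap.
#' @return a [RelevanceMap-class].
#' @export
gradcamBaseline <- function(model, S, severity, targetClass,
                            branch = "impairment") {
  out <- forwardWithTaps(model, S, severity)
  tap <- out@taps[[branch]]
  G <- classGradient(model, S, severity, targetClass)[[branch]]@values
  alpha <- colMeans(G)
  freqAxis <- if (length(tap@freqAxis)) tap@freqAxis else NULL
  cam <- segmentCam(alpha, tapValues(tap), freqAxis)
  spans <- data.frame(start = 0L, end = nrow(tapValues(tap)))
  aggregateCams(list(cam), spans, nrow(tapValues(tap)),
                segmentConfig(tseg = nrow(tapValues(tap)), overlap = 0,
                              smoothWidth = 0),
                outFrames = ncol(S),
                freqCenters = if (!is.null(freqAxis)) tap@freqCenters,
                branch = branch, targetClass = targetClass, fps = 100,
                provenance = list(method = "gradcam"))
}
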