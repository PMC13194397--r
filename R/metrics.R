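# Faithfulness metrics (deletion/insertion perturbation curves with AUPC,
# ADCC) and filter/attribution validation statistics (binarization, IoU and
# Dice, Mann-Whitney U, Cohen's d, Spearman rank correlation, baselines).

#' Faithfulness-curve configuration
#' @param steps number of perturbation steps K (curve has K + 1 points).
#' @param baseline baseline-input recipe: `"input-mean"` (per-mel-bin mean
#'   of the input, spectrally neutral), `"silence"` (the log-mel floor) or
#'   `"zeros"` (literal zero matrix).
#' @return validated config list.
#' @export
faithfulnessConfig <- function(steps = 20L, baseline = "input-mean") {
  stopifnot2(steps >= 2, "need at least 2 steps")
  stopifnot2(baseline %in% c("input-mean", "silence", "zeros"),
             "unknown baseline recipe")
  list(steps = as.integer(steps), baseline = baseline)
}

baselineInput <- function(S, recipe) {
  switch(recipe,
         "input-mean" = matrix(rowMeans(S), nrow(S), ncol(S)),
         "silence" = matrix(log(1e-6), nrow(S), ncol(S)),
         "zeros" = matrix(0, nrow(S), ncol(S)))
}

# descending relevance with deterministic ties: ascending time then
# frequency = ascending column-major index of the nMel x T matrix
rankBins <- function(raw) order(-as.vector(raw), seq_along(raw))

#' Deletion and insertion perturbation curves with AUPC
#'
#' Bins are ranked by raw relevance (ties broken by grid order, ascending
#' time then frequency). Deletion replaces the top `k/K` fraction with the
#' baseline and records the class probability; insertion starts from the
#' baseline and restores the top fraction. Step 0 is included (full input
#' for deletion, pure baseline for insertion); AUPC is the trapezoidal area
#' over the fraction axis.
#'
#' @param model a [KeywordModel-class] (or any function
#'   `(S, severity) -> probability vector`).
#' @param S log-mel spectrogram.
#' @param severity AQ score.
#' @param map a [RelevanceMap-class] on the same grid as `S`.
#' @param targetClass 0-based class index.
#' @param config a [faithfulnessConfig()].
#' @return list of two curves (`deletion`, `insertion`), each with `probs`
#'   (length K + 1) and `aupc`, plus the `baseline` recipe used.
#' @export
deletionInsertion <- function(model, S, severity, map, targetClass,
                              config = faithfulnessConfig()) {
  raw <- relevanceRaw(map)
  stopifnot2(identical(dim(raw), dim(S)),
             "relevance map grid must equal the input grid")
  f <- asProbFun(model)
  B <- baselineInput(S, config$baseline)
  ord <- rankBins(raw)
  K <- config$steps
  nBins <- length(S)
  delP <- insP <- numeric(K + 1)
  for (k in 0:K) {
    nTop <- round(k / K * nBins)
    top <- if (nTop > 0) ord[seq_len(nTop)] else integer(0)
    xDel <- S; xDel[top] <- B[top]
    xIns <- B; xIns[top] <- S[top]
    delP[k + 1] <- f(xDel, severity)[targetClass + 1L]
    insP[k + 1] <- f(xIns, severity)[targetClass + 1L]
  }
  trap <- function(p) sum((p[-1] + p[-length(p)]) / 2) / K
  list(deletion = list(kind = "deletion", probs = delP, aupc = trap(delP)),
       insertion = list(kind = "insertion", probs = insP, aupc = trap(insP)),
       baseline = config$baseline)
}

asProbFun <- function(model) {
  if (is.function(model)) return(model)
  function(S, severity) predictProbs(model, S, severity)
}

#' Combine ADCC components
#'
#' Harmonic mean of coherency, `1 - complexity` and `1 - averageDrop`; zero
#' if any of the three terms is non-positive.
#' @param coherency,complexity,averageDrop components in `[0, 1]`.
#' @return ADCC value in `[0, 1]`.
#' @export
adccCombine <- function(coherency, complexity, averageDrop) {
  terms <- c(coherency, 1 - complexity, 1 - averageDrop)
  if (any(terms <= 0)) return(0)
  3 / sum(1 / terms)
}

#' Average drop, coherency, complexity (ADCC)
#'
#' Average drop is the relative confidence loss when the model sees only the
#' map-masked input; complexity is the mean absolute value of the display
#' map; coherency is the Pearson correlation (clipped to `[0, 1]`) between
#' the display map and the display map recomputed on the masked input.
#' Masking defaults to the baseline blend `map * x + (1 - map) * B`
#' (consistent with the deletion/insertion baseline semantics on a log
#' spectrogram); `masking = "multiply"` applies the literal product.
#'
#' @param model a [KeywordModel-class] or probability function.
#' @param S log-mel spectrogram.
#' @param severity AQ score.
#' @param map a [RelevanceMap-class] on the grid of `S`.
#' @param targetClass 0-based class index.
#' @param mapFun function `maskedInput -> RelevanceMap` used to recompute
#'   the map for coherency (`NULL` falls back to [gradcamBaseline()], which
#'   requires `model` to be a [KeywordModel-class]).
#' @param masking `"blend"` or `"multiply"`.
#' @param baseline baseline recipe for the blend.
#' @return list with `averageDrop`, `coherency`, `complexity`, `adcc`.
#' @export
adcc <- function(model, S, severity, map, targetClass, mapFun = NULL,
                 masking = "blend", baseline = "input-mean") {
  disp <- relevanceDisplay(map)
  stopifnot2(identical(dim(disp), dim(S)),
             "relevance map grid must equal the input grid")
  f <- asProbFun(model)
  masked <- if (masking == "blend") {
    B <- baselineInput(S, baseline)
    disp * S + (1 - disp) * B
  } else S * disp
  px <- f(S, severity)[targetClass + 1L]
  pm <- f(masked, severity)[targetClass + 1L]
  averageDrop <- if (px <= 0) {
    warning("target-class probability is zero; average drop set to 0")
    0
  } else max(0, px - pm) / px
  complexity <- mean(abs(disp))
  if (is.null(mapFun))
    mapFun <- function(x) gradcamBaseline(model, x, severity, targetClass,
                                          branch(map))
  disp2 <- relevanceDisplay(mapFun(masked))
  coherency <- if (sd(disp) == 0 || sd(disp2) == 0) {
    if (isTRUE(all.equal(disp, disp2))) 1 else 0
  } else clamp(cor(as.vector(disp), as.vector(disp2)), 0, 1)
  list(averageDrop = averageDrop, coherency = coherency,
       complexity = complexity,
       adcc = adccCombine(coherency, complexity, averageDrop))
}

#' Binarize a relevance or filter map
#'
#' `"utterance-mean"`: strictly above the map mean. `"otsu"`: 256-bin
#' histogram threshold maximizing between-class variance (via
#' `EBImage::otsu`); a constant map yields all zeros with a warning.
#' @param values numeric vector or matrix.
#' @param method `"utterance-mean"` or `"otsu"`.
#' @return 0/1 object of the same shape.
#' @export
binarizeMap <- function(values, method = c("utterance-mean", "otsu")) {
  method <- match.arg(method)
  stopifnot2(length(values) > 0, "empty map")
  if (method == "utterance-mean") {
    out <- (values > mean(values)) * 1
  } else {
    rng <- range(values)
    if (rng[2] - rng[1] <= 0) {
      warning("constant map: Otsu threshold undefined, returning all zeros")
      return(values * 0)
    }
    thr <- EBImage::otsu(as.matrix(values), range = rng, levels = 256)
    out <- (values > thr) * 1
  }
  out
}

#' Frame-level IoU and Dice between binary masks
#'
#' Both conventions define 0/0 as 1 (two empty masks agree perfectly).
#' @param a,b binary vectors or matrices of equal length.
#' @return list with `iou` and `dice`.
#' @export
frameIouDice <- function(a, b) {
  stopifnot2(length(a) == length(b), "mask lengths differ")
  a <- as.numeric(a != 0); b <- as.numeric(b != 0)
  inter <- sum(a * b)
  un <- sum(pmax(a, b))
  size <- sum(a) + sum(b)
  if (un == 0) return(list(iou = 1, dice = 1))
  list(iou = inter / un, dice = 2 * inter / size)
}

#' Two-group comparison: Mann-Whitney U, Cohen's d, activation ratio
#'
#' Two-sided Mann-Whitney U test (exact where `stats::wilcox.test` supports
#' it, normal approximation otherwise), Cohen's d with pooled standard
#' deviation, and the ratio of group means.
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `U`, `p`, `cohensD`, `ratio`.
#' @export
groupStats <- function(a, b) {
  stopifnot2(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                   (na + nb - 2))
  d <- if (pooled == 0) {
    if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
  } else (mean(a) - mean(b)) / pooled
  list(U = unname(wt$statistic), p = wt$p.value, cohensD = d,
       ratio = mean(a) / mean(b))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho` and `p` (`rho = NA` for constant input).
#' @export
spearmanStat <- function(x, y) {
  stopifnot2(length(x) == length(y) && length(x) >= 3,
             "need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

#' Reference relevance baselines
#'
#' `"energy"`: per-frame RMS (from the linear mel power) broadcast over
#' bins, min-max normalized; `"inverted-energy"`: its complement (a naive
#' pause detector); `"random"`: the reference map with temporally shuffled
#' columns, averaged over `nTrials` shuffles.
#' @param S log-mel spectrogram.
#' @param kind `"energy"`, `"inverted-energy"` or `"random"`.
#' @param refMap [RelevanceMap-class] to shuffle (required for
#'   `"random"`).
#' @param nTrials shuffle count for the random baseline.
#' @param seed RNG seed for the shuffles.
#' @return a [RelevanceMap-class].
#' @export
baselineMaps <- function(S, kind = c("energy", "inverted-energy", "random"),
                         refMap = NULL, nTrials = 50L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random") {
    stopifnot2(!is.null(refMap), "random baseline needs a reference map")
    raw0 <- relevanceRaw(refMap)
    acc <- raw0 * 0
    withSeed(seed, for (i in seq_len(nTrials)) {
      acc <- acc + raw0[, sample(ncol(raw0)), drop = FALSE]
    })
    raw <- acc / nTrials
    tc <- refMap@targetClass
  } else {
    rms <- sqrt(colMeans(exp(S)))
    rng <- range(rms)
    em <- if (rng[2] - rng[1] <= 0) rms * 0
          else (rms - rng[1]) / (rng[2] - rng[1])
    v <- if (kind == "energy") em else 1 - em
    raw <- matrix(rep(v, each = nrow(S)), nrow(S))
    tc <- 0L
  }
  methods::new("RelevanceMap", branch = "baseline", raw = unname(raw),
               display = unname(displayCopy(raw)), fps = 100,
               targetClass = as.integer(tc),
               provenance = list(method = paste0("baseline-", kind)))
}

#' Temporal activation profile of a relevance map
#' @param map a [RelevanceMap-class].
#' @return numeric per-frame mean over frequency bins of the raw map.
#' @export
temporalProfile <- function(map) colMeans(relevanceRaw(map))

#' Ground-truth anomaly mask of an utterance
#'
#' Union of all truth anomaly intervals rasterized on a frame grid.
#' @param utt an [Utterance-class].
#' @param fps frames per second.
#' @param nFrames frame count.
#' @param types which truth-interval types to include.
#' @return 0/1 numeric vector.
#' @export
truthMask <- function(utt, fps, nFrames,
                      types = c("pause", "mispronunciation", "boundary")) {
  iv <- do.call(rbind, lapply(truthIntervals(utt)[types], asIntervals))
  maskValues(intervalsToMask(iv, fps, nFrames, "mispronunciation"))
}

#' Frame-level IoU of a relevance map against truth error regions
#'
#' The map's temporal profile is binarized (utterance-mean threshold by
#' default) and compared with the rasterized union of the utterance's truth
#' anomaly intervals.
#' @param map a [RelevanceMap-class].
#' @param utt the corresponding [Utterance-class].
#' @param method binarization method (see [binarizeMap()]).
#' @param types truth-interval types to count as error regions.
#' @return list with `iou` and `dice`.
#' @export
mapTruthIoU <- function(map, utt, method = "utterance-mean",
                        types = c("pause", "mispronunciation", "boundary")) {
  prof <- temporalProfile(map)
  pred <- binarizeMap(prof, method)
  truth <- truthMask(utt, framesPerSecond(map), length(prof), types)
  frameIouDice(pred, truth)
}
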