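# Synthetic utterance generation: clean keyword rendering, severity-coupled
# anomaly specification, anomaly planting with exact ground truth, and
# dataset assembly with speaker-disjoint splits.

AQ_MIN <- 20.5
AQ_MAX <- 94.8

#' Severity-to-anomaly coupling parameters
#'
#' Floors apply at the mildest severity (AQ 94.8), ceilings at the most
#' severe (AQ 20.5); every rate interpolates linearly in `(94.8 - AQ)`.
#' Defaults are not calibrated to any clinical corpus (no per-type anomaly
#' rates are published for the reference protocol); they are chosen so that
#' severe speakers produce frequent, clearly visible anomalies while mild
#' speakers stay near-clean.
#' @param pauseRate expected pauses per utterance `(floor, ceiling)`.
#' @param pauseDuration pause duration range in seconds.
#' @param substitutionProb per-phoneme substitution probability range.
#' @param deletionProb per-phoneme deletion probability range.
#' @param insertionProb per-phoneme insertion probability range.
#' @param boundaryShiftProb per-word-junction shift probability range.
#' @param boundaryShift boundary-shift magnitude range in seconds.
#' @return coupling parameter list.
#' @export
couplingDefaults <- function(pauseRate = c(0, 1.5),
                             pauseDuration = c(0.5, 0.9),
                             substitutionProb = c(0, 0.35),
                             deletionProb = c(0, 0.10),
                             insertionProb = c(0, 0.10),
                             boundaryShiftProb = c(0, 0.6),
                             boundaryShift = c(0.35, 0.65)) {
  list(pauseRate = pauseRate, pauseDuration = pauseDuration,
       substitutionProb = substitutionProb, deletionProb = deletionProb,
       insertionProb = insertionProb, boundaryShiftProb = boundaryShiftProb,
       boundaryShift = boundaryShift)
}

#' Map a severity score to anomaly rates
#'
#' Rates and probabilities are non-increasing in severity score (lower AQ =
#' more severe = more anomalies), linear between the coupling floors and
#' ceilings.
#' @param severity AQ score in `[20.5, 94.8]`.
#' @param coupling coupling parameters from [couplingDefaults()].
#' @return `anomalySpec` list with fields `pauseRate`, `pauseDuration`,
#'   `substitutionProb`, `deletionProb`, `insertionProb`,
#'   `boundaryShiftProb`, `boundaryShift`, `severity`.
#' @export
severityToAnomaly <- function(severity, coupling = couplingDefaults()) {
  stopifnot2(is.finite(severity) && severity >= AQ_MIN && severity <= AQ_MAX,
             sprintf("severity must lie in [%.1f, %.1f], got %s",
                     AQ_MIN, AQ_MAX, format(severity)))
  u <- (AQ_MAX - severity) / (AQ_MAX - AQ_MIN)
  lerp <- function(r) r[1] + (r[2] - r[1]) * u
  spec <- list(
    pauseRate = lerp(coupling$pauseRate),
    pauseDuration = coupling$pauseDuration,
    substitutionProb = lerp(coupling$substitutionProb),
    deletionProb = lerp(coupling$deletionProb),
    insertionProb = lerp(coupling$insertionProb),
    boundaryShiftProb = lerp(coupling$boundaryShiftProb),
    boundaryShift = coupling$boundaryShift,
    severity = severity)
  probs <- c(spec$substitutionProb, spec$deletionProb, spec$insertionProb,
             spec$boundaryShiftProb)
  stopifnot2(all(probs >= 0 & probs <= 1),
             "coupling produced probabilities outside [0, 1]")
  structure(spec, class = "anomalySpec")
}

# render one phoneme segment: harmonic tone stack (voiced) or tone + noise
# per band; 5 ms cosine ramps; normalized to a fixed RMS so VAD sees speech
synthPhoneme <- function(symbol, duration, speakerFactor = 1,
                         sampleRate = SAMPLE_RATE) {
  inv <- phonemeInventory()
  rec <- inv[[symbol]]
  stopifnot2(!is.null(rec), paste("unknown phoneme:", symbol))
  n <- max(16L, as.integer(round(duration * sampleRate)))
  t <- (0:(n - 1)) / sampleRate
  sig <- numeric(n)
  for (i in seq_len(nrow(rec$bands))) {
    cf <- rec$bands$center[i] * speakerFactor
    bw <- rec$bands$bandwidth[i]
    amp <- rec$bands$amp[i]
    sig <- sig + amp * sin(2 * pi * cf * t + runif(1, 0, 2 * pi))
    if (rec$voiced && i == 1)  # weak octave harmonic for timbre
      sig <- sig + 0.25 * amp * sin(2 * pi * 2 * cf * t + runif(1, 0, 2 * pi))
    lo <- max(cf - bw / 2, 40) / (sampleRate / 2)
    hi <- min(cf + bw / 2, sampleRate / 2 - 40) / (sampleRate / 2)
    if (hi > lo) {
      bf <- signal::butter(2, c(lo, hi), type = "pass")
      noise <- signal::filtfilt(bf, rnorm(n))
      nr <- sqrt(mean(noise^2))
      if (nr > 0) sig <- sig + 0.25 * amp * noise / nr
    }
  }
  ramp <- min(as.integer(0.005 * sampleRate), n %/% 2)
  if (ramp > 0) {
    w <- 0.5 - 0.5 * cos(pi * (0:(ramp - 1)) / ramp)
    sig[seq_len(ramp)] <- sig[seq_len(ramp)] * w
    sig[(n - ramp + 1):n] <- sig[(n - ramp + 1):n] * rev(w)
  }
  rms <- sqrt(mean(sig^2))
  if (rms > 0) sig <- sig * (0.08 / rms)   # about -22 dBFS
  sig
}

# near-silent span: Gaussian noise at -60 dBFS, so energy VAD is exercised
synthPause <- function(duration, sampleRate = SAMPLE_RATE) {
  n <- max(1L, as.integer(round(duration * sampleRate)))
  rnorm(n) * 0.001
}

# internal item-plan representation shared by generation and planting:
# a list of items {kind: "phone"|"pause", symbol, audio, wordIdx,
# anomaly: NA|"substitution"|"insertion", boundaryDelta}
itemsToUtterance <- function(items, spec, severity, keywordId,
                             extraTruth = list(), sampleRate = SAMPLE_RATE) {
  wave <- numeric(0)
  prod <- list(); truthPause <- list(); truthMis <- list()
  wordStart <- rep(NA_real_, length(spec$words))
  wordEnd <- rep(NA_real_, length(spec$words))
  wordShift <- rep(0, length(spec$words))
  t0 <- 0
  for (it in items) {
    dur <- length(it$audio) / sampleRate
    t1 <- t0 + dur
    if (it$kind == "pause") {
      truthPause[[length(truthPause) + 1L]] <- c(t0, t1)
    } else {
      prod[[length(prod) + 1L]] <- data.frame(
        symbol = it$symbol, start = t0, end = t1)
      w <- it$wordIdx
      if (is.na(wordStart[w])) wordStart[w] <- t0
      wordEnd[w] <- t1
      if (!is.null(it$boundaryDelta) && it$boundaryDelta > 0)
        wordShift[w] <- it$boundaryDelta
      if (!is.na(it$anomaly))
        truthMis[[length(truthMis) + 1L]] <- c(t0, t1)
    }
    wave <- c(wave, it$audio)
    t0 <- t1
  }
  # a boundary-shifted word keeps its canonical end in the word tier while
  # its audio (and produced tier) extend into the gap before the next word
  wordEnd <- wordEnd - wordShift
  keep <- !is.na(wordStart)
  wordTier <- data.frame(word = spec$words[keep], start = wordStart[keep],
                         end = wordEnd[keep])
  truthBoundary <- lapply(which(wordShift > 0), function(w)
    c(wordEnd[w], wordEnd[w] + wordShift[w]))
  asDf <- function(lst) {
    if (!length(lst)) return(emptyIntervals())
    m <- do.call(rbind, lst)
    df <- data.frame(start = m[, 1], end = m[, 2])
    df[order(df$start), , drop = FALSE]
  }
  truth <- list(pause = asDf(truthPause),
                mispronunciation = asDf(c(truthMis, extraTruth$mispronunciation)),
                boundary = asDf(truthBoundary))
  producedTier <- do.call(rbind, prod)
  rownames(producedTier) <- NULL
  methods::new("Utterance",
    waveform = wave, sampleRate = as.numeric(sampleRate),
    canonicalPhonemes = spec$phonemes,
    producedTier = producedTier, wordTier = wordTier,
    severity = as.numeric(severity), keywordId = spec$keywordId,
    correctness = NROW(truth$mispronunciation) == 0 &&
      NROW(truth$boundary) == 0,
    truthIntervals = truth)
}

#' Generate a clean keyword utterance
#'
#' Concatenates per-phoneme band-recipe segments; the produced tier equals
#' the canonical sequence, the correctness flag is `TRUE`, and all
#' truth-interval lists are empty.
#' @param spec a [keywordSpec()].
#' @param severity AQ score carried by the utterance.
#' @param speakerFactor multiplicative perturbation of recipe center
#'   frequencies (speaker surrogate).
#' @param seed optional integer; when given, generation is bit-reproducible
#'   and the caller's RNG state is untouched.
#' @return an [Utterance-class].
#' @export
genKeywordWaveform <- function(spec, severity = AQ_MAX, speakerFactor = 1,
                               seed = NULL) {
  stopifnot2(inherits(spec, "keywordSpec"), "spec must be a keywordSpec")
  stopifnot2(length(spec$phonemes) >= 1, "empty phoneme list")
  gen <- function() {
    items <- lapply(seq_along(spec$phonemes), function(i) list(
      kind = "phone", symbol = spec$phonemes[i],
      audio = synthPhoneme(spec$phonemes[i], spec$durations[i], speakerFactor),
      wordIdx = spec$wordOf[i], anomaly = NA_character_, boundaryDelta = 0))
    itemsToUtterance(items, spec, severity, spec$keywordId)
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

# linear time-stretch of an audio segment by factor >= 1
stretchAudio <- function(x, factor) {
  nOut <- as.integer(round(length(x) * factor))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = nOut))$y
}

#' Plant severity-coupled anomalies into a clean utterance
#'
#' Pauses are inserted as near-silent spans at word-internal phoneme
#' boundaries; substitutions replace a phoneme's recipe with a different
#' inventory phoneme; deletions remove a segment; insertions add one;
#' boundary shifts stretch the last phoneme of a word across the word
#' junction, opening a gap in the word tier. Every edit is recorded in the
#' truth intervals and reflected in the produced tier; the correctness flag
#' follows its invariant (no mispronunciations and no boundary errors).
#'
#' @param utt a clean [Utterance-class] (`correctness = TRUE`).
#' @param spec an `anomalySpec` from [severityToAnomaly()].
#' @param keywordSpecs keyword inventory (for tier bookkeeping).
#' @param speakerFactor speaker surrogate factor for synthesized segments.
#' @param plan optional explicit edit plan overriding sampling: a list with
#'   any of `pauseAfter` (phoneme indices), `pauseDur`, `substituteAt`,
#'   `substituteWith`, `deleteAt`, `insertAfter`, `insertSymbol`,
#'   `boundaryShiftAt` (word junction index), `boundaryDelta`.
#' @param seed optional integer for bit-reproducible planting.
#' @return an [Utterance-class] with planted anomalies.
#' @export
plantAnomalies <- function(utt, spec, keywordSpecs = keywordInventory(),
                           speakerFactor = 1, plan = NULL, seed = NULL) {
  stopifnot2(isTRUE(correctness(utt)), "plantAnomalies needs a clean utterance")
  stopifnot2(inherits(spec, "anomalySpec"), "spec must be an anomalySpec")
  run <- function() plantAnomaliesImpl(utt, spec, keywordSpecs, speakerFactor,
                                       plan)
  if (is.null(seed)) run() else withSeed(seed, run())
}

plantAnomaliesImpl <- function(utt, spec, keywordSpecs, speakerFactor, plan) {
  inv <- phonemeInventory()
  kspec <- matchKeywordSpec(utt, keywordSpecs)
  nPh <- length(kspec$phonemes)
  sr <- sampleRate(utt)
  tier <- producedTier(utt)
  segAudio <- lapply(seq_len(nPh), function(i) {
    a <- as.integer(round(tier$start[i] * sr)) + 1L
    b <- as.integer(round(tier$end[i] * sr))
    waveform(utt)[a:b]
  })

  if (is.null(plan)) {
    plan <- samplePlan(kspec, spec, inv, nPh)
  }
  stopifnot2(length(setdiff(seq_len(nPh), plan$deleteAt %||% integer(0))) > 0,
             "cannot delete every phoneme: at least one must survive")

  subAt <- plan$substituteAt %||% integer(0)
  subWith <- plan$substituteWith %||% character(0)
  delAt <- plan$deleteAt %||% integer(0)
  insAfter <- plan$insertAfter %||% integer(0)
  insSym <- plan$insertSymbol %||% character(0)
  insDur <- plan$insertDur %||% rep(0.1, length(insAfter))
  pauseAfter <- plan$pauseAfter %||% integer(0)
  pauseDur <- plan$pauseDur %||% rep(mean(spec$pauseDuration), length(pauseAfter))
  bAt <- plan$boundaryShiftAt %||% integer(0)
  bDelta <- plan$boundaryDelta %||% rep(mean(spec$boundaryShift), length(bAt))

  # deletions leave a nominal half-frame-wide truth span at the cut point
  items <- list(); extraMis <- list()
  cutTimes <- numeric(0)
  for (i in seq_len(nPh)) {
    if (i %in% delAt) { cutTimes <- c(cutTimes, NA); next }
    if (i %in% subAt) {
      sym <- subWith[match(i, subAt)]
      audio <- synthPhoneme(sym, kspec$durations[i], speakerFactor)
      items[[length(items) + 1L]] <- list(kind = "phone", symbol = sym,
        audio = audio, wordIdx = kspec$wordOf[i], anomaly = "substitution",
        boundaryDelta = 0, canonIdx = i)
    } else {
      items[[length(items) + 1L]] <- list(kind = "phone",
        symbol = kspec$phonemes[i], audio = segAudio[[i]],
        wordIdx = kspec$wordOf[i], anomaly = NA_character_,
        boundaryDelta = 0, canonIdx = i)
    }
    if (i %in% insAfter) {
      j <- match(i, insAfter)
      audio <- synthPhoneme(insSym[j], insDur[j], speakerFactor)
      items[[length(items) + 1L]] <- list(kind = "phone", symbol = insSym[j],
        audio = audio, wordIdx = kspec$wordOf[i], anomaly = "insertion",
        boundaryDelta = 0, canonIdx = NA_integer_)
    }
    if (i %in% pauseAfter) {
      j <- match(i, pauseAfter)
      items[[length(items) + 1L]] <- list(kind = "pause", symbol = NA_character_,
        audio = synthPause(pauseDur[j]), wordIdx = NA_integer_,
        anomaly = NA_character_, boundaryDelta = 0, canonIdx = NA_integer_)
    }
  }
  # boundary shifts: stretch the last surviving phone of the junction's word
  for (j in seq_along(bAt)) {
    w <- bAt[j]
    phoneIdx <- which(vapply(items, function(it)
      it$kind == "phone" && !is.na(it$wordIdx) && it$wordIdx == w, logical(1)))
    if (!length(phoneIdx)) next
    lastIdx <- max(phoneIdx)
    it <- items[[lastIdx]]
    oldDur <- length(it$audio) / sr
    it$audio <- stretchAudio(it$audio, (oldDur + bDelta[j]) / oldDur)
    it$boundaryDelta <- bDelta[j]
    items[[lastIdx]] <- it
  }
  # deletion truth spans, in output-time coordinates
  outTime <- 0; delTruth <- list()
  canonSeen <- integer(0)
  for (it in items) {
    if (it$kind == "phone" && !is.na(it$canonIdx))
      canonSeen <- c(canonSeen, it$canonIdx)
  }
  if (length(delAt)) {
    t0 <- 0
    ptr <- 1
    for (it in items) {
      dur <- length(it$audio) / sr
      t0 <- t0 + dur
    }
    # locate each deletion between its surviving neighbours
    t <- 0; bounds <- numeric(0); canonAt <- integer(0)
    for (it in items) {
      if (it$kind == "phone" && !is.na(it$canonIdx)) {
        bounds <- c(bounds, t)
        canonAt <- c(canonAt, it$canonIdx)
      }
      t <- t + length(it$audio) / sr
    }
    total <- t
    for (d in sort(delAt)) {
      after <- which(canonAt > d)
      cut <- if (length(after)) bounds[min(after)] else total
      delTruth[[length(delTruth) + 1L]] <-
        c(max(0, cut - 0.005), min(total, cut + 0.005))
    }
  }
  itemsToUtterance(items, kspec, severity(utt), keywordId(utt),
                   extraTruth = list(mispronunciation = delTruth),
                   sampleRate = sr)
}

matchKeywordSpec <- function(utt, keywordSpecs) {
  for (ks in keywordSpecs)
    if (ks$keywordId == keywordId(utt) &&
        identical(ks$phonemes, canonicalPhonemes(utt))) return(ks)
  # fall back: reconstruct a single-word spec from the utterance itself
  keywordSpec(keywordId(utt), canonicalPhonemes(utt),
              durations = producedTier(utt)$end - producedTier(utt)$start)
}

samplePlan <- function(kspec, spec, inv, nPh) {
  syms <- names(inv)
  subAt <- which(runif(nPh) < spec$substitutionProb)
  subWith <- vapply(subAt, function(i)
    sample(setdiff(syms, kspec$phonemes[i]), 1L), character(1))
  delCand <- which(runif(nPh) < spec$deletionProb)
  delCand <- setdiff(delCand, subAt)
  if (length(delCand) + 0 >= nPh)  # keep at least one phoneme
    delCand <- delCand[-1]
  insAfter <- which(runif(nPh) < spec$insertionProb)
  insAfter <- setdiff(insAfter, delCand)
  insSymbol <- vapply(insAfter, function(i) sample(syms, 1L), character(1))
  insDur <- runif(length(insAfter), 0.07, 0.15)
  # pauses: word-internal phoneme boundaries only (no word-tier gap), so a
  # pause never masquerades as a boundary error
  internal <- which(kspec$wordOf[-nPh] == kspec$wordOf[-1])
  internal <- setdiff(internal, delCand)
  nP <- min(rpois(1, spec$pauseRate), length(internal))
  pauseAfter <- if (nP > 0) sort(sample(internal, nP)) else integer(0)
  pauseDur <- runif(length(pauseAfter), spec$pauseDuration[1],
                    spec$pauseDuration[2])
  nW <- length(kspec$words)
  junctions <- seq_len(max(nW - 1, 0))
  bAt <- junctions[runif(length(junctions)) < spec$boundaryShiftProb]
  bDelta <- runif(length(bAt), spec$boundaryShift[1], spec$boundaryShift[2])
  list(substituteAt = subAt, substituteWith = subWith, deleteAt = delCand,
       insertAfter = insAfter, insertSymbol = insSymbol, insertDur = insDur,
       pauseAfter = pauseAfter, pauseDur = pauseDur,
       boundaryShiftAt = bAt, boundaryDelta = bDelta)
}

#' Severity sampler matching the reference cohort
#'
#' AQ scores drawn from a Beta(3.4, 1.6) rescaled to `[20.5, 94.8]`: mean
#' 71, roughly 40% of speakers mild (AQ >= 76) and under 10% severe
#' (AQ < 50), mirroring the published cohort summary this generator
#' emulates.
#' @param n number of draws.
#' @return numeric AQ vector.
#' @export
severityCohortSampler <- function(n) {
  clamp(AQ_MIN + (AQ_MAX - AQ_MIN) * stats::rbeta(n, 3.4, 1.6),
        AQ_MIN, AQ_MAX)
}

#' Generate a synthetic dataset with speaker-disjoint splits
#'
#' Severity is a per-speaker property (each speaker surrogate draws one AQ
#' from the sampler); speaker surrogates perturb all recipe center
#' frequencies by a fixed factor and never span splits. Utterance RNG streams
#' derive from `(seed, entry index)`, so generation is order-independent and
#' bit-reproducible.
#'
#' @param outDir output directory (created if needed).
#' @param nPerClass utterances per keyword class.
#' @param severitySampler function `n -> n` AQ scores in `[20.5, 94.8]`.
#' @param splitFractions named fractions for `train`/`val`/`test`, summing
#'   to 1.
#' @param seed integer generator seed.
#' @param nSpeakers number of speaker surrogates.
#' @param coupling severity coupling from [couplingDefaults()].
#' @param writeFiles write WAV/TextGrid/JSON to `outDir` (set `FALSE` to get
#'   utterances in memory only).
#' @return a [DatasetManifest-class]; when `writeFiles = FALSE` the
#'   utterances are attached as attribute `"utterances"`.
#' @export
genDataset <- function(outDir = tempfile("synthset"), nPerClass = 4,
                       severitySampler = severityCohortSampler,
                       splitFractions = c(train = 0.7, val = 0.15, test = 0.15),
                       seed = 1L, nSpeakers = 45L,
                       coupling = couplingDefaults(), writeFiles = TRUE) {
  stopifnot2(nPerClass >= 1, "nPerClass must be >= 1")
  stopifnot2(abs(sum(splitFractions) - 1) < 1e-9, "split fractions must sum to 1")
  specs <- keywordInventory()
  nClass <- length(specs)
  n <- nClass * nPerClass
  splits <- names(splitFractions)

  # speakers: fixed severity + recipe factor, assigned to splits by fraction
  spkMeta <- withSeed(deriveSeed(seed, 10^6), {
    cnt <- pmax(1L, as.integer(round(splitFractions * nSpeakers)))
    cnt[1] <- nSpeakers - sum(cnt[-1])
    spkSplit <- rep(splits, cnt)
    data.frame(speaker = seq_len(nSpeakers), split = spkSplit,
               severity = clamp(severitySampler(nSpeakers), AQ_MIN, AQ_MAX),
               factor = 1 + runif(nSpeakers, -0.05, 0.05))
  })

  # entry split by fractions, stratified within class; speaker sampled from
  # that split's pool
  entrySplit <- withSeed(deriveSeed(seed, 10^6 + 1), {
    perClass <- as.integer(floor(splitFractions * nPerClass))
    rem <- nPerClass - sum(perClass)
    if (rem > 0) perClass[seq_len(rem)] <- perClass[seq_len(rem)] + 1L
    unlist(lapply(seq_len(nClass), function(k) sample(rep(splits, perClass))))
  })
  entrySpeaker <- withSeed(deriveSeed(seed, 10^6 + 2), {
    vapply(entrySplit, function(s) {
      pool <- spkMeta$speaker[spkMeta$split == s]
      if (length(pool) == 1) pool else sample(pool, 1L)
    }, numeric(1))
  })

  if (writeFiles) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n); utts <- vector("list", n)
  idx <- 0L
  for (k in seq_len(nClass)) for (j in seq_len(nPerClass)) {
    idx <- idx + 1L
    spk <- entrySpeaker[idx]
    sev <- spkMeta$severity[spk]
    fac <- spkMeta$factor[spk]
    utt <- withSeed(deriveSeed(seed, idx), {
      clean <- genKeywordWaveform(specs[[k]], severity = sev,
                                  speakerFactor = fac)
      plantAnomalies(clean, severityToAnomaly(sev, coupling),
                     keywordSpecs = specs, speakerFactor = fac)
    })
    audioPath <- annPath <- NA_character_
    if (writeFiles) {
      stem <- sprintf("utt_%04d", idx)
      audioPath <- file.path(outDir, paste0(stem, ".wav"))
      annPath <- file.path(outDir, paste0(stem, ".TextGrid"))
      writeWav(waveform(utt), audioPath, sampleRate(utt))
      writeAnnotations(utt, annPath)
    } else utts[[idx]] <- utt
    rows[[idx]] <- data.frame(
      audio = audioPath, annotation = annPath,
      keywordId = specs[[k]]$keywordId, severity = sev,
      correctness = correctness(utt), split = entrySplit[idx], speaker = spk)
  }
  manifest <- methods::new("DatasetManifest",
    entries = do.call(rbind, rows), seed = as.integer(seed),
    parameters = list(nPerClass = nPerClass, nSpeakers = nSpeakers,
                      splitFractions = as.list(splitFractions),
                      coupling = coupling))
  if (writeFiles)
    writeManifest(manifest, file.path(outDir, "manifest.jsonl"))
  else attr(manifest, "utterances") <- utts
  manifest
}
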