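# Training loop (Adam, cross-entropy), evaluation, checkpointing.

#' Load an utterance referenced by a manifest row
#' @param entry one row of [manifestEntries()].
#' @param utterances optional in-memory utterance list (from
#'   `genDataset(writeFiles = FALSE)`).
#' @param index row index, needed with `utterances`.
#' @return an [Utterance-class].
#' @export
loadUtterance <- function(entry, utterances = NULL, index = NULL) {
  if (!is.null(utterances)) return(utterances[[index]])
  readAnnotations(entry$annotation, wavPath = entry$audio)
}

# spectrogram + label cache for one manifest; framePhonemes are the
# produced-tier symbols sampled at the transformer tap's frame centers
# (index nSym + 1 = silence/pause), supervising the auxiliary loss
prepareExamples <- function(manifest, utterances = NULL,
                            config = modelConfig()) {
  e <- manifestEntries(manifest)
  syms <- names(phonemeInventory())
  kT <- config$convKernel[2]; sT <- config$convStride[2]
  lapply(seq_len(NROW(e)), function(i) {
    utt <- loadUtterance(e[i, ], utterances, i)
    S <- logMelSpectrogram(waveform(utt), sampleRate(utt))
    nbT <- (ncol(S) - kT) %/% sT + 1L
    centers <- ((seq_len(nbT) - 1L) * sT + (kT + 1) / 2 - 0.5) * 0.01
    pt <- producedTier(utt)
    frameLab <- vapply(centers, function(tc) {
      row <- which(pt$start <= tc & tc < pt$end)
      if (length(row)) match(pt$symbol[row[1]], syms) else length(syms) + 1L
    }, integer(1))
    list(S = S, severity = severity(utt), label = e$keywordId[i],
         split = e$split[i], frameLab = frameLab)
  })
}

# training-time augmentation: small mel-axis shift (edge-replicated),
# Gaussian input noise, and time/frequency masking (random spans replaced by
# the per-bin mean, teaching classification from partial evidence — the
# regime anomalous productions live in); draws come from the caller's
# seeded epoch stream
augmentSpectrogram <- function(S, cfg) {
  if (cfg$augFreqShift > 0) {
    k <- sample(-cfg$augFreqShift:cfg$augFreqShift, 1)
    if (k != 0) {
      n <- nrow(S)
      idx <- clamp(seq_len(n) - k, 1L, n)
      S <- S[idx, , drop = FALSE]
    }
  }
  if (cfg$augTimeMask > 0) {
    fill <- rowMeans(S)
    for (rep in 1:2) if (runif(1) < 0.8) {
      w <- sample.int(cfg$augTimeMask, 1)
      t0 <- sample.int(max(1L, ncol(S) - w), 1)
      S[, t0:(t0 + w - 1L)] <- fill
    }
  }
  if (cfg$augFreqMask > 0 && runif(1) < 0.8) {
    w <- sample.int(cfg$augFreqMask, 1)
    f0 <- sample.int(nrow(S) - w, 1)
    S[f0:(f0 + w - 1L), ] <- mean(S[f0:(f0 + w - 1L), ])
  }
  if (cfg$augNoise > 0)
    S <- S + matrix(rnorm(length(S)) * cfg$augNoise * 3.5, nrow(S))
  S
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mHat <- state$m[[nm]] / (1 - beta1^state$t)
    vHat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mHat / (sqrt(vHat) + eps)
  }
  list(params = params, state = state)
}

splitAccuracy <- function(model, examples, split) {
  idx <- which(vapply(examples, function(x) x$split, character(1)) == split)
  if (!length(idx)) return(NA_real_)
  hits <- vapply(idx, function(i) {
    pr <- predictProbs(model, examples[[i]]$S, examples[[i]]$severity)
    (which.max(pr) - 1L) == examples[[i]]$label
  }, logical(1))
  mean(hits)
}

#' Train the keyword classifier on a synthetic dataset
#'
#' Minibatch Adam on the cross-entropy loss, deterministic given the config
#' seed (initialization, batch order). Reports accuracy on every split.
#' @param model an initialized [KeywordModel-class] (its config drives
#'   epochs, batch size and learning rate).
#' @param manifest a [DatasetManifest-class] with `train`/`val`/`test` tags.
#' @param utterances optional in-memory utterances (see [genDataset()]).
#' @param checkpoint optional path; when given the trained model is saved
#'   there.
#' @param verbose print per-epoch loss.
#' @return list with `model` (trained) and `report` (split accuracies, final
#'   training loss).
#' @export
trainToy <- function(model, manifest, utterances = NULL, checkpoint = NULL,
                     verbose = FALSE) {
  cfg <- model@config
  examples <- prepareExamples(manifest, utterances, cfg)
  splits <- vapply(examples, function(x) x$split, character(1))
  trainIdx <- which(splits == "train")
  stopifnot2(length(trainIdx) > 0, "training split is empty")
  params <- model@params
  state <- adamInit(params)
  lastLoss <- NA_real_
  if (cfg$epochs > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- if (identical(cfg$lrSchedule, "cosine"))
        cfg$learningRate * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs))
      else cfg$learningRate
      # one seeded stream per epoch covers batch order and augmentation
      epochRun <- withSeed(deriveSeed(cfg$seed, 5000 + epoch), {
        order <- sample(trainIdx)
        losses <- numeric(0)
        for (b in split(order, ceiling(seq_along(order) / cfg$batchSize))) {
          acc <- NULL
          bl <- 0
          for (i in b) {
            ex <- examples[[i]]
            S <- augmentSpectrogram(ex$S, cfg)
            m2 <- model; m2@params <- params
            fw <- modelForward(m2, S, ex$severity)
            y <- numeric(cfg$nClasses); y[ex$label + 1L] <- 1
            bl <- bl + (-sum(y * log(pmax(fw$probs, 1e-12))))
            dFtfExtra <- NULL; gAux <- NULL
            if (cfg$auxPhonemeWeight > 0) {
              X3 <- fw$cache$X3
              Lp <- sweep(X3 %*% params$Wp, 2, params$bp, "+")
              Pp <- rowSoftmax(Lp)
              Tn <- nrow(X3)
              Yp <- matrix(0, Tn, ncol(Pp))
              Yp[cbind(seq_len(Tn), ex$frameLab)] <- 1
              w <- cfg$auxPhonemeWeight / Tn
              dLp <- (Pp - Yp) * w
              dFtfExtra <- dLp %*% t(params$Wp)
              gAux <- list(Wp = t(X3) %*% dLp, bp = colSums(dLp))
              bl <- bl - w * sum(log(pmax(Pp[Yp == 1], 1e-12)))
            }
            bw <- modelBackward(m2, fw, fw$probs - y, wantParams = TRUE,
                                dFtfExtra = dFtfExtra)
            g <- bw$params
            if (!is.null(gAux)) { g$Wp <- gAux$Wp; g$bp <- gAux$bp }
            acc <- if (is.null(acc)) g else Map(`+`, acc, g)
          }
          acc <- lapply(acc, function(gm) gm / length(b))
          upd <- adamStep(params, acc, state, lr)
          params <- upd$params; state <- upd$state
          losses <- c(losses, bl / length(b))
        }
        list(params = params, state = state, loss = mean(losses))
      })
      params <- epochRun$params; state <- epochRun$state
      lastLoss <- epochRun$loss
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", epoch, cfg$epochs, lastLoss))
    }
  }
  model@params <- params
  model@trained <- cfg$epochs > 0
  report <- list(
    train = splitAccuracy(model, examples, "train"),
    val = splitAccuracy(model, examples, "val"),
    test = splitAccuracy(model, examples, "test"),
    finalLoss = lastLoss)
  if (!is.null(checkpoint)) saveCheckpoint(model, checkpoint)
  list(model = model, report = report)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the weights, the configuration snapshot
#' (including the spectrogram convention) and the training seed.
#' @param model a [KeywordModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(format = "acamspeech-checkpoint-1",
              config = model@config, params = model@params,
              trainSeed = model@trainSeed, trained = model@trained,
              spectrogram = list(sampleRate = 16000, winLength = 400,
                                 hopLength = 160, nMel = model@config$nMel,
                                 log = "natural, floor 1e-6"))
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#' @param path checkpoint path.
#' @return a [KeywordModel-class].
#' @export
loadCheckpoint <- function(path) {
  stopifnot2(file.exists(path), paste("no such checkpoint:", path))
  obj <- readRDS(path)
  stopifnot2(identical(obj$format, "acamspeech-checkpoint-1"),
             "unrecognized checkpoint format")
  methods::new("KeywordModel", config = obj$config, params = obj$params,
               trainSeed = obj$trainSeed, trained = obj$trained)
}
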