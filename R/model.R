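# FiLM-conditioned spectrogram keyword classifier.
#
# Architecture: log-mel input -> one strided 2-D convolution block (ReLU)
# whose output is the *prediction* feature tap (frequency axis retained as
# channel blocks) -> linear projection + sinusoidal positions -> one
# single-head self-attention block with residual -> position-wise FFN with
# residual, whose output is the *impairment* feature tap -> FiLM modulation
# (gamma/beta generated from the raw severity score) -> global average
# pooling over time -> 2-layer MLP head -> 15 logits.
#
# Forward and backward passes are written out by hand (no autodiff framework
# in this stack); gradient correctness is pinned by central-finite-difference
# tests. Evaluation is strictly deterministic: no dropout, no normalization
# layers, no stochastic kernels.

#' Model configuration
#'
#' @param nMel mel bins of the input spectrogram.
#' @param convChannels CNN channels.
#' @param convKernel `(freq, time)` kernel size.
#' @param convStride `(freq, time)` strides.
#' @param hiddenDim transformer width H.
#' @param transformerLayers number of attention + FFN encoder blocks.
#' @param ffDim position-wise FFN width.
#' @param filmHidden FiLM generator hidden width.
#' @param headHidden classifier-head hidden width.
#' @param nClasses number of keyword classes.
#' @param epochs,batchSize,learningRate training hyperparameters.
#' @param lrSchedule learning-rate schedule: half-cosine decay to zero over
#'   the epochs, or constant.
#' @param augFreqShift training-time augmentation: uniform mel-bin shift in
#'   `[-augFreqShift, augFreqShift]` (0 disables).
#' @param augNoise training-time Gaussian input noise standard deviation
#'   (0 disables).
#' @param augTimeMask maximum width (frames) of random time masks (0
#'   disables).
#' @param augFreqMask maximum width (mel bins) of random frequency masks
#'   (0 disables).
#' @param auxPhonemeWeight weight of the auxiliary frame-level phoneme
#'   classification loss on the transformer tap during training (0
#'   disables). The produced phoneme tier supervises each tap frame,
#'   grounding the encoder in phoneme identity; the keyword head and
#'   pooling are unaffected.
#' @param seed training/initialization seed.
#' @return validated config list.
#' @export
modelConfig <- function(nMel = 128L, convChannels = 12L,
                        convKernel = c(16L, 5L), convStride = c(8L, 3L),
                        hiddenDim = 40L, transformerLayers = 2L,
                        ffDim = 64L, filmHidden = 16L,
                        headHidden = 32L, nClasses = 15L, epochs = 36L,
                        batchSize = 16L, learningRate = 2e-3,
                        lrSchedule = c("cosine", "constant"),
                        augFreqShift = 2L, augNoise = 0.05,
                        augTimeMask = 0L, augFreqMask = 0L,
                        auxPhonemeWeight = 0.5, seed = 1L) {
  lrSchedule <- match.arg(lrSchedule)
  cfg <- list(nMel = as.integer(nMel), convChannels = as.integer(convChannels),
              convKernel = as.integer(convKernel),
              convStride = as.integer(convStride),
              hiddenDim = as.integer(hiddenDim),
              transformerLayers = as.integer(transformerLayers),
              ffDim = as.integer(ffDim),
              filmHidden = as.integer(filmHidden),
              headHidden = as.integer(headHidden),
              nClasses = as.integer(nClasses), epochs = as.integer(epochs),
              batchSize = as.integer(batchSize),
              learningRate = learningRate, lrSchedule = lrSchedule,
              augFreqShift = as.integer(augFreqShift), augNoise = augNoise,
              augTimeMask = as.integer(augTimeMask),
              augFreqMask = as.integer(augFreqMask),
              auxPhonemeWeight = auxPhonemeWeight,
              seed = as.integer(seed))
  cfg$nBlocksF <- (cfg$nMel - cfg$convKernel[1]) %/% cfg$convStride[1] + 1L
  cfg$tapChannels <- cfg$nBlocksF * cfg$convChannels
  stopifnot2(cfg$nClasses >= 2, "need at least 2 classes")
  cfg
}

#' Initialize an untrained keyword model
#'
#' He/Xavier-scaled random weights; the FiLM generator's output layer starts
#' at zero with gamma bias 1 and beta bias 0, so the untrained model is an
#' exact FiLM identity (conditioning has no effect until trained).
#' @param config a [modelConfig()].
#' @return a [KeywordModel-class].
#' @export
initKeywordModel <- function(config = modelConfig()) {
  H <- config$hiddenDim
  withSeed(config$seed, {
    rn <- function(n, m, sc) matrix(rnorm(n * m, sd = sc), n, m)
    patch <- prod(config$convKernel)
    p <- list(
      Wc = rn(patch, config$convChannels, sqrt(2 / patch)),
      bc = numeric(config$convChannels),
      Win = rn(config$tapChannels, H, sqrt(2 / config$tapChannels)),
      bin = numeric(H),
      filmW1 = matrix(rnorm(config$filmHidden, sd = 0.02), 1),
      filmB1 = numeric(config$filmHidden),
      filmW2 = matrix(0, config$filmHidden, 2L * H),
      filmB2 = c(rep(1, H), rep(0, H)),
      Wh1 = rn(H, config$headHidden, sqrt(2 / H)),
      bh1 = numeric(config$headHidden),
      Wh2 = rn(config$headHidden, config$nClasses, sqrt(2 / config$headHidden)),
      bh2 = numeric(config$nClasses))
    nSym <- length(phonemeInventory()) + 1L   # phonemes + silence
    p$Wp <- rn(H, nSym, sqrt(2 / H))
    p$bp <- numeric(nSym)
    for (l in seq_len(config$transformerLayers)) {
      p[[paste0("Wq_", l)]] <- rn(H, H, sqrt(1 / H))
      p[[paste0("Wk_", l)]] <- rn(H, H, sqrt(1 / H))
      p[[paste0("Wv_", l)]] <- rn(H, H, sqrt(1 / H))
      p[[paste0("Wo_", l)]] <- rn(H, H, sqrt(1 / H))
      p[[paste0("W1_", l)]] <- rn(H, config$ffDim, sqrt(2 / H))
      p[[paste0("b1_", l)]] <- numeric(config$ffDim)
      p[[paste0("W2_", l)]] <- rn(config$ffDim, H, sqrt(2 / config$ffDim))
      p[[paste0("b2_", l)]] <- numeric(H)
    }
    methods::new("KeywordModel", config = config, params = p,
                 trainSeed = config$seed, trained = FALSE)
  })
}

# fixed affine input scaling: log-mel floor is log(1e-6) ~ -13.8, speech
# bins sit around [-5, 0]; keeps the perturbation scale meaningful
scaleInput <- function(S) (S + 7) / 3.5

# cached im2col index matrices, keyed by input width
patchIndexCache <- new.env(parent = emptyenv())

patchIndices <- function(config, nT) {
  key <- sprintf("%d_%d_%d_%d_%d_%d", config$nMel, nT, config$convKernel[1],
                 config$convKernel[2], config$convStride[1],
                 config$convStride[2])
  if (!is.null(patchIndexCache[[key]])) return(patchIndexCache[[key]])
  kF <- config$convKernel[1]; kT <- config$convKernel[2]
  sF <- config$convStride[1]; sT <- config$convStride[2]
  nbF <- config$nBlocksF
  nbT <- (nT - kT) %/% sT + 1L
  stopifnot2(nbT >= 1, "input too short for the convolution kernel")
  idx <- matrix(0L, nbT * nbF, kF * kT)
  r <- 0L
  for (tb in seq_len(nbT)) for (fb in seq_len(nbF)) {
    r <- r + 1L
    rows <- ((fb - 1L) * sF + 1L):((fb - 1L) * sF + kF)
    cols <- ((tb - 1L) * sT + 1L):((tb - 1L) * sT + kT)
    idx[r, ] <- as.vector(outer(rows, (cols - 1L) * config$nMel, "+"))
  }
  out <- list(idx = idx, nbT = nbT, nbF = nbF)
  patchIndexCache[[key]] <- out
  out
}

sinusoidalPositions <- function(nT, H) {
  pos <- matrix(0, nT, H)
  t <- seq_len(nT) - 1L
  for (i in seq_len(H %/% 2L)) {
    w <- 1 / (10000^((2 * (i - 1)) / H))
    pos[, 2L * i - 1L] <- sin(w * t)
    pos[, 2L * i] <- cos(w * t)
  }
  0.1 * pos
}

softmaxVec <- function(z) { z <- z - max(z); e <- exp(z); e / sum(e) }

rowSoftmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Generate FiLM modulation parameters from a severity score
#'
#' The raw AQ score feeds the generator MLP unnormalized (the first layer
#' absorbs its scale); the output of length 2H splits into gamma and beta.
#' @param model a [KeywordModel-class].
#' @param severity finite AQ score.
#' @return list with numeric `gamma` and `beta`, each of length H.
#' @export
filmGenerate <- function(model, severity) {
  stopifnot2(is.numeric(severity) && length(severity) == 1 &&
               is.finite(severity), "severity must be a finite scalar")
  p <- model@params
  H <- model@config$hiddenDim
  hF <- tanh(severity * p$filmW1 + p$filmB1)
  g <- as.vector(hF %*% p$filmW2) + p$filmB2
  list(gamma = g[seq_len(H)], beta = g[H + seq_len(H)], hidden = hF)
}

#' Apply FiLM modulation to a feature sequence
#'
#' `out[t, h] = gamma[h] * features[t, h] + beta[h]`, gamma/beta broadcast
#' across the time dimension.
#' @param features `T x H` matrix.
#' @param params list with `gamma` and `beta` of length H.
#' @return modulated `T x H` matrix.
#' @export
filmModulate <- function(features, params) {
  stopifnot2(ncol(features) == length(params$gamma),
             "feature width must equal the FiLM parameter length")
  sweep(sweep(features, 2, params$gamma, "*"), 2, params$beta, "+")
}

# full forward pass with optional tap overrides (used by finite-difference
# tests); returns all intermediates needed by the backward pass
modelForward <- function(model, S, severity, tapOverride = NULL) {
  cfg <- model@config
  p <- model@params
  stopifnot2(nrow(S) == cfg$nMel,
             sprintf("input has %d mel bins; model expects %d", nrow(S),
                     cfg$nMel))
  H <- cfg$hiddenDim
  xn <- scaleInput(S)
  pi <- patchIndices(cfg, ncol(S))
  P <- matrix(xn[pi$idx], nrow(pi$idx), ncol(pi$idx))
  Zpre <- sweep(P %*% p$Wc, 2, p$bc, "+")
  Z <- pmax(Zpre, 0)
  # F_cnn[t, (f-1)*C + c] = Z[(t-1)*nbF + f, c]
  Tn <- pi$nbT
  Fcnn <- matrix(0, Tn, cfg$tapChannels)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1L) * pi$nbF + 1L):(t * pi$nbF)
    Fcnn[t, ] <- as.vector(t(Z[rows, , drop = FALSE]))
  }
  if (!is.null(tapOverride$prediction)) Fcnn <- tapOverride$prediction
  pos <- sinusoidalPositions(Tn, H)
  X1p <- sweep(Fcnn %*% p$Win, 2, p$bin, "+") + pos
  X <- X1p
  layers <- vector("list", cfg$transformerLayers)
  for (l in seq_len(cfg$transformerLayers)) {
    Q <- X %*% p[[paste0("Wq_", l)]]
    K <- X %*% p[[paste0("Wk_", l)]]
    V <- X %*% p[[paste0("Wv_", l)]]
    A <- rowSoftmax(Q %*% t(K) / sqrt(H))
    O <- A %*% V
    Xa <- X + O %*% p[[paste0("Wo_", l)]]
    Apre <- sweep(Xa %*% p[[paste0("W1_", l)]], 2, p[[paste0("b1_", l)]], "+")
    U <- pmax(Apre, 0)
    Xout <- Xa + sweep(U %*% p[[paste0("W2_", l)]], 2,
                       p[[paste0("b2_", l)]], "+")
    layers[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A = A, O = O, Xa = Xa,
                        Apre = Apre, U = U)
    X <- Xout
  }
  X3 <- X
  if (!is.null(tapOverride$impairment)) X3 <- tapOverride$impairment
  film <- filmGenerate(model, severity)
  Y <- filmModulate(X3, film)
  u <- colMeans(Y)
  a1 <- as.vector(u %*% p$Wh1) + p$bh1
  h1 <- pmax(a1, 0)
  logits <- as.vector(h1 %*% p$Wh2) + p$bh2
  list(logits = logits, probs = softmaxVec(logits),
       cache = list(P = P, Zpre = Zpre, Z = Z, Fcnn = Fcnn, X1p = X1p,
                    layers = layers, X3 = X3, film = film, Y = Y, u = u,
                    a1 = a1, h1 = h1, Tn = Tn, nbF = pi$nbF,
                    severity = severity))
}

# backward pass from a logit-space output gradient; returns the two tap
# gradients always, and parameter gradients when wantParams = TRUE.
# dFtfExtra adds an externally computed gradient w.r.t. the transformer tap
# (auxiliary training losses) before the encoder backprop.
modelBackward <- function(model, fw, dlogits, wantParams = FALSE,
                          dFtfExtra = NULL) {
  cfg <- model@config
  p <- model@params
  cc <- fw$cache
  H <- cfg$hiddenDim
  Tn <- cc$Tn
  g <- if (wantParams) list() else NULL
  dh1 <- as.vector(p$Wh2 %*% dlogits)
  if (wantParams) { g$Wh2 <- outer(cc$h1, dlogits); g$bh2 <- dlogits }
  da1 <- dh1 * (cc$a1 > 0)
  if (wantParams) { g$Wh1 <- outer(cc$u, da1); g$bh1 <- da1 }
  du <- as.vector(p$Wh1 %*% da1)
  dY <- matrix(du, Tn, H, byrow = TRUE) / Tn
  gamma <- cc$film$gamma
  dX3 <- sweep(dY, 2, gamma, "*")        # gradient w.r.t. the impairment tap
  if (wantParams) {
    dgamma <- colSums(dY * cc$X3)
    dbeta <- colSums(dY)
    dg2 <- c(dgamma, dbeta)
    g$filmW2 <- outer(as.vector(cc$film$hidden), dg2)
    g$filmB2 <- dg2
    dhF <- as.vector(p$filmW2 %*% dg2)
    dpre <- dhF * (1 - as.vector(cc$film$hidden)^2)
    g$filmW1 <- matrix(cc$severity * dpre, 1)
    g$filmB1 <- dpre
  }
  dX <- if (is.null(dFtfExtra)) dX3 else dX3 + dFtfExtra
  for (l in rev(seq_len(cfg$transformerLayers))) {
    ly <- cc$layers[[l]]
    W2l <- p[[paste0("W2_", l)]]; W1l <- p[[paste0("W1_", l)]]
    Wol <- p[[paste0("Wo_", l)]]
    dU <- dX %*% t(W2l)
    dApre <- dU * (ly$Apre > 0)
    dXa <- dX + dApre %*% t(W1l)
    if (wantParams) {
      g[[paste0("W2_", l)]] <- t(ly$U) %*% dX
      g[[paste0("b2_", l)]] <- colSums(dX)
      g[[paste0("W1_", l)]] <- t(ly$Xa) %*% dApre
      g[[paste0("b1_", l)]] <- colSums(dApre)
    }
    dO <- dXa %*% t(Wol)
    dA <- dO %*% t(ly$V)
    dV <- t(ly$A) %*% dO
    rs <- rowSums(dA * ly$A)
    dS <- (dA - matrix(rs, Tn, Tn)) * ly$A
    dQ <- dS %*% ly$K / sqrt(H)
    dK <- t(dS) %*% ly$Q / sqrt(H)
    dX <- dXa + dQ %*% t(p[[paste0("Wq_", l)]]) +
      dK %*% t(p[[paste0("Wk_", l)]]) + dV %*% t(p[[paste0("Wv_", l)]])
    if (wantParams) {
      g[[paste0("Wo_", l)]] <- t(ly$O) %*% dXa
      g[[paste0("Wq_", l)]] <- t(ly$Xin) %*% dQ
      g[[paste0("Wk_", l)]] <- t(ly$Xin) %*% dK
      g[[paste0("Wv_", l)]] <- t(ly$Xin) %*% dV
    }
  }
  dX1p <- dX
  dFcnn <- dX1p %*% t(p$Win)             # gradient w.r.t. the prediction tap
  if (wantParams) {
    g$Win <- t(cc$Fcnn) %*% dX1p; g$bin <- colSums(dX1p)
    dZ <- matrix(0, Tn * cc$nbF, cfg$convChannels)
    for (t in seq_len(Tn)) {
      rows <- ((t - 1L) * cc$nbF + 1L):(t * cc$nbF)
      dZ[rows, ] <- t(matrix(dFcnn[t, ], cfg$convChannels, cc$nbF))
    }
    dZpre <- dZ * (cc$Zpre > 0)
    g$Wc <- t(cc$P) %*% dZpre
    g$bc <- colSums(dZpre)
  }
  list(dFcnn = dFcnn, dFtf = dX3, params = g)
}

tapFps <- function(config) 100 / config$convStride[2]

makeTaps <- function(model, fw) {
  cfg <- model@config
  freqAxis <- rep(seq_len(cfg$nBlocksF), each = cfg$convChannels)
  centers <- (seq_len(cfg$nBlocksF) - 1) * cfg$convStride[1] +
    (cfg$convKernel[1] + 1) / 2
  list(
    prediction = methods::new("FeatureTap", branch = "prediction",
      values = fw$cache$Fcnn, fps = tapFps(cfg), freqAxis = as.integer(freqAxis),
      freqCenters = centers),
    impairment = methods::new("FeatureTap", branch = "impairment",
      values = fw$cache$X3, fps = tapFps(cfg), freqAxis = integer(0),
      freqCenters = numeric(0)))
}

#' Forward pass with feature taps
#'
#' Runs the classifier on a log-mel spectrogram and captures the prediction
#' (CNN block) and impairment (transformer block) feature taps in the same
#' pass. Evaluation is deterministic: identical inputs give bit-identical
#' outputs.
#' @param model a [KeywordModel-class].
#' @param S `nMel x T` log-mel spectrogram.
#' @param severity AQ score for FiLM conditioning.
#' @return a [ModelOutputs-class].
#' @export
forwardWithTaps <- function(model, S, severity) {
  fw <- modelForward(model, S, severity)
  methods::new("ModelOutputs", logits = fw$logits,
               probabilities = fw$probs, taps = makeTaps(model, fw))
}

#' Class-logit gradients with respect to both feature taps
#'
#' Backpropagates the scalar logit of class `targetClass` to the prediction
#' and impairment taps.
#' @param model a [KeywordModel-class].
#' @param S `nMel x T` log-mel spectrogram.
#' @param severity AQ score.
#' @param targetClass 0-based class index in `[0, nClasses - 1]`.
#' @return named list of [GradientMap-class] (`prediction`, `impairment`).
#' @export
classGradient <- function(model, S, severity, targetClass) {
  cfg <- model@config
  stopifnot2(targetClass >= 0 && targetClass < cfg$nClasses,
             sprintf("targetClass must lie in [0, %d]", cfg$nClasses - 1L))
  fw <- modelForward(model, S, severity)
  dlogits <- numeric(cfg$nClasses)
  dlogits[targetClass + 1L] <- 1
  bw <- modelBackward(model, fw, dlogits)
  list(prediction = methods::new("GradientMap", branch = "prediction",
                                 values = bw$dFcnn),
       impairment = methods::new("GradientMap", branch = "impairment",
                                 values = bw$dFtf))
}

#' Predicted class probabilities
#' @param model a [KeywordModel-class].
#' @param S spectrogram.
#' @param severity AQ score.
#' @return numeric probability vector over classes.
#' @export
predictProbs <- function(model, S, severity) {
  modelForward(model, S, severity)$probs
}
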