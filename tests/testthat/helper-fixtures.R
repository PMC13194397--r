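# Shared fixtures: tiny utterances, a small model, and independent oracles
# used across test files. Everything is generated in code under fixed seeds.

tinyModel <- function(seed = 3L, epochs = 0L) {
  initKeywordModel(modelConfig(epochs = epochs, seed = seed))
}

# model with a non-trivial FiLM generator (untrained FiLM is an exact
# identity by construction, which would hide conditioning bugs)
tinyModelFilmActive <- function(seed = 3L) {
  m <- tinyModel(seed)
  withr::with_seed(seed + 100L, {
    m@params$filmW2 <- matrix(rnorm(length(m@params$filmW2), sd = 0.05),
                              nrow(m@params$filmW2))
  })
  m
}

cleanUtterance <- function(keyword = "canoe", severity = 70, seed = 42L,
                           speakerFactor = 1) {
  genKeywordWaveform(keywordInventory()[[keyword]], severity = severity,
                     speakerFactor = speakerFactor, seed = seed)
}

uttSpectrogram <- function(utt) logMelSpectrogram(waveform(utt),
                                                  sampleRate(utt))

# independent Levenshtein distance (plain DP, no backtrace) used as the
# alignment oracle
levenshteinOracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]), D[i, j + 1] + 1L,
                           D[i + 1, j] + 1L)
  D[n + 1, m + 1]
}

# straight-line reimplementation of the per-branch CAM pipeline
# (normalize -> dual filter -> optional gating -> segment weights -> CAM),
# kept deliberately naive and loop-based
straightLineCam <- function(G, F, eps = 1e-5, af = NULL, tseg = nrow(G),
                            overlap = 0) {
  Gn <- G / (mean(G^2) + eps)
  Ggd <- matrix(0, nrow(G), ncol(G))
  for (t in seq_len(nrow(G))) for (k in seq_len(ncol(G)))
    if (F[t, k] > 0 && Gn[t, k] > 0) Ggd[t, k] <- Gn[t, k]
  if (!is.null(af))
    for (t in seq_len(nrow(G))) Ggd[t, ] <- Ggd[t, ] * af[t]
  spans <- segmentIndices(nrow(G), segmentConfig(tseg = tseg,
                                                 overlap = overlap))
  cams <- list()
  for (i in seq_len(NROW(spans))) {
    rows <- (spans$start[i] + 1):spans$end[i]
    alpha <- numeric(ncol(G))
    for (k in seq_len(ncol(G))) alpha[k] <- mean(Ggd[rows, k])
    cam <- numeric(length(rows))
    for (t in seq_along(rows)) cam[t] <- sum(alpha * F[rows[t], ])
    cams[[i]] <- cam
  }
  list(cams = cams, spans = spans, Ggd = Ggd, Gn = Gn)
}

# tiny manifest in memory for training-path tests
tinyDataset <- function(nPerClass = 2, seed = 21L, nSpeakers = 9L) {
  man <- genDataset(nPerClass = nPerClass, seed = seed,
                    nSpeakers = nSpeakers, writeFiles = FALSE)
  list(manifest = man, utterances = attr(man, "utterances"))
}
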