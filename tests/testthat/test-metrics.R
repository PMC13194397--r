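# Faithfulness metrics and validation statistics.

# linear scoring stub: probability of class 1 rises with the masked sum of a
# fixed weight pattern, class 2 is its complement
stubProbFun <- function(W) {
  function(S, severity) {
    z <- sum(W * S)
    p <- 1 / (1 + exp(-z))
    c(p, 1 - p)
  }
}

stubMap <- function(raw) {
  methods::new("RelevanceMap", branch = "prediction", raw = raw,
               display = (raw - min(raw)) /
                 max(1e-12, diff(range(raw))),
               fps = 100, targetClass = 0L, provenance = list())
}

test_that("deletion/insertion endpoints and bounds hold for the classifier", {
  m <- tinyModel()
  u <- cleanUtterance("canoe", seed = 81)
  S <- uttSpectrogram(u)
  expl <- gradcamBaseline(m, S, 50, 3L, "prediction")
  di <- deletionInsertion(m, S, 50, expl, 3L,
                          faithfulnessConfig(steps = 5))
  B <- matrix(rowMeans(S), nrow(S), ncol(S))
  fS <- predictProbs(m, S, 50)[4]
  fB <- predictProbs(m, B, 50)[4]
  expect_equal(di$deletion$probs[1], fS)
  expect_equal(di$deletion$probs[6], fB)
  expect_equal(di$insertion$probs[1], fB)
  expect_equal(di$insertion$probs[6], fS)
  expect_true(di$deletion$aupc >= 0 && di$deletion$aupc <= 1)
  expect_true(di$insertion$aupc >= 0 && di$insertion$aupc <= 1)
  expect_error(deletionInsertion(m, S, 50, stubMap(matrix(1, 2, 2)), 3L),
               "grid")
})

test_that("curves on a 4x4 stub match exhaustive hand enumeration", {
  withr::with_seed(11, {
    W <- matrix(rnorm(16), 4, 4)
    S <- matrix(rnorm(16), 4, 4)
    raw <- matrix(runif(16), 4, 4)
  })
  f <- stubProbFun(W)
  map <- stubMap(raw)
  K <- 4L
  di <- deletionInsertion(f, S, 50, map, 0L, faithfulnessConfig(
    steps = K, baseline = "zeros"))
  # brute-force enumeration over the explicit ranking
  ord <- order(-as.vector(raw), seq_along(raw))
  delO <- insO <- numeric(K + 1)
  for (k in 0:K) {
    top <- if (k > 0) ord[seq_len(round(k / K * 16))] else integer(0)
    xd <- S; xd[top] <- 0
    xi <- matrix(0, 4, 4); xi[top] <- S[top]
    delO[k + 1] <- f(xd, 50)[1]
    insO[k + 1] <- f(xi, 50)[1]
  }
  expect_equal(di$deletion$probs, delO)
  expect_equal(di$insertion$probs, insO)
  expect_equal(di$deletion$aupc, sum((delO[-1] + delO[-5]) / 2) / K)
  # a uniform map is ranked purely by grid order, bit-reproducibly
  uni <- stubMap(matrix(1, 4, 4))
  d1 <- deletionInsertion(f, S, 50, uni, 0L,
                          faithfulnessConfig(steps = K, baseline = "zeros"))
  d2 <- deletionInsertion(f, S, 50, uni, 0L,
                          faithfulnessConfig(steps = K, baseline = "zeros"))
  expect_identical(d1$deletion$probs, d2$deletion$probs)
  xd <- S; xd[1:4] <- 0   # first step removes the first column (grid order)
  expect_equal(d1$deletion$probs[2], f(xd, 50)[1])
})

test_that("ADCC combination matches its closed forms", {
  expect_equal(adccCombine(1, 0, 0), 1)
  expect_equal(adccCombine(0.5, 0.5, 0.5), 0.5)
  expect_equal(adccCombine(0.8, 0.2, 0.1),
               3 / (1 / 0.8 + 1 / 0.8 + 1 / 0.9))
  expect_equal(adccCombine(0, 0.2, 0.1), 0)
  expect_equal(adccCombine(1, 1, 0), 0)
})

test_that("ADCC components are computed and bounded on the classifier", {
  m <- tinyModel()
  u <- cleanUtterance("sphinx", seed = 82)
  S <- uttSpectrogram(u)
  map <- gradcamBaseline(m, S, 40, 2L, "prediction")
  rep_ <- adcc(m, S, 40, map, 2L)
  for (f in c("averageDrop", "coherency", "complexity", "adcc")) {
    expect_gte(rep_[[f]], 0)
    expect_lte(rep_[[f]], 1)
  }
  expect_equal(rep_$adcc, adccCombine(rep_$coherency, rep_$complexity,
                                      rep_$averageDrop))
  expect_equal(rep_$complexity, mean(relevanceDisplay(map)))
  # coherency of a map against itself (identity mapFun) is 1
  self_ <- adcc(m, S, 40, map, 2L, mapFun = function(x) map)
  expect_equal(self_$coherency, 1)
})

test_that("binarization thresholds behave as specified", {
  expect_equal(binarizeMap(c(0, 0, 1, 1), "utterance-mean"), c(0, 0, 1, 1))
  expect_equal(binarizeMap(rep(0.3, 6), "utterance-mean"), rep(0, 6))
  # bimodal map: Otsu splits between the modes
  v <- c(rep(0.1, 50), rep(0.9, 50))
  got <- binarizeMap(v, "otsu")
  expect_equal(got, c(rep(0, 50), rep(1, 50)))
  # exhaustive threshold sweep oracle: the chosen split maximizes
  # between-class variance
  bestVar <- -Inf; bestMask <- NULL
  for (thr in seq(0.05, 0.95, by = 0.01)) {
    mask <- v > thr
    if (all(mask) || !any(mask)) next
    w1 <- mean(mask); w0 <- 1 - w1
    bc <- w0 * w1 * (mean(v[mask]) - mean(v[!mask]))^2
    if (bc > bestVar) { bestVar <- bc; bestMask <- mask * 1 }
  }
  expect_equal(got, bestMask)
  expect_warning(binarizeMap(rep(0.5, 8), "otsu"), "constant")
})

test_that("IoU and Dice follow set arithmetic and their exact relation", {
  a <- numeric(20); a[1:10] <- 1
  b <- numeric(20); b[6:15] <- 1
  r <- frameIouDice(a, b)
  expect_equal(r$iou, 1 / 3)
  expect_equal(r$dice, 0.5)
  same <- frameIouDice(a, a)
  expect_equal(same$iou, 1); expect_equal(same$dice, 1)
  disj <- frameIouDice(a, 1 - a)
  expect_equal(disj$iou, 0); expect_equal(disj$dice, 0)
  empty <- frameIouDice(numeric(5), numeric(5))
  expect_equal(empty$iou, 1); expect_equal(empty$dice, 1)
  # dice = 2 iou / (1 + iou) for random masks
  withr::with_seed(12, for (i in 1:20) {
    x <- rbinom(30, 1, 0.4); y <- rbinom(30, 1, 0.4)
    r <- frameIouDice(x, y)
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou))
    expect_lte(r$iou, r$dice)
  })
  expect_error(frameIouDice(a, b[1:10]), "lengths")
})

test_that("group statistics match hand computations", {
  same <- groupStats(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$cohensD, 0)
  expect_equal(same$ratio, 1)
  sep <- groupStats(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)   # no pair with a > b
  expect_lt(sep$cohensD, 0)
  # location-shift identity: shifting one group by c changes d by c/pooledSD
  withr::with_seed(13, { a <- rnorm(10); b <- rnorm(10) })
  base <- groupStats(a, b)
  shift <- groupStats(a + 2, b)
  pooled <- sqrt((9 * var(a) + 9 * var(b)) / 18)
  expect_equal(shift$cohensD - base$cohensD, 2 / pooled)
  zv <- groupStats(c(1, 1, 1), c(0, 0, 0))
  expect_true(is.infinite(zv$cohensD) && zv$cohensD > 0)
})

test_that("Spearman statistics agree with stats::cor.test", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearmanStat(x, x)$rho, 1)
  expect_equal(spearmanStat(x, -x)$rho, -1)
  expect_equal(spearmanStat(x, x)$p, 0)
  withr::with_seed(14, { x <- rnorm(25); y <- x + rnorm(25) })
  got <- spearmanStat(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 0.05)
  # worked n = 5 example against the rank formula (no ties)
  x5 <- c(10, 20, 30, 40, 50); y5 <- c(1, 3, 2, 5, 4)
  d <- rank(x5) - rank(y5)
  expect_equal(spearmanStat(x5, y5)$rho, 1 - 6 * sum(d^2) / (5 * 24))
  expect_warning(spearmanStat(rep(1, 5), 1:5), "constant")
})

test_that("baseline maps have the documented structure", {
  m <- tinyModel()
  u <- cleanUtterance("comb", seed = 83)
  S <- uttSpectrogram(u)
  en <- baselineMaps(S, "energy")
  inv <- baselineMaps(S, "inverted-energy")
  expect_equal(relevanceRaw(en)[1, ] + relevanceRaw(inv)[1, ],
               rep(1, ncol(S)))
  # silence framing: append near-silence and the energy map stays low there
  S2 <- cbind(S, matrix(log(1e-6), nrow(S), 30))
  en2 <- baselineMaps(S2, "energy")
  expect_lt(mean(relevanceRaw(en2)[1, (ncol(S) + 1):(ncol(S) + 30)]), 0.05)
  expect_gt(mean(relevanceRaw(baselineMaps(S2, "inverted-energy"))[
    1, (ncol(S) + 1):(ncol(S) + 30)]), 0.95)
  # random baseline: shuffle-invariant for constants, seed-reproducible
  constMap <- stubMap(matrix(4, nrow(S), ncol(S)))
  r1 <- baselineMaps(S, "random", refMap = constMap, nTrials = 5, seed = 3)
  expect_true(all(relevanceRaw(r1) == 4))
  someMap <- gradcamBaseline(m, S, 60, 1L, "impairment")
  r2 <- baselineMaps(S, "random", refMap = someMap, nTrials = 5, seed = 3)
  r3 <- baselineMaps(S, "random", refMap = someMap, nTrials = 5, seed = 3)
  expect_identical(relevanceRaw(r2), relevanceRaw(r3))
  expect_equal(mean(relevanceRaw(r2)), mean(relevanceRaw(someMap)),
               tolerance = 1e-9)
})

test_that("map-versus-truth IoU rewards maps aligned with anomaly spans", {
  u <- cleanUtterance("cactus", seed = 84)
  u2 <- plantAnomalies(u, severityToAnomaly(45),
                       plan = list(pauseAfter = 2L, pauseDur = 0.6),
                       seed = 9)
  S <- uttSpectrogram(u2)
  tm <- truthMask(u2, 100, ncol(S))
  expect_true(any(tm == 1) && any(tm == 0))
  aligned <- stubMap(matrix(rep(tm, each = nrow(S)) + 1e-9, nrow(S)))
  off <- stubMap(matrix(rep(1 - tm, each = nrow(S)) + 1e-9, nrow(S)))
  expect_gt(mapTruthIoU(aligned, u2)$iou, 0.9)
  expect_lt(mapTruthIoU(off, u2)$iou, 0.1)
})
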