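# Attribution core: normalization, dual filtering, gating, segmentation,
# aggregation, perturbation accumulation, end-to-end reductions.

test_that("gradient normalization matches its closed form", {
  z <- matrix(0, 3, 4)
  expect_equal(normalizeGradients(z), z)
  one <- matrix(2.0, 1, 1)
  expect_equal(normalizeGradients(one), matrix(2.0 / (4.0 + 1e-5), 1, 1))
  withr::with_seed(2, G <- matrix(rnorm(24), 4, 6))
  m <- mean(G^2)
  expect_equal(normalizeGradients(G), G / (m + 1e-5))
  # scaling behaviour against direct recomputation
  c_ <- 3.7
  expect_equal(normalizeGradients(c_ * G), (c_ * G) / (mean((c_ * G)^2) + 1e-5))
})

test_that("dual filtering keeps exactly the doubly-positive cells", {
  withr::with_seed(3, {
    G <- matrix(rnorm(20), 5, 4)
    F <- matrix(rnorm(20), 5, 4)
  })
  got <- dualFilter(G, F)
  oracle <- matrix(0, 5, 4)
  for (t in 1:5) for (k in 1:4)
    if (F[t, k] > 0 && G[t, k] > 0) oracle[t, k] <- G[t, k]
  expect_equal(got, oracle)
  expect_true(all(got >= 0))
  expect_equal(dualFilter(-abs(G), F), matrix(0, 5, 4))
  Gp <- abs(G); Fp <- abs(F)
  expect_equal(dualFilter(Gp, Fp), Gp)
  expect_error(dualFilter(G, F[, 1:3]), "match")
})

test_that("aphasia-filter gating is a per-frame scalar product", {
  withr::with_seed(4, G <- abs(matrix(rnorm(18), 6, 3)))
  expect_equal(gateWithFilter(G, rep(0, 6)), G * 0)
  expect_equal(gateWithFilter(G, rep(1, 6)), G)
  expect_equal(gateWithFilter(G, rep(2.5, 6)), 2.5 * G)
  af <- c(0, 1.2, 3.7, 0, 1, 2.2)
  got <- gateWithFilter(G, af)
  for (t in 1:6) expect_equal(got[t, ], G[t, ] * af[t])
  expect_error(gateWithFilter(G, rep(1, 5)), "frames")
})

test_that("segment starts follow the overlap formula and tile when O = 0", {
  s <- segmentIndices(25, segmentConfig(tseg = 10, overlap = 0.5))
  expect_equal(s$start, c(0, 5, 10, 15, 20))
  expect_equal(s$end, c(10, 15, 20, 25, 25))
  # O = 0 tiles without overlap
  s0 <- segmentIndices(23, segmentConfig(tseg = 10, overlap = 0))
  expect_equal(s0$start, c(0, 10, 20))
  expect_equal(s0$end, c(10, 20, 23))
  cover <- numeric(23)
  for (i in seq_len(NROW(s0))) {
    r <- (s0$start[i] + 1):s0$end[i]
    cover[r] <- cover[r] + 1
  }
  expect_true(all(cover == 1))
  # degenerate: segment longer than the sequence
  sd_ <- segmentIndices(7, segmentConfig(tseg = 10, overlap = 0.5))
  expect_equal(sd_, data.frame(start = 0L, end = 7L))
  # whole-sequence segment
  s1 <- segmentIndices(10, segmentConfig(tseg = 10, overlap = 0))
  expect_equal(s1, data.frame(start = 0L, end = 10L))
})

test_that("segment weights and CAMs match their formulas", {
  expect_equal(segmentWeights(matrix(0.7, 5, 3)), rep(0.7, 3))
  expect_equal(segmentWeights(matrix(0, 2, 4)), rep(0, 4))
  withr::with_seed(5, G <- matrix(rnorm(12), 4, 3))
  expect_equal(segmentWeights(G), apply(G, 2, mean))
  withr::with_seed(6, F <- matrix(rnorm(12), 4, 3))
  ek <- c(0, 1, 0)
  expect_equal(segmentCam(ek, F), F[, 2])
  expect_equal(segmentCam(c(0, 0, 0), F), rep(0, 4))
  alpha <- rnorm(3)
  expect_equal(segmentCam(alpha, F), as.vector(F %*% alpha))
  # retained frequency axis: block-wise matrix products
  withr::with_seed(7, F2 <- matrix(rnorm(24), 4, 6))
  fa <- c(1L, 1L, 2L, 2L, 3L, 3L)
  alpha2 <- rnorm(6)
  got <- segmentCam(alpha2, F2, fa)
  expect_equal(dim(got), c(4L, 3L))
  for (f in 1:3) {
    k <- which(fa == f)
    expect_equal(got[, f], as.vector(F2[, k] %*% alpha2[k]))
  }
})

test_that("aggregation averages overlaps by coverage and preserves constants", {
  cfgNoSmooth <- segmentConfig(tseg = 10, overlap = 0.5, smoothWidth = 0,
                               outMel = 4L)
  # constant segment CAMs give a constant canvas
  spans <- data.frame(start = c(0L, 5L), end = c(10L, 15L))
  agg <- aggregateCams(list(rep(2, 10), rep(2, 10)), spans, 15, cfgNoSmooth,
                       outFrames = 15)
  expect_true(all(abs(relevanceRaw(agg) - 2) < 1e-12))
  # two overlapping segments a, b: overlap = (a + b) / 2 before smoothing
  a <- seq(1, 2, length.out = 10); b <- seq(4, 3, length.out = 10)
  agg2 <- aggregateCams(list(a, b), spans, 15, cfgNoSmooth, outFrames = 15)
  prof <- relevanceRaw(agg2)[1, ]
  expect_equal(prof[6:10], (a[6:10] + b[1:5]) / 2)
  expect_equal(prof[1:5], a[1:5])
  expect_equal(prof[11:15], b[6:10])
  expect_error(aggregateCams(list(), spans, 15, cfgNoSmooth), "empty")
})

test_that("a single full-span segment equals the unsegmented CAM path", {
  m <- tinyModel()
  u <- cleanUtterance("house", seed = 71)
  S <- uttSpectrogram(u)
  g <- classGradient(m, S, 60, 1L)
  tap <- forwardWithTaps(m, S, 60)@taps$impairment
  Tn <- nrow(tapValues(tap))
  Gn <- normalizeGradients(g$impairment@values)
  Ggd <- dualFilter(Gn, tapValues(tap))
  # global path: one alpha over all frames
  alpha <- segmentWeights(Ggd)
  camGlobal <- pmax(segmentCam(alpha, tapValues(tap)), 0)
  cfg1 <- segmentConfig(tseg = Tn, overlap = 0, smoothWidth = 0)
  spans <- segmentIndices(Tn, cfg1)
  agg <- aggregateCams(list(segmentCam(alpha, tapValues(tap))), spans, Tn,
                       cfg1, outFrames = Tn)
  expect_equal(relevanceRaw(agg)[1, ], camGlobal, tolerance = 1e-12)
})

test_that("composed pipeline matches a straight-line reimplementation", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      Tn <- sample(4:8, 1); K <- sample(3:6, 1)
      G <- matrix(rnorm(Tn * K), Tn, K)
      F <- matrix(rnorm(Tn * K), Tn, K)
      af <- runif(Tn, 0, 3.7)
      tseg <- sample(2:Tn, 1)
      oracle <- straightLineCam(G, F, af = af, tseg = tseg, overlap = 0)
      Gn <- normalizeGradients(G)
      Ggd <- gateWithFilter(dualFilter(Gn, F), af)
      expect_lt(max(abs(Ggd - oracle$Ggd)), 1e-10)
      spans <- segmentIndices(Tn, segmentConfig(tseg = tseg, overlap = 0))
      for (i in seq_len(NROW(spans))) {
        rows <- (spans$start[i] + 1):spans$end[i]
        alpha <- segmentWeights(Ggd[rows, , drop = FALSE])
        cam <- segmentCam(alpha, F[rows, , drop = FALSE])
        expect_lt(max(abs(cam - oracle$cams[[i]])), 1e-10)
      }
    }
  })
})

test_that("perturbation accumulation reduces to the base gradient at N = 0", {
  m <- tinyModel()
  u <- cleanUtterance("bench", seed = 72)
  S <- uttSpectrogram(u)
  base <- classGradient(m, S, 55, 2L)
  acc <- accumulateGradients(m, S, 55, 2L, perturbationConfig(n = 0L))
  expect_identical(acc$gradients$prediction, base$prediction@values)
  expect_identical(acc$gradients$impairment, base$impairment@values)
  expect_equal(NROW(acc$trace$prediction), 0)
})

test_that("sigma stays fixed with zero step size and is capped at pMax", {
  m <- tinyModel()
  u <- cleanUtterance("comb", seed = 73)
  S <- uttSpectrogram(u)
  acc <- accumulateGradients(m, S, 50, 1L,
                             perturbationConfig(n = 3L, sigma0 = 0.02,
                                                stepSize = 0))
  expect_equal(acc$trace$prediction$sigma, rep(0.02, 3))
  expect_equal(acc$trace$impairment$sigma, rep(0.02, 3))
  # large step: sigma must be monotone and capped
  acc2 <- accumulateGradients(m, S, 50, 1L,
                              perturbationConfig(n = 4L, sigma0 = 0.01,
                                                 pMax = 0.015,
                                                 stepSize = 1e6))
  for (br in c("prediction", "impairment")) {
    sig <- acc2$trace[[br]]$sigma
    expect_true(all(diff(sig) >= 0))
    expect_true(all(sig <= 0.015 + 1e-12))
  }
  expect_warning(
    accumulateGradients(m, S, 50, 1L,
                        perturbationConfig(n = 1L, sigma0 = 0, stepSize = 0)),
    "no-ops")
})

test_that("accumulation equals an explicitly coded perturbation loop", {
  m <- tinyModel()
  u <- cleanUtterance("canoe", seed = 74)
  S <- uttSpectrogram(u)
  cfg <- perturbationConfig(n = 2L, sigma0 = 0.02, pMax = 0.1,
                            stepSize = 0.05, seed = 123L)
  acc <- accumulateGradients(m, S, 45, 3L, cfg)
  # independent loop with the same RNG protocol
  base <- classGradient(m, S, 45, 3L)
  oracle <- withr::with_seed(123L, {
    out <- list()
    for (br in c("prediction", "impairment")) {
      G <- base[[br]]@values
      sigma <- cfg$sigma0
      for (p in 1:cfg$n) {
        noise <- matrix(rnorm(length(S)) * sigma, nrow(S))
        gp <- classGradient(m, S + noise, 45, 3L)[[br]]@values
        G <- G + gp
        sigma <- min(cfg$pMax, sigma + cfg$stepSize * mean(abs(gp)))
      }
      out[[br]] <- G
    }
    out
  })
  expect_identical(acc$gradients$prediction, oracle$prediction)
  expect_identical(acc$gradients$impairment, oracle$impairment)
})

test_that("explanations obey gating nullity, linearity and determinism", {
  m <- tinyModel()
  u <- cleanUtterance("cactus", seed = 75)
  mkConst <- function(val, n) {
    mk <- function(x, ty) methods::new("AnomalyMask", type = ty,
                                       values = x, fps = 100)
    masks <- list(pause = mk(as.numeric(rep(val > 0, n)), "pause"),
                  mispronunciation = mk(numeric(n), "mispronunciation"),
                  boundary = mk(numeric(n), "boundary"))
    buildCompositeFilter(masks, filterWeights(pause = max(val, 0)))
  }
  S <- uttSpectrogram(u)
  n <- ncol(S)
  pc <- perturbationConfig(n = 2L, seed = 7L)
  # AF = 0 kills the impairment map, leaves the prediction map alone
  e0 <- acamExplain(m, u, perturbation = pc, filter = mkConst(0, n))
  e1 <- acamExplain(m, u, perturbation = pc, filter = mkConst(1, n))
  expect_true(all(relevanceRaw(impairmentMap(e0)) == 0))
  expect_equal(relevanceRaw(predictionMap(e0)),
               relevanceRaw(predictionMap(e1)))
  # AF = c scales the raw impairment map by c (display copy exempt)
  eC <- acamExplain(m, u, perturbation = pc, filter = mkConst(2.5, n))
  expect_equal(relevanceRaw(impairmentMap(eC)),
               2.5 * relevanceRaw(impairmentMap(e1)), tolerance = 1e-10)
  # determinism under a fixed seed
  e1b <- acamExplain(m, u, perturbation = pc, filter = mkConst(1, n))
  expect_identical(relevanceRaw(predictionMap(e1)),
                   relevanceRaw(predictionMap(e1b)))
  expect_identical(relevanceRaw(impairmentMap(e1)),
                   relevanceRaw(impairmentMap(e1b)))
  # raw maps are non-negative; display maps live in [0, 1] with same argmax
  for (mp in list(predictionMap(e1), impairmentMap(e1))) {
    expect_true(all(relevanceRaw(mp) >= 0))
    expect_true(all(relevanceDisplay(mp) >= 0 & relevanceDisplay(mp) <= 1))
    expect_equal(which.max(relevanceRaw(mp)), which.max(relevanceDisplay(mp)))
  }
})

test_that("the Grad-CAM baseline follows its defining reduction", {
  m <- tinyModel()
  u <- cleanUtterance("house", seed = 76)
  S <- uttSpectrogram(u)
  gc <- gradcamBaseline(m, S, 60, 4L, "impairment")
  # oracle: GAP weights x features, ReLU, broadcast
  g <- classGradient(m, S, 60, 4L)$impairment@values
  tap <- forwardWithTaps(m, S, 60)@taps$impairment
  cam <- pmax(as.vector(tapValues(tap) %*% colMeans(g)), 0)
  profile <- relevanceRaw(gc)[1, ]
  expect_equal(profile, linResample(cam, ncol(S)), tolerance = 1e-12)
  # zero gradients give a zero map
  m0 <- m; m0@params$Win <- m0@params$Win * 0
  gc0 <- gradcamBaseline(m0, S, 60, 4L, "prediction")
  expect_true(all(relevanceRaw(gc0) == 0))
})
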