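# Aphasia filter: VAD pauses, edit-distance alignment, boundary gaps,
# mask rasterization, weighted composition, grid resampling.

test_that("energy VAD classifies silence and speech correctly", {
  sr <- 16000
  withr::with_seed(4, {
    silence <- rnorm(sr) * 0.001            # 1 s at about -60 dBFS
    tone <- sin(2 * pi * 440 * (0:(sr - 1)) / sr) * 0.5
  })
  p1 <- detectPauses(silence, vadConfig(thresholdDb = -40, minPause = 0.25))
  expect_equal(NROW(p1), 1)
  expect_equal(p1$start, 0, tolerance = 0.02)
  expect_equal(p1$end, 1, tolerance = 0.03)
  expect_equal(NROW(detectPauses(tone)), 0)
  # a planted pause is recovered within a hop or two
  u <- cleanUtterance("cactus", seed = 61)
  u2 <- plantAnomalies(u, severityToAnomaly(50),
                       plan = list(pauseAfter = 2L, pauseDur = 0.4), seed = 6)
  det <- detectPauses(waveform(u2))
  truth <- truthIntervals(u2)$pause
  expect_equal(NROW(det), 1)
  expect_lt(abs(det$start - truth$start), 0.03)
  expect_lt(abs(det$end - truth$end), 0.03)
})

test_that("alignment reproduces hand-checkable edit scripts", {
  mkTier <- function(syms, dur = 0.1) {
    n <- length(syms)
    data.frame(symbol = syms, start = (0:(n - 1)) * dur, end = (1:n) * dur)
  }
  # identical sequences: all matches
  ops <- alignPhonemes(c("k", "ae", "t"), mkTier(c("k", "ae", "t")))
  expect_true(all(ops$kind == "match"))
  expect_equal(attr(ops, "distance"), 0)
  # single deletion in the middle
  ops <- alignPhonemes(c("k", "ae", "k", "t", "ax", "s"),
                       mkTier(c("k", "ae", "t", "ax", "s")))
  expect_equal(sum(ops$kind == "deletion"), 1)
  expect_equal(sum(ops$kind != "match"), 1)
  # empty produced tier: all deletions
  ops <- alignPhonemes(c("a", "b", "c"), data.frame(symbol = character(0),
                                                    start = numeric(0),
                                                    end = numeric(0)))
  expect_equal(sum(ops$kind == "deletion"), 3)
  # deletion spans are non-empty and sit between the flanking segments
  ops <- alignPhonemes(c("k", "ae", "k", "t"), mkTier(c("k", "ae", "t")))
  del <- ops[ops$kind == "deletion", ]
  expect_equal(NROW(del), 1)
  expect_gt(del$end, del$start)
  expect_gte(del$start, 0.19)
  expect_lte(del$end, 0.21)
})

test_that("alignment cost equals an independent Levenshtein oracle", {
  syms <- letters[1:6]
  withr::with_seed(99, {
    for (rep in 1:30) {
      a <- sample(syms, sample(1:10, 1), replace = TRUE)
      b <- sample(syms, sample(0:10, 1), replace = TRUE)
      tier <- if (length(b))
        data.frame(symbol = b, start = (seq_along(b) - 1) * 0.1,
                   end = seq_along(b) * 0.1)
      else data.frame(symbol = character(0), start = numeric(0),
                      end = numeric(0))
      ops <- alignPhonemes(a, tier)
      expect_equal(sum(ops$kind != "match"), levenshteinOracle(a, b))
      # bookkeeping: every canonical and produced index appears exactly once
      expect_equal(sort(ops$canonicalIndex[!is.na(ops$canonicalIndex)]),
                   seq_along(a))
      expect_equal(sort(ops$producedIndex[!is.na(ops$producedIndex)]),
                   seq_along(b))
    }
  })
})

test_that("boundary-gap detection flags exactly the oversized gaps", {
  one <- data.frame(word = "w", start = 0, end = 1)
  expect_equal(NROW(detectBoundaryErrors(one)), 0)
  two <- data.frame(word = c("a", "b"), start = c(0, 1.5), end = c(1, 2))
  got <- detectBoundaryErrors(two, boundaryConfig(maxGap = 0.3))
  expect_equal(got, data.frame(start = 1, end = 1.5))
  expect_equal(NROW(detectBoundaryErrors(two, boundaryConfig(maxGap = 0.6))),
               0)
  # planted boundary shift recovered with high IoU
  u <- cleanUtterance("canoe", seed = 62)
  u2 <- plantAnomalies(u, severityToAnomaly(40),
                       plan = list(boundaryShiftAt = 1L,
                                   boundaryDelta = 0.5), seed = 7)
  det <- detectBoundaryErrors(wordTier(u2))
  expect_gte(intervalIoU(det, truthIntervals(u2)$boundary), 0.8)
})

test_that("mask rasterization follows frame-center containment", {
  m <- intervalsToMask(emptyIntervals(), 100, 50, "pause")
  expect_true(all(maskValues(m) == 0))
  m <- intervalsToMask(data.frame(start = 0, end = 1), 100, 50, "pause")
  expect_true(all(maskValues(m) == 1))
  # [0.10, 0.20) at 100 fps sets 0-based frames 10..19
  m <- intervalsToMask(data.frame(start = 0.10, end = 0.20), 100, 50,
                       "mispronunciation")
  expect_equal(which(maskValues(m) == 1), 11:20)
  expect_error(intervalsToMask(data.frame(start = -0.1, end = 0.2), 100, 50,
                               "pause"), "negative")
})

test_that("the composite filter is the exact weighted mask sum", {
  mk <- function(idx, n = 30, type = "pause") {
    v <- numeric(n); v[idx] <- 1
    methods::new("AnomalyMask", type = type, values = v, fps = 100)
  }
  masks <- list(pause = mk(11:20), mispronunciation = mk(16:25,
                                                         type = "mispronunciation"),
                boundary = mk(integer(0), type = "boundary"))
  af <- buildCompositeFilter(masks, filterWeights())
  v <- filterValues(af)
  expect_equal(v[11:15], rep(1.0, 5))
  expect_equal(v[16:20], rep(2.2, 5))
  expect_equal(v[21:25], rep(1.2, 5))
  expect_equal(v[c(1:10, 26:30)], rep(0, 15))
  # all three masks on: the weight sum 1.0 + 1.2 + 1.5 = 3.7
  all3 <- list(pause = mk(1:30), mispronunciation = mk(1:30,
                                                       type = "mispronunciation"),
               boundary = mk(1:30, type = "boundary"))
  expect_true(all(filterValues(buildCompositeFilter(all3)) == 3.7))
  # zero masks, zero filter; and the bound holds
  none <- list(pause = mk(integer(0)),
               mispronunciation = mk(integer(0), type = "mispronunciation"),
               boundary = mk(integer(0), type = "boundary"))
  expect_true(all(filterValues(buildCompositeFilter(none)) == 0))
  expect_true(all(v >= 0 & v <= sum(filterWeights())))
  bad <- masks; bad$boundary <- mk(integer(0), n = 10, type = "boundary")
  expect_error(buildCompositeFilter(bad), "grid")
})

test_that("filter resampling preserves values and step edges", {
  mk <- function(v) {
    masks <- list(
      pause = methods::new("AnomalyMask", type = "pause", values = as.numeric(v > 0),
                           fps = 100),
      mispronunciation = methods::new("AnomalyMask", type = "mispronunciation",
                                      values = v * 0, fps = 100),
      boundary = methods::new("AnomalyMask", type = "boundary", values = v * 0,
                              fps = 100))
    buildCompositeFilter(masks, filterWeights(pause = 1))
  }
  v <- c(rep(0, 20), rep(1, 20))
  af <- mk(v)
  same <- resampleFilter(af, 40, 100)
  expect_identical(filterValues(same), filterValues(af))
  const <- mk(rep(1, 40))
  down <- resampleFilter(const, 17, 42.5)
  expect_true(all(filterValues(down) == 1))
  expect_equal(length(filterValues(down)), 17)
  # 2:1 downsample: the step edge moves by at most one target frame
  half <- resampleFilter(af, 20, 50)
  expect_true(all(filterValues(half) %in% c(0, 1)))
  edge <- which(diff(filterValues(half)) == 1)
  expect_lte(abs(edge - 10), 1)
  expect_error(resampleFilter(af, 0, 50), "zero-length")
})

test_that("planted anomalies of each type are recovered with high IoU", {
  ious <- list(pause = numeric(0), mispronunciation = numeric(0),
               boundary = numeric(0))
  kws <- names(keywordInventory())
  for (i in 1:10) {
    kw <- kws[(i %% 15) + 1]
    u <- cleanUtterance(kw, seed = 900 + i)
    ks <- keywordInventory()[[kw]]
    nPh <- length(ks$phonemes)
    internal <- which(ks$wordOf[-nPh] == ks$wordOf[-1])
    plan <- list(pauseAfter = internal[1], pauseDur = 0.7,
                 substituteAt = 3L,
                 substituteWith = setdiff(names(phonemeInventory()),
                                          ks$phonemes)[1],
                 boundaryShiftAt = 1L, boundaryDelta = 0.5)
    u2 <- plantAnomalies(u, severityToAnomaly(40), plan = plan,
                         seed = 950 + i)
    truth <- truthIntervals(u2)
    det <- detectPauses(waveform(u2))
    ious$pause <- c(ious$pause, intervalIoU(det, truth$pause))
    ops <- alignPhonemes(canonicalPhonemes(u2), producedTier(u2))
    mis <- ops[ops$kind != "match", c("start", "end")]
    ious$mispronunciation <- c(ious$mispronunciation,
                               intervalIoU(mis, truth$mispronunciation))
    gaps <- detectBoundaryErrors(wordTier(u2))
    ious$boundary <- c(ious$boundary, intervalIoU(gaps, truth$boundary))
  }
  expect_gte(mean(ious$pause), 0.9)
  expect_gte(mean(ious$mispronunciation), 0.9)
  expect_gte(mean(ious$boundary), 0.9)
})

test_that("mean filter activation falls as severity rises", {
  sevs <- seq(20.5, 94.8, length.out = 60)
  kws <- names(keywordInventory())
  af <- vapply(seq_along(sevs), function(i) {
    u <- genKeywordWaveform(keywordInventory()[[kws[(i %% 15) + 1]]],
                            severity = sevs[i], seed = 1200 + i)
    u2 <- plantAnomalies(u, severityToAnomaly(sevs[i]), seed = 1600 + i)
    mean(filterValues(buildAphasiaFilter(u2)))
  }, numeric(1))
  st <- spearmanStat(af, sevs)
  expect_lt(st$rho, 0)
  expect_lt(st$p, 0.01)
})
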