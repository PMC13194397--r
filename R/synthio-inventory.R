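# Phoneme inventory and keyword specifications.
#
# Phoneme acoustics are stylized spectral recipes (per-band center frequency,
# bandwidth and relative amplitude), not naturalistic speech: each phoneme is
# rendered as a harmonic tone stack plus narrow-band noise in its bands. The
# classifier only needs separable classes; the explanation machinery needs
# ground-truth anomaly locations, which this representation makes exact.

band <- function(center, bandwidth, amp) {
  data.frame(center = center, bandwidth = bandwidth, amp = amp)
}

#' Phoneme inventory with spectral recipes
#'
#' Each phoneme maps to a recipe: a data.frame of `(center, bandwidth, amp)`
#' bands, the first band being dominant, plus a voicing flag and a default
#' duration in seconds. Symbols are simplified ARPAbet.
#' @return named list of phoneme recipes.
#' @export
phonemeInventory <- function() {
  v <- function(f1, f2, dur = 0.14) list(
    bands = rbind(band(f1, 120, 1.0), band(f2, 160, 0.6)),
    voiced = TRUE, duration = dur)
  cns <- function(f, bw = 600, dur = 0.09, amp2 = NULL) {
    b <- band(f, bw, 1.0)
    if (!is.null(amp2)) b <- rbind(b, amp2)
    list(bands = b, voiced = FALSE, duration = dur)
  }
  list(
    # vowels: rough (F1, F2) targets
    iy = v(310, 2350), ih = v(410, 2000), eh = v(560, 1860), ae = v(700, 1720),
    aa = v(760, 1090), ao = v(590, 920),  uw = v(330, 800),  uh = v(460, 1050),
    ah = v(640, 1250), er = v(500, 1450), ey = v(440, 2120), ow = v(510, 860),
    aw = v(710, 1320), ay = v(730, 1830), oy = v(550, 1620), ax = v(520, 1390, 0.10),
    # sonorant consonants
    m = v(260, 1150, 0.09), n = v(300, 1500, 0.09), ng = v(280, 1320, 0.09),
    l = v(380, 1080, 0.09), r = v(420, 1210, 0.09), w = v(350, 720, 0.08),
    y = v(300, 2250, 0.08),
    # obstruents: dominant noise/burst band
    b = cns(480, 400, 0.07),  d = cns(1650, 500, 0.07), g = cns(1250, 500, 0.07),
    p = cns(880, 500, 0.07),  t = cns(4050, 900, 0.07), k = cns(1950, 700, 0.07),
    f = cns(4450, 1100, 0.09), s = cns(5500, 1300, 0.10), sh = cns(3450, 1100, 0.10),
    th = cns(5050, 1200, 0.08), ch = cns(2550, 900, 0.08), v = cns(360, 300, 0.08),
    z = cns(4800, 1200, 0.09), h = cns(1750, 1300, 0.07))
}

#' Build a keyword specification
#'
#' @param keywordId integer class id in `[0, 14]`.
#' @param phonemes character vector of phoneme symbols (inventory keys).
#' @param durations per-phoneme durations in seconds (defaults from the
#'   inventory when `NULL`).
#' @param wordOf integer vector assigning each phoneme to a word-tier unit.
#' @param words labels of the word-tier units.
#' @return validated `keywordSpec` list.
#' @export
keywordSpec <- function(keywordId, phonemes, durations = NULL,
                        wordOf = rep(1L, length(phonemes)),
                        words = "word") {
  inv <- phonemeInventory()
  stopifnot2(length(phonemes) >= 2, "a keyword needs at least 2 phonemes")
  stopifnot2(all(phonemes %in% names(inv)),
             paste("unknown phoneme symbol(s):",
                   paste(setdiff(phonemes, names(inv)), collapse = ", ")))
  if (is.null(durations))
    durations <- vapply(phonemes, function(p) inv[[p]]$duration, numeric(1))
  stopifnot2(all(durations > 0), "phoneme durations must be positive")
  stopifnot2(length(durations) == length(phonemes),
             "durations and phonemes differ in length")
  stopifnot2(length(wordOf) == length(phonemes) &&
               all(wordOf %in% seq_along(words)),
             "wordOf must index into words for every phoneme")
  structure(list(keywordId = as.integer(keywordId), phonemes = phonemes,
                 durations = unname(durations), wordOf = as.integer(wordOf),
                 words = words),
            class = "keywordSpec")
}

#' The 15 keyword classes
#'
#' Confrontation-naming items (Boston Naming Test style), each rendered as a
#' two-word carrier phrase "a <keyword>" so the word tier has a junction where
#' boundary anomalies can occur. The 15 specs are pairwise distinct in at
#' least one dominant-band center frequency.
#' @return list of 15 [keywordSpec()] objects, ids 0..14.
#' @export
keywordInventory <- function() {
  defs <- list(
    beaver      = c("b", "iy", "v", "er"),
    bench       = c("b", "eh", "n", "ch"),
    cactus      = c("k", "ae", "k", "t", "ah", "s"),
    canoe       = c("k", "ah", "n", "uw"),
    comb        = c("k", "ow", "m"),
    hammock     = c("h", "ae", "m", "ah", "k"),
    house       = c("h", "aw", "s"),
    octopus     = c("aa", "k", "t", "ah", "p", "uh", "s"),
    palette     = c("p", "ae", "l", "ah", "t"),
    sphinx      = c("s", "f", "ih", "ng", "k", "s"),
    stethoscope = c("s", "t", "eh", "th", "ah", "s", "k", "ow", "p"),
    toothbrush  = c("t", "uw", "th", "b", "r", "ah", "sh"),
    tripod      = c("t", "r", "ay", "p", "aa", "d"),
    unicorn     = c("y", "uw", "n", "ah", "k", "ao", "r", "n"),
    volcano     = c("v", "aa", "l", "k", "ey", "n", "ow"))
  specs <- vector("list", length(defs))
  for (i in seq_along(defs)) {
    ph <- c("ax", defs[[i]])
    specs[[i]] <- keywordSpec(
      keywordId = i - 1L, phonemes = ph,
      wordOf = c(1L, rep(2L, length(defs[[i]]))),
      words = c("a", names(defs)[i]))
  }
  names(specs) <- names(defs)
  stopifnot2(keywordRecipesDistinct(specs),
             "keyword recipes are not pairwise distinct")
  specs
}

# pairwise distinctness of dominant-center-frequency sequences
keywordRecipesDistinct <- function(specs) {
  inv <- phonemeInventory()
  sig <- vapply(specs, function(s)
    paste(vapply(s$phonemes, function(p) inv[[p]]$bands$center[1], numeric(1)),
          collapse = ","), character(1))
  !anyDuplicated(sig)
}
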