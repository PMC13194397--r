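# Annotation round-trip: Praat TextGrid (interval tiers "phones-produced",
# "words") plus a JSON sidecar carrying the canonical phoneme sequence,
# severity, keyword id, correctness and truth intervals. The sidecar schema
# is versioned; readers reject unknown versions and missing fields by name.

SIDE_SCHEMA <- "acamspeech-annotation-1"

fmtNum <- function(x) sprintf("%.17g", x)

#' Write utterance annotations (TextGrid + JSON sidecar)
#'
#' @param utt an [Utterance-class].
#' @param path TextGrid output path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(utt, path) {
  dur <- length(waveform(utt)) / sampleRate(utt)
  tiers <- list(
    `phones-produced` = data.frame(label = producedTier(utt)$symbol,
                                   start = producedTier(utt)$start,
                                   end = producedTier(utt)$end),
    words = data.frame(label = wordTier(utt)$word,
                       start = wordTier(utt)$start,
                       end = wordTier(utt)$end))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = 0")
  w("xmax = %s", fmtNum(dur))
  w("tiers? <exists>")
  w("size = %d", length(tiers))
  w("item []:")
  for (i in seq_along(tiers)) {
    tier <- tiers[[i]]
    w("    item [%d]:", i)
    w('        class = "IntervalTier"')
    w('        name = "%s"', names(tiers)[i])
    w("        xmin = 0")
    w("        xmax = %s", fmtNum(dur))
    w("        intervals: size = %d", NROW(tier))
    for (j in seq_len(NROW(tier))) {
      w("        intervals [%d]:", j)
      w("            xmin = %s", fmtNum(tier$start[j]))
      w("            xmax = %s", fmtNum(tier$end[j]))
      w('            text = "%s"', tier$label[j])
    }
  }
  side <- list(
    schema = SIDE_SCHEMA,
    canonical_phonemes = as.list(canonicalPhonemes(utt)),
    severity = severity(utt),
    keyword_id = keywordId(utt),
    correctness = correctness(utt),
    truth_intervals = lapply(truthIntervals(utt), function(iv)
      lapply(seq_len(NROW(iv)), function(i) list(start = iv$start[i],
                                                 end = iv$end[i]))))
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecarPath <- function(path) sub("\\.TextGrid$", ".json", path)

parseTextGrid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  num <- function(l) as.numeric(sub('^.*= *', "", l))
  txt <- function(l) sub('" *$', "", sub('^.*= *"', "", l))
  tiers <- list(); cur <- NULL; curName <- NULL; iv <- NULL
  i <- 1
  while (i <= length(lines)) {
    l <- lines[i]
    if (grepl('name = "', l)) {
      if (!is.null(curName)) tiers[[curName]] <- do.call(rbind, cur)
      curName <- txt(l); cur <- list()
    } else if (grepl("intervals \\[", l)) {
      s <- num(lines[i + 1]); e <- num(lines[i + 2]); lab <- txt(lines[i + 3])
      cur[[length(cur) + 1L]] <- data.frame(label = lab, start = s, end = e)
      i <- i + 3
    }
    i <- i + 1
  }
  if (!is.null(curName)) tiers[[curName]] <- do.call(rbind, cur)
  tiers
}

#' Read utterance annotations
#'
#' Parses the TextGrid tiers and JSON sidecar, validates them against the
#' utterance invariants (time-sorted, non-overlapping tiers; required sidecar
#' fields; known schema version) and returns them; if `wavPath` is given the
#' waveform is attached and a full [Utterance-class] is returned.
#'
#' @param path TextGrid path (sidecar expected next to it).
#' @param wavPath optional WAV path.
#' @return list with `producedTier`, `wordTier`, `canonicalPhonemes`,
#'   `severity`, `keywordId`, `correctness`, `truthIntervals` — or an
#'   [Utterance-class] when `wavPath` is given.
#' @export
readAnnotations <- function(path, wavPath = NULL) {
  stopifnot2(file.exists(path), paste("no such annotation file:", path))
  sp <- sidecarPath(path)
  stopifnot2(file.exists(sp), paste("missing JSON sidecar:", sp))
  tiers <- parseTextGrid(path)
  for (need in c("phones-produced", "words"))
    stopifnot2(need %in% names(tiers),
               paste0("TextGrid is missing tier '", need, "'"))
  side <- jsonlite::read_json(sp)
  stopifnot2(identical(side$schema, SIDE_SCHEMA),
             paste("unsupported sidecar schema:", side$schema %||% "<none>"))
  for (f in c("canonical_phonemes", "severity", "keyword_id", "correctness",
              "truth_intervals"))
    stopifnot2(!is.null(side[[f]]), paste("sidecar is missing field", f))
  prod <- tiers[["phones-produced"]]
  words <- tiers[["words"]]
  for (nm in names(tiers)) {
    tier <- tiers[[nm]]
    if (NROW(tier) > 1) {
      stopifnot2(!is.unsorted(tier$start),
                 paste0("tier '", nm, "' is not time-sorted"))
      stopifnot2(all(tier$start[-1] >= tier$end[-NROW(tier)] - 1e-9),
                 paste0("tier '", nm, "' has overlapping intervals"))
    }
  }
  truth <- lapply(side$truth_intervals, function(lst) {
    if (!length(lst)) return(emptyIntervals())
    data.frame(start = vapply(lst, function(z) z$start, numeric(1)),
               end = vapply(lst, function(z) z$end, numeric(1)))
  })
  ann <- list(
    producedTier = data.frame(symbol = prod$label, start = prod$start,
                              end = prod$end),
    wordTier = data.frame(word = words$label, start = words$start,
                          end = words$end),
    canonicalPhonemes = vapply(side$canonical_phonemes, as.character,
                               character(1)),
    severity = as.numeric(side$severity),
    keywordId = as.integer(side$keyword_id),
    correctness = as.logical(side$correctness),
    truthIntervals = truth)
  if (is.null(wavPath)) return(ann)
  wav <- readWav(wavPath)
  methods::new("Utterance",
    waveform = wav$samples, sampleRate = as.numeric(wav$sampleRate),
    canonicalPhonemes = ann$canonicalPhonemes,
    producedTier = ann$producedTier, wordTier = ann$wordTier,
    severity = ann$severity, keywordId = ann$keywordId,
    correctness = ann$correctness, truthIntervals = ann$truthIntervals)
}

#' Write a dataset manifest as JSON lines
#' @param manifest a [DatasetManifest-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  header <- list(type = "header", seed = manifest@seed,
                 parameters = manifest@parameters)
  writeLines(as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA)), con)
  e <- manifest@entries
  for (i in seq_len(NROW(e)))
    writeLines(as.character(jsonlite::toJSON(as.list(e[i, ]),
                                             auto_unbox = TRUE, digits = NA)),
               con)
  invisible(path)
}

#' Read a dataset manifest written by [writeManifest()]
#' @param path JSONL manifest path.
#' @return a [DatasetManifest-class].
#' @export
readManifest <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  stopifnot2(identical(header$type, "header"), "manifest header missing")
  rows <- lapply(lines[-1], function(l)
    as.data.frame(jsonlite::fromJSON(l, simplifyVector = TRUE),
                  stringsAsFactors = FALSE))
  methods::new("DatasetManifest",
    entries = do.call(rbind, rows), seed = as.integer(header$seed),
    parameters = header$parameters)
}
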