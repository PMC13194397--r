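#' @import methods
#' @importFrom stats rnorm runif rpois fft mvfft approx sd cor wilcox.test
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot2 <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so callers are unaffected.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-entry substream: keep well inside 32-bit range
deriveSeed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(index) * 7L
}

#' 1-D Gaussian smoothing with edge renormalization
#'
#' Kernel standard deviation is `width / 2` frames, truncated at `width`
#' frames each side; near the edges the kernel is renormalized over the
#' in-range support so constants are preserved exactly.
#' @param x numeric vector.
#' @param width kernel width in frames; `width <= 0` returns `x` unchanged.
#' @return smoothed numeric vector of the same length.
#' @export
gaussianSmooth1d <- function(x, width = 5) {
  n <- length(x)
  if (width <= 0 || n < 2) return(x)
  r <- max(1L, as.integer(ceiling(width)))
  k <- exp(-(( -r:r )^2) / (2 * (width / 2)^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    w <- k[keep]
    out[i] <- sum(x[j[keep]] * w) / sum(w)
  }
  out
}

# linear resampling on frame centers (i - 0.5) / n
linResample <- function(x, nOut) {
  n <- length(x)
  if (nOut == n) return(x)
  if (n == 1L) return(rep(x, nOut))
  src <- (seq_len(n) - 0.5) / n
  dst <- (seq_len(nOut) - 0.5) / nOut
  approx(src, x, xout = dst, rule = 2)$y
}

# nearest-frame-center resampling (values preserved, no interpolation)
nearestResample <- function(x, nOut) {
  n <- length(x)
  if (nOut == n) return(x)
  dst <- (seq_len(nOut) - 0.5) / nOut
  idx <- clamp(ceiling(dst * n), 1L, n)
  x[idx]
}

# recursively sort list names so hashes are stable under key reordering
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Stable digest of an R object
#'
#' Canonical-JSON serialization (names sorted recursively) hashed with MD5;
#' used for provenance stamps on exported artifacts.
#' @param x a list-like object (configs, parameters).
#' @return hex digest string.
#' @export
hashObject <- function(x) {
  json <- jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

# intervals as data.frame(start, end); all helpers below use seconds
emptyIntervals <- function() data.frame(start = numeric(0), end = numeric(0))

asIntervals <- function(x) {
  if (is.null(x) || NROW(x) == 0) return(emptyIntervals())
  data.frame(start = as.numeric(x$start), end = as.numeric(x$end))
}

# union length of a set of (possibly overlapping) intervals
intervalUnionLength <- function(iv) {
  if (NROW(iv) == 0) return(0)
  iv <- iv[order(iv$start), , drop = FALSE]
  tot <- 0; curS <- iv$start[1]; curE <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] > curE) { tot <- tot + (curE - curS); curS <- iv$start[i]; curE <- iv$end[i] }
    else curE <- max(curE, iv$end[i])
  }
  tot + (curE - curS)
}

# intersection length of two interval sets
intervalIntersectLength <- function(a, b) {
  if (NROW(a) == 0 || NROW(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$start[i], b$start[j]); hi <- min(a$end[i], b$end[j])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

#' Interval-set intersection over union
#'
#' Temporal IoU between two sets of `(start, end)` intervals in seconds.
#' Both sets empty yields 1 (perfect agreement on "nothing there").
#' @param a,b data.frames with `start` and `end` columns (seconds).
#' @return IoU in `[0, 1]`.
#' @export
intervalIoU <- function(a, b) {
  a <- asIntervals(a); b <- asIntervals(b)
  inter <- intervalIntersectLength(a, b)
  un <- intervalUnionLength(rbind(a, b))
  if (un == 0) return(1)
  inter / un
}
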