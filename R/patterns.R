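#' Read a pattern set from a pattern file
#'
#' Pattern files hold one \code{'0'}/\code{'1'} mask per line; blank lines and
#' lines starting with \code{'#'} are ignored.  All patterns must share the
#' same weight.
#'
#' @param file path to a pattern file, or a connection.
#' @param anchored whether the returned set enforces end-anchoring; reading
#'   fails if a mask violates it.
#' @return A [PatternSet-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("# two seeds", "101011", "111001"), f)
#' readPatternSet(f)
#' @seealso [writePatternSet()]
#' @export
readPatternSet <- function(file, anchored = TRUE) {
  if (is.character(file) && !file.exists(file))
    stop(sprintf("cannot open pattern file '%s'", file))
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  msk <- trimws(lines[keep])
  bad <- which(!grepl("^[01]+$", msk))
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop(sprintf("line %d is not a '0'/'1' mask: '%s'", lineno, msk[bad[1]]))
  }
  if (!length(msk)) stop("no patterns found in file")
  patternSet(msk, anchored = anchored)
}

#' Write a pattern set to a pattern file
#'
#' Masks are written one per line in the order held in the set, so
#' \code{readPatternSet(writePatternSet(x, f))} round-trips bit-exactly.
#'
#' @param x a [PatternSet-class].
#' @param file output path or connection.
#' @param header optional comment lines (written with a \code{'# '} prefix).
#' @return \code{file}, invisibly.
#' @export
writePatternSet <- function(x, file, header = NULL) {
  stopifnot(is(x, "PatternSet"))
  validObject(x)
  out <- character(0)
  if (length(header)) out <- paste0("# ", header)
  writeLines(c(out, masks(x)), file)
  invisible(file)
}

#' Evenly scheduled pattern lengths between a minimum and a maximum
#'
#' For sensitivity-oriented seed design, sets with varied lengths outperform
#' fixed-length sets; lengths are spread as the arithmetic progression from
#' \code{minLength} to \code{maxLength}, rounded to the nearest integer.  A
#' single pattern takes \code{maxLength} (for fixed weight, the longer seed
#' dominates).
#'
#' @param m number of patterns.
#' @param minLength,maxLength extreme pattern lengths.
#' @return Integer vector of \code{m} non-decreasing lengths.
#' @examples
#' scheduleLengths(3, 10, 20)  # 10 15 20
#' @export
scheduleLengths <- function(m, minLength, maxLength) {
  stopifnot(m >= 1, minLength >= 1)
  if (minLength > maxLength)
    stop("minLength must not exceed maxLength")
  if (m == 1L) return(as.integer(maxLength))
  r <- seq_len(m) - 1L
  as.integer(floor(minLength + r * (maxLength - minLength) / (m - 1) + 0.5))
}

#' Generate a random pattern set
#'
#' Each pattern receives exactly \code{weight} match positions placed
#' uniformly at random among its eligible positions (the interior positions
#' when end-anchored).  Masks duplicated within the set are re-drawn.  The
#' result is a deterministic function of R's RNG state, so use
#' \code{set.seed()} for reproducibility.
#'
#' @param m number of patterns.
#' @param lengths integer vector of per-pattern lengths (recycled to length
#'   \code{m}; see [scheduleLengths()] for length ranges).
#' @param weight shared number of match positions.
#' @param anchored enforce \code{'1'} at both ends (requires
#'   \code{weight >= 2} unless a pattern has length 1).
#' @return A [PatternSet-class].
#' @examples
#' set.seed(1)
#' randomPatternSet(3, lengths = 31, weight = 22)
#' @export
randomPatternSet <- function(m, lengths, weight, anchored = TRUE) {
  stopifnot(m >= 1, weight >= 1)
  lengths <- as.integer(rep_len(lengths, m))
  if (any(weight > lengths))
    stop(sprintf("weight %d exceeds a pattern length (min length %d)",
                 weight, min(lengths)))
  if (anchored && any(lengths >= 2L & weight < 2L))
    stop("end-anchoring requires weight >= 2 for patterns of length >= 2")

  # distinct-mask capacity per length: patterns of different lengths cannot
  # collide, so feasibility is checked within each length group
  capacity <- function(len) {
    if (len == 1L) return(1)
    if (anchored) choose(len - 2L, weight - 2L) else choose(len, weight)
  }
  for (len in unique(lengths)) {
    need <- sum(lengths == len)
    cap <- capacity(len)
    if (need > cap)
      stop(sprintf(paste0("cannot draw %d distinct masks of length %d and ",
                          "weight %d: only %g exist"), need, len, weight, cap))
  }

  drawMask <- function(len) {
    if (len == 1L) return("1")
    bits <- rep("0", len)
    if (anchored) {
      bits[c(1L, len)] <- "1"
      if (weight > 2L && len > 2L)
        bits[1L + sample.int(len - 2L, weight - 2L)] <- "1"
    } else {
      bits[sample.int(len, weight)] <- "1"
    }
    paste(bits, collapse = "")
  }

  out <- character(m)
  for (r in seq_len(m)) {
    for (attempt in seq_len(100000L)) {
      cand <- drawMask(lengths[r])
      if (!cand %in% out[seq_len(r - 1L)]) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("failed to draw a distinct mask; the mask space is too small")
    out[r] <- cand
  }
  patternSet(out, anchored = anchored)
}

#' Swap a match position with a don't-care position in one pattern
#'
#' The elementary move of the hill climbers: position \code{i} (a match
#' position) becomes a don't-care and position \code{j} (a don't-care)
#' becomes a match position, preserving the weight.
#'
#' @param x a [PatternSet-class].
#' @param r pattern index (1-based).
#' @param i,j 1-based positions in pattern \code{r}; \code{i} must hold
#'   \code{'1'} and \code{j} must hold \code{'0'}.  With end-anchoring the
#'   swap may not touch the first or last position.
#' @return The modified [PatternSet-class].
#' @export
swapPositions <- function(x, r, i, j) {
  stopifnot(is(x, "PatternSet"))
  msk <- masks(x)
  if (r < 1 || r > length(msk)) stop("pattern index out of range")
  b <- strsplit(msk[r], "")[[1]]
  len <- length(b)
  if (i < 1 || i > len || j < 1 || j > len) stop("position out of range")
  if (b[i] != "1") stop(sprintf("position %d is not a match position", i))
  if (b[j] != "0") stop(sprintf("position %d is not a don't-care position", j))
  if (isAnchored(x) && (i %in% c(1L, len) || j %in% c(1L, len)))
    stop("swap would violate end-anchoring")
  b[i] <- "0"; b[j] <- "1"
  msk[r] <- paste(b, collapse = "")
  patternSet(msk, anchored = isAnchored(x))
}

.asMaskVector <- function(x) {
  if (is(x, "PatternSet")) {
    validObject(x)
    masks(x)
  } else {
    as.character(x)
  }
}
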