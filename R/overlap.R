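#' Union and shared match-position counts for a shifted pattern pair
#'
#' With pattern \code{b} shifted \code{shift} positions to the right relative
#' to pattern \code{a} (left for negative shifts), \code{unionCount} is the
#' number of columns that are match positions of \code{a} or \code{b} (or
#' both), and \code{sharedCount} the number of columns that are match
#' positions of both.  For patterns of common weight w the identity
#' \code{shared = 2w - union} holds at every shift.
#'
#' @param a,b pattern masks as \code{'0'}/\code{'1'} strings.
#' @param shift integer shift(s) of \code{b} relative to \code{a}.
#' @return Integer vector of counts, one per shift.
#' @examples
#' unionCount("101011", "111001", 2)   # 6
#' sharedCount("101011", "111001", 2)  # 2
#' @export
unionCount <- function(a, b, shift) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  wa <- sum(strsplit(a, "")[[1]] == "1")
  wb <- sum(strsplit(b, "")[[1]] == "1")
  wa + wb - cpp_shared_counts(a, b, as.integer(shift))
}

#' @rdname unionCount
#' @export
sharedCount <- function(a, b, shift) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  cpp_shared_counts(a, b, as.integer(shift))
}

#' Per-shift overlap table for a pattern pair
#'
#' Tabulates the union count n and the shared count sigma over the shift
#' range of the pair: all shifts \code{1 - l_b, ..., l_a - 1} for distinct
#' patterns; for a pattern against itself the restricted range
#' \code{0, ..., l_a - 1} avoids double-counting, while the full symmetric
#' range is what the overlap-complexity definition sums over
#' (\code{selfRange = "full"}).
#'
#' @param a,b pattern masks (strings), or a [PatternSet-class] with indices
#'   \code{r}, \code{rp}.
#' @param r,rp pattern indices into \code{a} when it is a PatternSet.
#' @param selfRange \code{"full"} or \code{"restricted"}; only relevant when
#'   the two patterns are the same set element.
#' @return data.frame with columns \code{shift}, \code{n}, \code{sigma}.
#' @export
pairOverlapTable <- function(a, b = NULL, r = NULL, rp = NULL,
                             selfRange = c("full", "restricted")) {
  selfRange <- match.arg(selfRange)
  self <- FALSE
  if (is(a, "PatternSet")) {
    stopifnot(!is.null(r), !is.null(rp))
    self <- r == rp
    msk <- masks(a)
    a2 <- msk[r]; b2 <- msk[rp]
  } else {
    a2 <- as.character(a); b2 <- as.character(b)
    self <- identical(a2, b2) && selfRange == "restricted"
  }
  la <- nchar(a2); lb <- nchar(b2)
  shifts <- if (self && selfRange == "restricted") 0:(la - 1L)
            else (1L - lb):(la - 1L)
  sig <- cpp_shared_counts(a2, b2, as.integer(shifts))
  wa <- sum(strsplit(a2, "")[[1]] == "1")
  wb <- sum(strsplit(b2, "")[[1]] == "1")
  data.frame(shift = shifts, n = wa + wb - sig, sigma = sig)
}

#' Overlap complexity of a pattern set
#'
#' The overlap complexity (OC) sums \code{2^sigma} over all unordered pattern
#' pairs and all relative shifts, where sigma is the number of shared match
#' columns at that shift.  Low OC correlates with high seed sensitivity, and
#' OC is cheap to evaluate, which makes it the standard optimization
#' surrogate.  The value is an exact integer (held in a double; exact as long
#' as it stays below 2^53, which covers all practical weights).
#'
#' As printed, the defining sum runs over the full symmetric shift range even
#' for a pattern paired with itself; the match-count variance instead
#' restricts self-pairs to nonnegative shifts.  Both conventions are
#' available via \code{selfRange}; the default follows the OC definition.
#'
#' @param x a [PatternSet-class] or a character vector of masks.
#' @param selfRange shift range used for self-pairs: \code{"full"}
#'   (symmetric, the OC definition) or \code{"restricted"} (nonnegative
#'   shifts only, the variance convention).
#' @return A single numeric (exact integer) value.
#' @examples
#' overlapComplexity(patternSet(c("101011", "111001")))
#' @seealso [matchVariance()], [patternContributions()]
#' @export
setGeneric("overlapComplexity",
           function(x, selfRange = c("full", "restricted"))
             standardGeneric("overlapComplexity"))

#' @rdname overlapComplexity
#' @export
setMethod("overlapComplexity", "PatternSet", function(x, selfRange) {
  selfRange <- match.arg(selfRange, c("full", "restricted"))
  validObject(x)
  cpp_oc(masks(x), selfRange == "full")$value
})

#' @rdname overlapComplexity
#' @export
setMethod("overlapComplexity", "character", function(x, selfRange) {
  selfRange <- match.arg(selfRange, c("full", "restricted"))
  cpp_oc(x, selfRange == "full")$value
})

#' Approximate variance of the spaced-word match count
#'
#' For a pattern set and the indel-free model in which homologous positions
#' of two length-\code{L} sequences match with probability \code{p} and all
#' other position pairs with probability \code{q}, the variance of the number
#' N of spaced-word matches is approximated in closed form by a sum over all
#' pattern pairs and shifts of \code{p^n - p^(2w)} (homologous part, weight
#' \code{L - l + 1}) and \code{q^n - q^(2w)} (background part, weight
#' \code{(L - l + 1)(L - l)}), where n is the union count at that shift.
#' Self-pairs are summed over the restricted shift range
#' \code{0, ..., l_r - 1}.
#'
#' The expected value of N depends only on the number of patterns, their
#' lengths and their weight; the variance is what distinguishes pattern
#' arrangements, and minimizing it stabilizes alignment-free distance
#' estimates.
#'
#' Two conventions are provided.  \code{matchVariance} counts each unordered
#' pair of match indicators once — the standard form of the estimator and
#' the optimization objective.  The covariance expansion of a variance,
#' however, runs over ordered indicator pairs; \code{orderedMatchVariance}
#' returns that completion, \code{2 V - D} with \code{D} the zero-shift
#' self terms, which is what sample variances of simulated data converge to
#' (see [empiricalMoments()]).  The two differ by an affine map whose offset
#' depends only on the set's shape (m, lengths, w), so they have identical
#' minimizers and either can drive the optimizer.
#'
#' @param x a [PatternSet-class] or character vector of masks.
#' @param model a [HomologyModel-class] supplying \code{p}, \code{q},
#'   \code{L}.
#' @return \code{matchVariance}: a single numeric value.
#'   \code{varianceComponents}: list with \code{homologous},
#'   \code{background} and \code{total}.  \code{varianceSurrogate}: the
#'   shape-constant-free surrogate whose minimizer coincides with the
#'   variance minimizer for fixed m, lengths and weight.
#' @examples
#' s <- patternSet(c("101011", "111001"))
#' matchVariance(s, homologyModel(p = 0.75, L = 1000))
#' @export
setGeneric("matchVariance",
           function(x, model) standardGeneric("matchVariance"))

#' @rdname matchVariance
#' @export
setMethod("matchVariance", "PatternSet", function(x, model) {
  validObject(x)
  .varCheck(x, model)
  cpp_var(masks(x), model@p, model@q, model@L)$value
})

#' @rdname matchVariance
#' @export
setMethod("matchVariance", "character", function(x, model) {
  .varCheck(patternSet(x, anchored = FALSE), model)
  cpp_var(x, model@p, model@q, model@L)$value
})

.varCheck <- function(x, model) {
  stopifnot(is(model, "HomologyModel"))
  if (model@L < maxLength(x))
    stop(sprintf("sequence length L = %g is below the maximum pattern length %d",
                 model@L, maxLength(x)))
  invisible(TRUE)
}

#' @rdname matchVariance
#' @export
orderedMatchVariance <- function(x, model) {
  msk <- .asMaskVector(x)
  ps <- patternSet(msk, anchored = FALSE)
  .varCheck(ps, model)
  V <- cpp_var(msk, model@p, model@q, model@L)$value
  w <- patternWeight(ps); l <- maxLength(ps); m <- length(msk)
  p <- model@p; q <- model@q; L <- model@L
  diag <- (L - l + 1) * m * (p^w - p^(2 * w)) +
    (L - l + 1) * (L - l) * m * (q^w - q^(2 * w))
  2 * V - diag
}

#' @rdname matchVariance
#' @export
varianceComponents <- function(x, model) {
  msk <- .asMaskVector(x)
  .varCheck(patternSet(msk, anchored = FALSE), model)
  v <- cpp_var(msk, model@p, model@q, model@L)
  list(homologous = v$homologous, background = v$background, total = v$value)
}

#' @rdname matchVariance
#' @export
varianceSurrogate <- function(x, model) {
  msk <- .asMaskVector(x)
  .varCheck(patternSet(msk, anchored = FALSE), model)
  cpp_var(msk, model@p, model@q, model@L)$surrogate
}

#' Per-pattern contributions to an objective
#'
#' The contribution C_r of pattern r is the sum over all r' of the additive
#' pair term alpha_\{r,r'\} of the objective (off-diagonal terms therefore
#' appear in both C_r and C_r'; the self term once).  Contributions come out
#' as a by-product of every objective evaluation and drive the
#' contribution-sorted hill climber: patterns with large C_r are mutated
#' first.
#'
#' @param x a [PatternSet-class] or character vector of masks.
#' @param objective \code{"oc"} or \code{"variance"}.
#' @param model a [HomologyModel-class]; required for the variance objective.
#' @param selfRange self-pair shift convention for OC (see
#'   [overlapComplexity()]).
#' @return Numeric vector of contributions, one per pattern.  The sum over r
#'   of C_r equals twice the objective minus the sum of the self terms.
#' @export
patternContributions <- function(x, objective = c("oc", "variance"),
                                 model = NULL,
                                 selfRange = c("full", "restricted")) {
  objective <- match.arg(objective)
  selfRange <- match.arg(selfRange)
  msk <- .asMaskVector(x)
  if (objective == "oc") {
    cpp_oc(msk, selfRange == "full")$contributions
  } else {
    if (is.null(model)) stop("the variance objective requires a HomologyModel")
    .varCheck(patternSet(msk, anchored = FALSE), model)
    cpp_var(msk, model@p, model@q, model@L)$contributions
  }
}
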