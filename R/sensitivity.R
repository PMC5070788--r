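#' Sensitivity of a pattern set in a Bernoulli homology model
#'
#' The sensitivity is the probability that a gap-free homology region of
#' length \code{H}, in which each position matches independently with
#' probability \code{p}, contains at least one seed hit: an offset o with
#' \code{o + l_r <= H} at which every match position of some pattern in the
#' set falls on a matching column.  This is the standard figure of merit for
#' seed sets in hit-and-extend database searching.
#'
#' The computation is an exact dynamic program over the last
#' \code{max(l_r) - 1} homology bits (a deterministic automaton on suffix
#' states), so the cost is \code{O(H * 2^(max(l_r) - 1))}; pattern lengths up
#' to 26 are supported.  Patterns longer than \code{H} are legal but cannot
#' produce hits.
#'
#' @param x a [PatternSet-class] or character vector of masks.
#' @param H homology-region length (positive integer).
#' @param p per-position match probability in \code{[0, 1]}.
#' @return The hit probability, a single numeric in \code{[0, 1]}.
#' @examples
#' sensitivity(patternSet("101", anchored = TRUE), H = 4, p = 0.5)  # 7/16
#' @seealso [sensitivityBruteForce()] for the enumeration oracle.
#' @export
setGeneric("sensitivity", function(x, H, p) standardGeneric("sensitivity"))

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "PatternSet", function(x, H, p) {
  validObject(x)
  .sensCheck(H, p)
  cpp_sensitivity(masks(x), as.integer(H), p)
})

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "character", function(x, H, p) {
  .sensCheck(H, p)
  cpp_sensitivity(x, as.integer(H), p)
})

.sensCheck <- function(H, p) {
  stopifnot(length(H) == 1L, H >= 1, length(p) == 1L, p >= 0, p <= 1)
  invisible(TRUE)
}

#' Brute-force sensitivity by enumeration of all homology strings
#'
#' Sums the probability \code{p^k (1-p)^(H-k)} of every binary string of
#' length \code{H} that contains a hit.  Exponential in \code{H} (guarded at
#' \code{H <= 22}); exists purely as an independent oracle for
#' [sensitivity()].
#'
#' @inheritParams sensitivity
#' @return The hit probability.
#' @export
sensitivityBruteForce <- function(x, H, p) {
  .sensCheck(H, p)
  if (H > 22) stop("brute-force sensitivity is limited to H <= 22")
  cpp_sensitivity_brute(.asMaskVector(x), as.integer(H), p)
}
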