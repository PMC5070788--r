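#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib seedforge, .registration = TRUE
NULL

#' PatternSet: a set of spaced-seed patterns
#'
#' A spaced seed is a binary mask over \{match = \code{'1'}, don't-care =
#' \code{'0'}\} positions.  A \code{PatternSet} holds an ordered collection of
#' such masks that share a common weight (number of match positions), the
#' standard setting for multiple-seed filtering in homology search and for
#' spaced-word counting in alignment-free comparison.
#'
#' With end-anchoring active (the default, and the convention used for most
#' published seed sets) the first and last position of every mask must be a
#' match position.  Duplicate masks are not allowed: a repeated mask adds no
#' sensitivity and trivially inflates both the overlap complexity and the
#' match-count variance.
#'
#' @slot masks character vector of \code{'0'}/\code{'1'} masks.
#' @slot weight integer, the shared number of match positions.
#' @slot anchored logical, whether end-anchoring is enforced.
#'
#' @seealso [patternSet()], [randomPatternSet()], [readPatternSet()]
#' @export
setClass("PatternSet",
         representation(masks = "character",
                        weight = "integer",
                        anchored = "logical"))

setValidity("PatternSet", function(object) {
  msk <- object@masks
  if (length(msk) < 1L)
    return("a PatternSet must contain at least one pattern")
  if (anyNA(msk) || !all(grepl("^[01]+$", msk)))
    return("masks must be nonempty strings over '0'/'1'")
  if (any(nchar(msk) > 64L))
    return("pattern length is limited to 64")
  wts <- vapply(strsplit(msk, ""), function(b) sum(b == "1"), integer(1))
  if (length(unique(wts)) != 1L)
    return(sprintf("all patterns must share the same weight; found weights {%s}",
                   paste(sort(unique(wts)), collapse = ", ")))
  if (wts[1] < 1L)
    return("pattern weight must be at least 1")
  if (!identical(wts[1], object@weight))
    return("weight slot disagrees with the masks")
  if (anyDuplicated(msk))
    return(sprintf("duplicate mask '%s': patterns in a set must be distinct",
                   msk[duplicated(msk)][1]))
  if (isTRUE(object@anchored)) {
    ends <- substr(msk, 1L, 1L) == "1" &
      substr(msk, nchar(msk), nchar(msk)) == "1"
    if (!all(ends))
      return(sprintf("end-anchoring requires '1' at both ends; violated by '%s'",
                     msk[!ends][1]))
  }
  TRUE
})

#' Construct a PatternSet
#'
#' @param masks character vector of \code{'0'}/\code{'1'} masks, all with the
#'   same number of \code{'1'}s.
#' @param anchored enforce a match position at both ends of every mask
#'   (default \code{TRUE}).
#' @return A [PatternSet-class] object.
#' @examples
#' patternSet(c("101011", "111001"))
#' @export
patternSet <- function(masks, anchored = TRUE) {
  masks <- as.character(masks)
  w <- if (length(masks) && !anyNA(masks))
    sum(strsplit(masks[1], "")[[1]] == "1") else NA_integer_
  new("PatternSet", masks = masks, weight = as.integer(w),
      anchored = isTRUE(anchored))
}

#' HomologyModel: the indel-free substitution model behind variance and
#' sensitivity calculations
#'
#' Two equal-length sequences are related position-wise: aligned (homologous)
#' positions match with probability \code{p}, all other position pairs match
#' with the background probability \code{q} (1/4 for uniform nucleotides).
#' \code{L} is the sequence length entering the match-count variance;
#' \code{H} is the length of the gap-free homology region entering the
#' sensitivity computation.
#'
#' @slot p numeric, match probability at homologous positions.
#' @slot q numeric, background match probability.
#' @slot L numeric, sequence length for the variance model.
#' @slot H numeric, homology-region length for the sensitivity model (may be
#'   \code{NA} when only variance is of interest).
#'
#' @seealso [homologyModel()], [matchVariance()], [sensitivity()]
#' @export
setClass("HomologyModel",
         representation(p = "numeric", q = "numeric",
                        L = "numeric", H = "numeric"))

setValidity("HomologyModel", function(object) {
  p <- object@p; q <- object@q; L <- object@L; H <- object@H
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    return("p must be a probability in [0, 1]")
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    return("q must be a probability in [0, 1]")
  if (length(L) != 1L || is.na(L) || L < 1)
    return("L must be a positive length")
  if (length(H) != 1L || (!is.na(H) && H < 1))
    return("H must be a positive length or NA")
  TRUE
})

#' Construct a HomologyModel
#'
#' @param p match probability at homologous (aligned) positions.
#' @param q background match probability; defaults to 1/4, the value implied
#'   by a uniform nucleotide distribution.
#' @param L sequence length used by the match-count variance.
#' @param H homology-region length used by the sensitivity model.
#' @return A [HomologyModel-class] object.  A warning (not an error) is given
#'   when \code{q > p}, which is outside the intended evolutionary regime but
#'   still well-defined.
#' @examples
#' homologyModel(p = 0.75, L = 10000)
#' @export
homologyModel <- function(p, q = 0.25, L = 10000, H = NA_real_) {
  obj <- new("HomologyModel", p = as.numeric(p), q = as.numeric(q),
             L = as.numeric(L), H = as.numeric(H))
  if (obj@q > obj@p)
    warning("background match probability q exceeds homologous p; ",
            "the model is outside the intended regime")
  obj
}

#' OptimizationResult: outcome of a hill-climbing run
#'
#' @slot set the best [PatternSet-class] found.
#' @slot objective character, one of \code{"oc"}, \code{"variance"},
#'   \code{"sensitivity"}.
#' @slot value numeric, the final objective value (a probability for
#'   sensitivity, minimized quantity otherwise).
#' @slot oc numeric, overlap complexity of the returned set.
#' @slot variance numeric, match-count variance of the returned set
#'   (\code{NA} when no model was supplied).
#' @slot sensitivity numeric, sensitivity of the returned set (\code{NA}
#'   unless computed).
#' @slot trace data.frame with columns \code{step}, \code{value},
#'   \code{normalized}: the objective after every accepted swap, with
#'   \code{step} counting probes (swap evaluations); \code{normalized} is
#'   relative to the starting value.
#' @slot evaluations numeric, total number of probes spent.
#' @slot seed integer, the seed recorded for reproducibility (\code{NA} when
#'   none was supplied).
#' @export
setClass("OptimizationResult",
         representation(set = "PatternSet", objective = "character",
                        value = "numeric", oc = "numeric",
                        variance = "numeric", sensitivity = "numeric",
                        trace = "data.frame", evaluations = "numeric",
                        seed = "integer"))
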