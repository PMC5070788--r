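#' Accessors for PatternSet and OptimizationResult objects
#'
#' \code{masks} returns the character masks; \code{patternWeight} the shared
#' weight w; \code{patternLengths} the per-pattern lengths; \code{maxLength}
#' the maximum length; \code{isAnchored} whether end-anchoring is enforced.
#' \code{bestSet}, \code{objectiveValue} and \code{climbTrace} access the
#' corresponding parts of an optimization result.
#'
#' @param x a [PatternSet-class] or [OptimizationResult-class] object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @rdname accessors
#' @export
setGeneric("patternLengths", function(x) standardGeneric("patternLengths"))

#' @rdname accessors
#' @export
setGeneric("maxLength", function(x) standardGeneric("maxLength"))

#' @rdname accessors
#' @export
setGeneric("isAnchored", function(x) standardGeneric("isAnchored"))

#' @rdname accessors
#' @export
setGeneric("bestSet", function(x) standardGeneric("bestSet"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("climbTrace", function(x) standardGeneric("climbTrace"))

#' @rdname accessors
#' @export
setMethod("masks", "PatternSet", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("patternWeight", "PatternSet", function(x) x@weight)

#' @rdname accessors
#' @export
setMethod("patternLengths", "PatternSet", function(x) nchar(x@masks))

#' @rdname accessors
#' @export
setMethod("maxLength", "PatternSet", function(x) max(nchar(x@masks)))

#' @rdname accessors
#' @export
setMethod("isAnchored", "PatternSet", function(x) x@anchored)

#' @rdname accessors
#' @export
setMethod("length", "PatternSet", function(x) length(x@masks))

#' @rdname accessors
#' @export
setMethod("as.character", "PatternSet", function(x) x@masks)

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d pattern%s, weight %d, max length %d%s\n",
              length(object@masks), if (length(object@masks) == 1) "" else "s",
              object@weight, max(nchar(object@masks)),
              if (object@anchored) ", end-anchored" else ""))
  show_n <- min(length(object@masks), 12L)
  cat(paste0("  ", object@masks[seq_len(show_n)]), sep = "\n")
  if (length(object@masks) > show_n)
    cat(sprintf("  ... and %d more\n", length(object@masks) - show_n))
})

setMethod("show", "HomologyModel", function(object) {
  cat(sprintf("HomologyModel: p = %g, q = %g, L = %g, H = %s\n",
              object@p, object@q, object@L,
              if (is.na(object@H)) "NA" else format(object@H)))
})

#' @rdname accessors
#' @export
setMethod("bestSet", "OptimizationResult", function(x) x@set)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "OptimizationResult", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("climbTrace", "OptimizationResult", function(x) x@trace)

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (objective: %s)\n", object@objective))
  cat(sprintf("  value: %s  [OC = %s%s%s]\n",
              format(object@value),
              format(object@oc),
              if (is.na(object@variance)) ""
              else sprintf(", Var(N) = %s", format(object@variance)),
              if (is.na(object@sensitivity)) ""
              else sprintf(", sensitivity = %.6f", object@sensitivity)))
  cat(sprintf("  probes: %g, accepted swaps recorded: %d\n",
              object@evaluations, max(0L, nrow(object@trace) - 1L)))
  show(object@set)
})
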