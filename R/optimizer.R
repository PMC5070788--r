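.objCode <- function(objective) switch(objective, oc = 0L, variance = 1L)

.climbResult <- function(res, objective, anchored, model, seed,
                         withSensitivity = FALSE, H = NULL, p = NULL) {
  set <- patternSet(res$masks, anchored = anchored)
  oc <- cpp_oc(masks(set), TRUE)$value
  vr <- if (!is.null(model))
    cpp_var(masks(set), model@p, model@q, model@L)$value else NA_real_
  sens <- if (withSensitivity) cpp_sensitivity(masks(set), as.integer(H), p)
          else NA_real_
  tr <- data.frame(step = res$traceStep, value = res$traceValue,
                   normalized = res$traceValue / res$traceValue[1])
  value <- switch(objective, oc = oc, variance = vr, sensitivity = sens)
  new("OptimizationResult", set = set, objective = objective,
      value = value, oc = oc, variance = vr, sensitivity = sens,
      trace = tr, evaluations = res$probes,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Contribution-sorted hill climbing on a pattern set
#'
#' Minimizes the overlap complexity or the match-count variance by repeated
#' single-position swaps.  Patterns are processed in descending order of
#' their contribution C_r to the objective.  For the current pattern one
#' random (match, don't-care) position pair is drawn and the swapped set is
#' evaluated: a strict improvement is accepted, the contributions are
#' updated, the patterns re-sorted, and processing restarts at the top;
#' otherwise the next pattern in the list is probed, wrapping around with
#' fresh random draws.  Each probe costs \code{O(m * l^2)} since only the
#' pairs involving the touched pattern are recomputed.
#'
#' Because convergence traces flatten out while probing continues, the
#' budget counts swap \emph{evaluations} (probes) by default; counting
#' accepted swaps instead is available via \code{budgetUnit = "swaps"}
#' together with a stagnation cutoff so a local minimum cannot spin forever.
#'
#' @param x the starting [PatternSet-class].
#' @param objective \code{"oc"} or \code{"variance"}.
#' @param model a [HomologyModel-class]; required for \code{"variance"}.
#' @param swaps iteration budget (default 25000).
#' @param budgetUnit \code{"probes"} (default) or \code{"swaps"}.
#' @param stall stop after this many consecutive rejected probes (0 =
#'   disabled; forced on for \code{budgetUnit = "swaps"}).
#' @param selfRange self-pair shift convention for the OC objective (see
#'   [overlapComplexity()]).
#' @return An [OptimizationResult-class].  Uses R's RNG: seed with
#'   \code{set.seed()} for reproducibility.
#' @examples
#' set.seed(7)
#' s0 <- randomPatternSet(5, lengths = 12, weight = 6)
#' hillClimb(s0, swaps = 2000)
#' @export
hillClimb <- function(x, objective = c("oc", "variance"), model = NULL,
                      swaps = 25000, budgetUnit = c("probes", "swaps"),
                      stall = 0, selfRange = c("full", "restricted")) {
  objective <- match.arg(objective)
  budgetUnit <- match.arg(budgetUnit)
  selfRange <- match.arg(selfRange)
  stopifnot(is(x, "PatternSet"), swaps >= 0)
  validObject(x)
  if (objective == "variance") {
    if (is.null(model)) stop("the variance objective requires a HomologyModel")
    .varCheck(x, model)
  }
  if (budgetUnit == "swaps" && stall <= 0)
    stall <- 10000 * length(x)
  m <- if (!is.null(model)) model else homologyModel(0.5, 0.25, maxLength(x))
  res <- cpp_hill_climb(masks(x), isAnchored(x), .objCode(objective),
                        selfRange == "full", m@p, m@q, m@L,
                        swaps, if (budgetUnit == "probes") 0L else 1L, stall)
  .climbResult(res, objective, isAnchored(x), model, NULL)
}

#' Reference hill climbing over all swap triplets
#'
#' The classical (slow) variant: every triplet (r, i, j) of a pattern, a
#' match position and a don't-care position is evaluated, the best strictly
#' improving swap is applied, and this repeats until no single swap improves
#' the objective, i.e. until a local minimum.  One step costs
#' \code{O(m^2 * l^4)}; the function exists as a reference and for tests.
#'
#' @inheritParams hillClimb
#' @param maxRounds safety cap on the number of accepted swaps.
#' @return An [OptimizationResult-class] whose set is a local minimum: no
#'   single swap improves it.
#' @export
hillClimbTriplets <- function(x, objective = c("oc", "variance"),
                              model = NULL, maxRounds = 1e6,
                              selfRange = c("full", "restricted")) {
  objective <- match.arg(objective)
  selfRange <- match.arg(selfRange)
  stopifnot(is(x, "PatternSet"))
  validObject(x)
  if (objective == "variance") {
    if (is.null(model)) stop("the variance objective requires a HomologyModel")
    .varCheck(x, model)
  }
  m <- if (!is.null(model)) model else homologyModel(0.5, 0.25, maxLength(x))
  res <- cpp_hill_climb_triplets(masks(x), isAnchored(x), .objCode(objective),
                                 selfRange == "full", m@p, m@q, m@L, maxRounds)
  res$traceStep <- 0; res$traceValue <- res$value; res$probes <- NA_real_
  .climbResult(res, objective, isAnchored(x), model, NULL)
}

#' Optimize a pattern set from random restarts
#'
#' The full design driver.  For the \code{"oc"} and \code{"variance"}
#' objectives, \code{inner * outer} independent hill climbs are started from
#' fresh random pattern sets and the overall best set is returned.  For the
#' \code{"sensitivity"} objective the expensive sensitivity computation is
#' never probed inside a climb; instead, per outer repetition, \code{inner}
#' climbs minimize the overlap complexity (the cheap surrogate), the
#' sensitivity is evaluated only for the lowest-OC set of the batch, and the
#' set with the overall highest sensitivity across the outer repetitions is
#' returned.  Published defaults are 25000 swap probes per climb, 100 inner
#' climbs and 5000 outer repetitions; reduced budgets are routine.
#'
#' Restart RNG streams are derived from \code{seed} via a fixed substream
#' table, so results do not depend on execution order of the restarts.
#'
#' @param m number of patterns.
#' @param weight shared pattern weight.
#' @param length fixed pattern length (all patterns equal); alternatively
#'   give \code{minLength}/\code{maxLength} for evenly scheduled lengths.
#' @param minLength,maxLength extreme lengths for [scheduleLengths()].
#' @param objective \code{"oc"}, \code{"variance"} or \code{"sensitivity"}.
#' @param model a [HomologyModel-class] (required for \code{"variance"};
#'   supplies \code{p}, \code{q}, \code{L}).
#' @param H,p homology length and match probability (required for
#'   \code{"sensitivity"}).
#' @param swaps probe budget per hill climb.
#' @param stall per-climb stagnation cutoff in consecutive rejected probes
#'   (0 = none); converged climbs stop early so more restarts fit a budget.
#' @param inner hill climbs per sensitivity evaluation (or per outer
#'   repetition).
#' @param outer outer repetitions.
#' @param anchored enforce end-anchoring.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param verbose print per-repetition progress.
#' @return An [OptimizationResult-class] for the best set found.
#' @examples
#' res <- optimizeSeeds(4, weight = 6, length = 12, objective = "oc",
#'                      swaps = 2000, inner = 2, outer = 2, seed = 11)
#' bestSet(res)
#' @export
optimizeSeeds <- function(m, weight, length = NULL,
                          minLength = NULL, maxLength = NULL,
                          objective = c("oc", "variance", "sensitivity"),
                          model = NULL, H = NULL, p = NULL,
                          swaps = 25000, inner = 100, outer = 5000,
                          stall = 0, anchored = TRUE, seed = NULL,
                          verbose = FALSE) {
  objective <- match.arg(objective)
  stopifnot(m >= 1, swaps >= 0, inner >= 1, outer >= 1)
  if (!is.null(length)) {
    lengths <- rep(as.integer(length), m)
  } else {
    if (is.null(minLength) || is.null(maxLength))
      stop("give either `length` or both `minLength` and `maxLength`")
    lengths <- scheduleLengths(m, minLength, maxLength)
  }
  if (objective == "variance" && is.null(model))
    stop("the variance objective requires a HomologyModel")
  if (objective == "sensitivity" && (is.null(H) || is.null(p)))
    stop("the sensitivity objective requires H and p")

  # fixed substream table: restart k always sees the same RNG stream
  nRestart <- if (objective == "sensitivity") inner * outer else inner * outer
  if (!is.null(seed)) set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, nRestart)

  climbOne <- function(k, obj, mdl) {
    set.seed(subseeds[k])
    s0 <- randomPatternSet(m, lengths, weight, anchored = anchored)
    hillClimb(s0, objective = obj, model = mdl, swaps = swaps, stall = stall)
  }

  if (objective != "sensitivity") {
    best <- NULL
    for (k in seq_len(nRestart)) {
      res <- climbOne(k, objective, model)
      if (is.null(best) || res@value < best@value) best <- res
      if (verbose && (k %% 25 == 0 || k == nRestart))
        message(sprintf("restart %d/%d: best %s = %g",
                        k, nRestart, objective, best@value))
    }
    best@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    return(best)
  }

  # sensitivity: OC is the inner surrogate; evaluate sensitivity once per
  # outer repetition, for the lowest-OC set of the batch
  best <- NULL
  for (o in seq_len(outer)) {
    batchBest <- NULL
    for (i in seq_len(inner)) {
      k <- (o - 1L) * inner + i
      res <- climbOne(k, "oc", NULL)
      if (is.null(batchBest) || res@oc < batchBest@oc) batchBest <- res
    }
    sens <- cpp_sensitivity(masks(batchBest@set), as.integer(H), p)
    if (is.null(best) || sens > best@sensitivity) {
      best <- batchBest
      best@sensitivity <- sens
      best@value <- sens
      best@objective <- "sensitivity"
    }
    if (verbose)
      message(sprintf("outer %d/%d: batch OC = %g, sensitivity = %.6f, best = %.6f",
                      o, outer, batchBest@oc, sens, best@sensitivity))
  }
  best@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  best
}
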