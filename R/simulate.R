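#' Spaced-word match test at a window pair
#'
#' Sequences \code{s1} and \code{s2} have a spaced-word match with respect to
#' a pattern at window starts (i, j) — 1-based — if the characters agree at
#' every match position of the pattern; don't-care columns are
#' unconstrained.
#'
#' @param s1,s2 sequences (character strings or anything coercible via
#'   \code{as.character}, e.g. a \code{DNAString}).
#' @param i,j 1-based window start positions in \code{s1} and \code{s2}.
#' @param pattern a \code{'0'}/\code{'1'} mask.
#' @return \code{TRUE} or \code{FALSE}.  Errors if a window does not fit.
#' @examples
#' spacedWordMatch("AATCGATCA", "CGTATTGATT", 2, 4, "110101")  # TRUE
#' @export
spacedWordMatch <- function(s1, s2, i, j, pattern) {
  cpp_spaced_word_match(as.character(s1)[1], as.character(s2)[1],
                        as.integer(i), as.integer(j), as.character(pattern)[1])
}

#' Count all spaced-word matches between two sequences
#'
#' N is the total number of (pattern, i, j) triples for which the two windows
#' match at every match position of that pattern; up to m matches can occur
#' at a single window pair (one per pattern).  Counting is done per pattern
#' by sorting the packed spaced words of both sequences and multiplying run
#' lengths, which agrees exactly with the quadratic all-window reference
#' (checked in the test suite).
#'
#' @param s1,s2 DNA sequences over ACGT (character or \code{DNAString}).
#' @param x a [PatternSet-class] or character vector of masks.
#' @return The match count N (numeric).
#' @export
countMatches <- function(s1, s2, x) {
  msk <- .asMaskVector(x)
  s1 <- as.character(s1)[1]; s2 <- as.character(s2)[1]
  if (nchar(s1) < max(nchar(msk)) || nchar(s2) < max(nchar(msk)))
    stop("sequences must be at least as long as the longest pattern")
  cpp_count_matches(s1, s2, msk)
}

#' Simulate a sequence pair under the indel-free homology model
#'
#' Draws S1 i.i.d. uniform over ACGT and copies each position into S2 with
#' probability \code{p}, otherwise replacing it by one of the other three
#' letters uniformly.  This realizes a homologous match probability of
#' exactly \code{p} at aligned positions and a background match probability
#' of q = 1/4 at all other position pairs (both marginals stay uniform).
#' No insertions or deletions.
#'
#' @param L sequence length.
#' @param p homologous match probability.
#' @return A named \code{DNAStringSet} of length 2 (\code{S1}, \code{S2});
#'   write to FASTA with \code{Biostrings::writeXStringSet()}.  Uses R's RNG.
#' @examples
#' set.seed(1)
#' simulatePair(50, p = 0.9)
#' @export
simulatePair <- function(L, p) {
  stopifnot(L >= 1, p >= 0, p <= 1)
  pair <- cpp_simulate_pair(as.integer(L), p)
  Biostrings::DNAStringSet(c(S1 = pair$S1, S2 = pair$S2))
}

#' Empirical moments of the spaced-word match count
#'
#' Simulates \code{reps} independent sequence pairs with [simulatePair()],
#' counts N for each, and returns the sample mean and variance with standard
#' errors.  The standard error of the sample variance uses the
#' fourth-central-moment formula, so the returned \code{seVariance} is valid
#' without normality assumptions.  This is the Monte-Carlo oracle against
#' which the closed-form [matchVariance()] is validated.
#'
#' @param x a [PatternSet-class] or character vector of masks.
#' @param L sequence length.
#' @param p homologous match probability (background q is 1/4 by
#'   construction).
#' @param reps number of simulated pairs (>= 2).
#' @return List with \code{mean}, \code{variance}, \code{seMean},
#'   \code{seVariance}, \code{reps}, and the raw counts \code{N}.
#' @export
empiricalMoments <- function(x, L, p, reps) {
  msk <- .asMaskVector(x)
  stopifnot(reps >= 2, L >= max(nchar(msk)))
  N <- cpp_empirical_counts(msk, as.integer(L), p, as.integer(reps))
  mu <- mean(N)
  v <- stats::var(N)
  d <- N - mu
  m2 <- mean(d^2)
  m4 <- mean(d^4)
  n <- length(N)
  varOfVar <- (m4 - (n - 3) / (n - 1) * m2^2) / n
  list(mean = mu, variance = v,
       seMean = sqrt(v / n), seVariance = sqrt(max(varOfVar, 0)),
       reps = n, N = N)
}
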