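---
title: "Designing multiple spaced seeds: objectives, model and algorithm"
author: "seedforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiple spaced seeds: objectives, model and algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedforge)
```

## The problem

A *spaced seed* is a binary pattern over match (`1`) and don't-care (`0`)
positions.  Two sequence windows "hit" under a seed when they agree at every
match position; the don't-care columns are free.  Compared with contiguous
k-mers, spaced seeds decorrelate the hits at neighbouring offsets, which
raises the probability of catching a diverged homology (database searching,
read mapping) and stabilizes match-count statistics (alignment-free
phylogeny).  In practice one uses a *set* of m seeds of common weight w
(number of match positions); a hit by any member counts.

The arrangement of the 1s within the masks is what matters.  seedforge
scores arrangements by three related objectives and searches the space of
arrangements by hill climbing:

* **Overlap complexity (OC).**  For two patterns and a relative shift s,
  let sigma be the number of columns where both have a match position.  OC
  sums `2^sigma` over all unordered pattern pairs and all shifts (for a
  pattern against itself the defining sum runs over the full symmetric
  shift range).  Heavily overlapping — e.g. periodic — masks blow this
  number up.  Low OC empirically tracks high sensitivity, and OC is cheap:
  that makes it the standard optimization surrogate.

* **Variance of the spaced-word match count.**  Under an indel-free model
  in which position i of one length-L sequence matches position i of the
  other with probability p, and all other position pairs match with
  background probability q, the expected number N of spaced-word matches
  depends only on (m, lengths, w) — but Var(N) depends on the arrangement.
  With n = 2w − sigma the union count at a shift, the estimator sums
  `p^n − p^(2w)` over pairs and shifts (homologous part, weight L−l+1) and
  `q^n − q^(2w)` (background part, weight (L−l+1)(L−l)); self-pairs use the
  non-negative shift range only.  Minimizing Var(N) stabilizes the distance
  estimates that alignment-free methods derive from N.

* **Sensitivity.**  The probability that a gap-free homology region of
  length H, whose positions match i.i.d. with probability p, contains at
  least one full-window hit by some seed in the set.  This is the figure of
  merit for hit-and-extend search.  It is expensive (the DP below is
  exponential in the seed length), which is exactly why the two surrogates
  above exist.

## Two variance conventions

`matchVariance()` counts each unordered pair of match indicators once; this
is the standard printed form of the estimator, it is the quantity the
optimizer reports, and published optimized-variance values are on this
scale.  The covariance expansion of a variance, however, runs over *ordered*
indicator pairs.  `orderedMatchVariance()` returns that completion,
`2 V − D`, where D collects the zero-shift self terms and depends only on
the set's shape.  Monte-Carlo sample variances converge to the ordered
completion — the test suite checks this at 3 standard errors over 20,000
simulated pairs — while the unordered form sits near half of it.  Because
the two differ by an affine, shape-constant map, they have identical
minimizers, so which one drives the optimizer is immaterial; which one you
compare with simulated data is not.

## The hill climber

The elementary move swaps one match position with one don't-care position
inside one pattern, preserving shape.  Both objectives decompose into
additive per-pair terms `alpha[r, r']`, so each pattern has a *contribution*
`C_r = sum over r' of alpha[r, r']`, obtained as a by-product of any
evaluation.  The climber sorts patterns by descending contribution and, for
the current pattern, draws a single random (match, don't-care) pair,
evaluating only the m pairs that involve the touched pattern — O(m·l^2) per
probe.  A strict improvement is accepted: contributions are updated, the
patterns re-sorted, and probing restarts at the top of the list; otherwise
the next pattern is probed, wrapping around with fresh draws.  The classical
alternative that scans *all* (pattern, i, j) triplets per step is kept as
`hillClimbTriplets()` — a reference implementation used by the tests to
certify local minimality.

Numerical choices worth stating:

* OC terms `2^sigma` and their sums are held in doubles as exact integers;
  this is exact as long as the total stays below 2^53, which holds for any
  weight up to about 40 — far beyond practical seed design.  Acceptance of
  a swap therefore never depends on floating-point rounding for OC.
* Variance terms are accumulated with compensated (Kahan) summation in the
  from-scratch path.  After an accepted swap the objective is re-summed
  from the cached per-pair table in a fixed order, so the incremental path
  is bit-identical to a from-scratch evaluation and a swap followed by its
  reverse restores the objective exactly.
* Ties are rejected (strict improvement only), which prevents cycling
  without a tabu list; equal contributions are ordered by pattern index
  (stable sort) for determinism.
* The iteration budget counts swap *evaluations* (probes), not accepted
  swaps: convergence traces flatten while probing continues, so counting
  acceptances would never terminate at a local optimum.  Counting accepted
  swaps is selectable (`budgetUnit = "swaps"`), in which case a stagnation
  cutoff is forced on.  An optional cutoff (`stall`) also lets converged
  climbs end early so that more random restarts fit a time budget.

`optimizeSeeds()` wraps the climber in random restarts.  For the
sensitivity objective the expensive DP is never probed inside a climb:
per outer repetition, `inner` climbs minimize OC and the sensitivity is
evaluated once, for the lowest-OC set of the batch; the best sensitivity
over the outer repetitions wins.  Published defaults are 25,000 probes per
climb, 100 inner climbs and 5,000 outer repetitions; the functions accept
arbitrary reductions and the package's own validation uses scaled-down
budgets (stated below).  Restart streams are derived from the seed via a
fixed substream table, so results do not depend on the order in which
restarts execute.

## Sensitivity computation

`sensitivity()` runs an exact DP over a deterministic automaton whose state
is the last `max(l_r) − 1` bits of the homology region's match/mismatch
string; a pattern of length l fires when at least l bits have been
generated and the last l bits cover all its match positions (full-window
containment — no partial or wrapped windows).  Cost is
O(H · 2^(max(l)−1)) time, so the implementation guards at pattern length
26; every shape the package's validation exercises stays at or below
length 24.  Probabilities are propagated as plain doubles — with H ≤ 64
there is no underflow risk.  `sensitivityBruteForce()` enumerates all 2^H
strings (guarded at H ≤ 22) and exists purely as an independent oracle;
the suite checks DP-vs-enumeration agreement to 1e-12 on hundreds of
random queries.

## Model parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| p | match probability at homologous positions | — | application-specific (0.70–0.95 typical) |
| q | background match probability | 0.25 | uniform nucleotide composition |
| L | sequence length in the variance model | 10,000 | moderate genomic fragment |
| H | homology-region length for sensitivity | — | taken from the target application (50–64 typical) |
| anchoring | `1` at both mask ends | on | standard convention for published seed sets; switchable off |

The background probability deserves a note: the simulator fixes q = 1/4 by
construction (uniform letters), while the analytic variance takes q as a
free parameter; when reproducing variance-optimization results q = 0.25 is
assumed, since nothing else is determined by a uniform-background model.

End-anchoring is on by default; the convention is standard for published
seed sets, and interior-only swaps preserve it.  Both behaviours are
supported because either convention appears in the wild.

Duplicate masks within a set are rejected at validation and re-drawn at
generation: a duplicate adds no sensitivity and inflates OC and Var(N)
trivially.

When seed lengths may vary, `scheduleLengths()` spreads them as an
arithmetic progression between a chosen minimum and maximum (nearest-integer
rounding; a single pattern takes the maximum, since for fixed weight a
longer seed dominates).  For sensitivity-oriented design the package's
working heuristic for the range is **minLength = w + 4, maxLength =
w + 13** (capped by the DP guard and by H): pilot experiments show that
near-contiguous seeds — lengths within a few positions of w — drag a set's
joint coverage down, while the gain from stretching beyond w + 13 is small
and the DP cost doubles with every added position of maximum length.

## What the simulator does and does not emulate

`simulatePair()` draws S1 i.i.d. uniform over ACGT and copies each position
into S2 with probability p, else replaces it with one of the other three
letters uniformly.  This realizes the indel-free two-parameter match model
exactly (homologous match probability p, background q = 1/4, uniform
marginals), which is the model under which the variance estimator and the
sensitivity DP are derived.  It does **not** contain indels, rate
heterogeneity, compositional bias, or repeats — so the Monte-Carlo
agreement the tests demonstrate validates the formulas *within the model*,
not the model's fidelity to real genomes.  On real data the objectives
remain sensible rankings rather than calibrated predictions.

`countMatches()` counts spaced-word matches per pattern by sorting the
packed spaced words of both sequences and multiplying run lengths; a
quadratic all-window reference implementation is kept in the test suite and
the two are asserted to agree exactly.

## Validation at desk scale

The automated suite validates, among other things: the pairwise-overlap
identities on thousands of random cases; exact equality of the OC power-sum
identity; bit-identity of incremental and from-scratch objective
evaluations across hundreds of random swaps; DP-vs-enumeration sensitivity
agreement; the ordered variance completion against sample variances of
20,000 simulated pairs (m = 3, l = 20, w = 16, L = 1,000, p ∈ {0.75, 0.9});
OC and variance minimization for 10 patterns of length 20 and weight 8
(3,000 and 400 stall-cut restarts respectively); and sensitivity
optimization at a reduced budget of 20 climbs × 5 repetitions for the
4-seed (w = 10, H = 50, p = 0.75) and 16-seed (w = 11, H = 64, p = 0.70)
settings.  These problem sizes are the package's own validation choices;
all budgets scale up through the public arguments.

## Known limitations

* Sensitivity DP memory/time is exponential in the maximum seed length
  (guard: 26).  Long-seed designs (e.g. length-31 classification seeds)
  can be optimized by OC or variance, but their sensitivity cannot be
  evaluated by this DP.
* The exactness of OC arithmetic degrades past weight ≈ 40 (sums approach
  2^53); no practical design comes close.
* One RNG stream drives each climb; restarts use derived substreams.
  Results are reproducible given a seed but, as with any stochastic local
  search, individual climbs are sensitive to the stream.
* Protein alphabets, vector/subset seeds, transition-aware seeds and
  coverage-based criteria are out of scope.
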