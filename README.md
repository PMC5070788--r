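# seedforge

Design of multiple spaced-seed pattern sets by contribution-sorted hill
climbing.

## The problem

Word-based sequence comparison — hit-and-extend database searching, read
mapping and classification, alignment-free phylogeny — works markedly better
when words are filtered through *spaced seeds*: binary masks of match (`1`)
and don't-care (`0`) positions.  Two windows hit under a seed when they agree
at every match position.  Given the number of seeds m, their weight w
(number of match positions) and their lengths, the *arrangement* of the
match positions decides how well a seed set performs, and good arrangements
are the non-periodic ones whose members overlap themselves and each other as
little as possible.

seedforge scores arrangements by three standard, related objectives and
optimizes them by stochastic local search:

* **Overlap complexity** — `OC(P) = Σ_{r≤r'} Σ_s 2^σ_{r,r'}[s]`, where
  `σ_{r,r'}[s]` counts the columns at which both patterns have a match
  position when one is shifted by `s`.  A cheap combinatorial proxy that is
  inversely related to sensitivity.
* **Variance of the spaced-word match count** — under an indel-free model
  with homologous match probability `p` and background probability `q`
  between two length-`L` sequences,
  `Var(N) ≈ (L−ℓ+1) Σ (p^n − p^{2w}) + (L−ℓ+1)(L−ℓ) Σ (q^n − q^{2w})`
  with `n = 2w − σ` the union count per pair and shift.  The mean of N is
  arrangement-independent; the variance is not, and minimizing it
  stabilizes alignment-free distance estimates.
* **Sensitivity** — the probability of at least one hit inside a gap-free
  homology region of length `H` with per-position match probability `p`,
  computed exactly by dynamic programming and maximized through the
  OC surrogate.

The optimizer swaps one match with one don't-care position per move,
processes patterns in descending order of their contribution
`C_r = Σ_{r'} α_{r,r'}` to the objective, and accepts strict improvements
only; random restarts wrap the climb.  A Monte-Carlo simulator of the
homology model and brute-force enumeration oracles validate every formula in
the test suite.

## Worked example

Design 4 seeds of weight 8 for homology regions of length 50 with 75 %
identity, at a small demonstration budget:

```r
library(seedforge)
res <- optimizeSeeds(4, weight = 8, minLength = 12, maxLength = 18,
                     objective = "sensitivity", H = 50, p = 0.75,
                     swaps = 25000, inner = 10, outer = 3, seed = 7)
res
#> OptimizationResult (objective: sensitivity)
#>   value: 0.9869891  [OC = 2608, sensitivity = 0.986989]
#>   probes: 25000, accepted swaps recorded: 21
#> PatternSet: 4 patterns, weight 8, max length 18, end-anchored
#>   110100110111
#>   11100101001011
#>   1110100010100011
#>   110100001000100111
```

The returned set hits a 50-position homology at 75 % identity with
probability 0.986989 (98.6989 %).  Every evaluator is exposed directly:

```r
s <- bestSet(res)
overlapComplexity(s)                                  # 2608
matchVariance(s, homologyModel(p = 0.75, L = 10000))  # 31561.0
sensitivity(s, H = 50, p = 0.75)                      # 0.986989
```

`matchVariance()` is the standard unordered-pair estimator;
`orderedMatchVariance()` returns its ordered-pair completion, which is what
sample variances of simulated sequence pairs converge to (see the methods
vignette, `vignettes/seed-design.Rmd`, for why both exist).

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/seedforge optimize --objective oc -m 10 -w 8 \
    --length 14 --swaps 25000 --inner 1 --outer 50 --seed 1 -o seeds.pat
Rscript inst/scripts/seedforge evaluate -p 0.75 -H 50 seeds.pat
```

Pattern files are plain text, one `0/1` mask per line, `#` comments.

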