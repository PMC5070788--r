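test_that("a zero budget returns the start set untouched", {
  set.seed(31)
  s0 <- randomPatternSet(4, 12, 6)
  res <- hillClimb(s0, swaps = 0)
  expect_identical(masks(bestSet(res)), masks(s0))
  expect_identical(nrow(climbTrace(res)), 1L)
  expect_equal(objectiveValue(res), overlapComplexity(s0), tolerance = 0)
})

test_that("both climbers find the optimum on the enumerable 1-pattern space", {
  # anchored length-5 weight-3 masks: 11001 (OC 22), 10101 (24), 10011 (22)
  space <- c("11001", "10101", "10011")
  ocs <- vapply(space, function(m) overlapComplexity(patternSet(m)), numeric(1))
  expect_identical(unname(sort(ocs)), c(22, 22, 24))
  set.seed(32)
  res <- hillClimb(patternSet("10101"), swaps = 200)
  expect_identical(objectiveValue(res), 22)
  rest <- hillClimbTriplets(patternSet("10101"))
  expect_identical(objectiveValue(rest), 22)
})

test_that("hill climbing never worsens and every accepted step improves", {
  set.seed(33)
  md <- homologyModel(0.75, 0.25, 2000)
  for (obj in c("oc", "variance")) {
    s0 <- randomPatternSet(6, 16, 8)
    res <- hillClimb(s0, objective = obj, model = md, swaps = 4000)
    v0 <- if (obj == "oc") overlapComplexity(s0) else matchVariance(s0, md)
    expect_lte(objectiveValue(res), v0)
    tr <- climbTrace(res)
    expect_true(all(diff(tr$value) < 0))     # strictly decreasing accepted steps
    expect_true(all(diff(tr$step) > 0))
    expect_equal(tr$normalized, tr$value / tr$value[1], tolerance = 1e-12)
    # swaps preserve shape: weight, lengths, cardinality, anchoring
    b <- bestSet(res)
    expect_identical(patternWeight(b), patternWeight(s0))
    expect_identical(patternLengths(b), patternLengths(s0))
    expect_identical(length(b), length(s0))
    expect_true(all(substr(masks(b), 1, 1) == "1"))
    expect_true(all(substr(masks(b), nchar(masks(b)), nchar(masks(b))) == "1"))
  }
})

test_that("identical seeds give identical results, traces included", {
  run <- function() {
    set.seed(34)
    s0 <- randomPatternSet(5, 14, 7)
    hillClimb(s0, swaps = 3000)
  }
  a <- run(); b <- run()
  expect_identical(masks(bestSet(a)), masks(bestSet(b)))
  expect_identical(climbTrace(a), climbTrace(b))
  c1 <- optimizeSeeds(4, 6, length = 12, swaps = 1500, inner = 2, outer = 2,
                      seed = 99)
  c2 <- optimizeSeeds(4, 6, length = 12, swaps = 1500, inner = 2, outer = 2,
                      seed = 99)
  expect_identical(masks(bestSet(c1)), masks(bestSet(c2)))
})

test_that("the triplet climber stops at a genuine local minimum", {
  set.seed(35)
  s0 <- randomPatternSet(3, 10, 5)
  res <- hillClimbTriplets(s0)
  s <- bestSet(res)
  best <- objectiveValue(res)
  msk <- masks(s)
  for (r in seq_along(msk)) {
    bits <- strsplit(msk[r], "")[[1]]
    ones <- setdiff(which(bits == "1"), c(1, length(bits)))
    zeros <- setdiff(which(bits == "0"), c(1, length(bits)))
    for (i in ones) for (j in zeros) {
      cand <- swapPositions(s, r, i, j)
      expect_gte(overlapComplexity(cand), best)
    }
  }
})

test_that("degenerate all-match patterns are handled without swapping", {
  s0 <- patternSet("11111")
  res <- hillClimb(s0, swaps = 50)
  expect_identical(masks(bestSet(res)), "11111")
})

test_that("best-of-k restarts is monotone non-worsening in k", {
  set.seed(36)
  seeds <- sample.int(1e6, 25)
  vals <- vapply(seeds, function(sd) {
    set.seed(sd)
    objectiveValue(hillClimb(randomPatternSet(5, 14, 7), swaps = 2000))
  }, numeric(1))
  bests <- vapply(c(1, 5, 25), function(k) min(vals[seq_len(k)]), numeric(1))
  expect_true(all(diff(bests) <= 0))
})

test_that("optimize with one restart reduces to a single seeded hill climb", {
  res <- optimizeSeeds(4, 6, length = 12, swaps = 1000, inner = 1, outer = 1,
                       seed = 5)
  set.seed(5)
  sub <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(sub)
  ref <- hillClimb(randomPatternSet(4, 12, 6), swaps = 1000)
  expect_identical(masks(bestSet(res)), masks(bestSet(ref)))
})

test_that("minimizing OC and minimizing Var yield cross-dominant sets", {
  md <- homologyModel(0.75, 0.25, 10000)
  rOC <- optimizeSeeds(10, 8, length = 20, objective = "oc",
                       swaps = 25000, inner = 1, outer = 3, seed = 41)
  rVar <- optimizeSeeds(10, 8, length = 20, objective = "variance",
                        model = md, swaps = 25000, inner = 1, outer = 3,
                        seed = 41)
  # each set wins on its own criterion
  expect_lte(rOC@oc, overlapComplexity(bestSet(rVar)))
  expect_lte(rVar@variance, matchVariance(bestSet(rOC), md))
})

test_that("sensitivity-objective optimization uses OC as the inner surrogate", {
  res <- optimizeSeeds(3, 5, minLength = 7, maxLength = 11,
                       objective = "sensitivity", H = 20, p = 0.7,
                       swaps = 2000, inner = 3, outer = 2, seed = 43)
  expect_s4_class(res, "OptimizationResult")
  expect_identical(res@objective, "sensitivity")
  expect_true(res@sensitivity > 0 && res@sensitivity <= 1)
  expect_equal(res@sensitivity, sensitivity(bestSet(res), 20, 0.7),
               tolerance = 1e-12)
  expect_identical(patternLengths(bestSet(res)), scheduleLengths(3, 7, 11))
})
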