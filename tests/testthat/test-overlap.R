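test_that("union and shared counts reproduce the worked pair example", {
  expect_identical(unionCount("101011", "111001", 2), 6L)
  expect_identical(sharedCount("101011", "111001", 2), 2L)
  # identical masks at shift 0 coincide completely
  expect_identical(unionCount("101011", "101011", 0), 4L)
  expect_identical(sharedCount("101011", "101011", 0), 4L)
  # no column overlap: union is 2w, shared 0
  expect_identical(unionCount("11", "11", 5), 4L)
  expect_identical(sharedCount("11", "11", 5), 0L)
})

test_that("shared = 2w - union over random pairs and shifts", {
  set.seed(101)
  for (k in 1:300) {
    la <- sample(3:20, 1); lb <- sample(3:20, 1)
    w <- sample(2:min(la, lb), 1)
    a <- randMask(la, w); b <- randMask(lb, w)
    s <- sample(-25:25, 1)
    n <- unionCount(a, b, s)
    sig <- sharedCount(a, b, s)
    expect_identical(sig, 2L * w - n)
    expect_identical(sig, oracleShared(a, b, s))
    expect_identical(n, oracleUnion(a, b, s))
  }
})

test_that("pairOverlapTable covers the documented shift ranges", {
  s <- patternSet(c("101011", "111001"))
  tab <- pairOverlapTable(s, r = 1, rp = 2)
  expect_identical(range(tab$shift), c(-5L, 5L))
  expect_true(all(tab$sigma == 8L - tab$n))
  self <- pairOverlapTable(s, r = 1, rp = 1, selfRange = "restricted")
  expect_identical(self$shift, 0:5)
  expect_identical(self$sigma[1], 4L)
})

test_that("overlap complexity matches exhaustive shift enumeration", {
  expect_identical(overlapComplexity(patternSet("11")), 8)
  expect_identical(overlapComplexity(patternSet("11001")), 22)
  expect_identical(overlapComplexity(patternSet("10101")), 24)
  set.seed(11)
  for (k in 1:20) {
    m <- sample(1:4, 1)
    msk <- replicate(m, randMask(sample(4:10, 1), 3))
    if (anyDuplicated(msk)) next
    expect_identical(overlapComplexity(msk), oracleOC(msk))
  }
})

test_that("the 2^(2w) power-sum identity holds exactly", {
  set.seed(12)
  for (k in 1:40) {
    m <- sample(1:5, 1)
    w <- sample(2:8, 1)
    msk <- unique(replicate(m, randMask(sample((w + 1):16, 1), w)))
    expect_identical(overlapComplexity(msk),
                     2^(2 * w) * oracleHalfPow(msk))
  }
})

test_that("variance matches its closed form and direct-summation oracle", {
  # single trivial pattern: symbolic expansion
  for (p in c(0.3, 0.75)) for (q in c(0.1, 0.25)) for (L in c(5, 40)) {
    expect_equal(matchVariance("1", homologyModel(p, q, L)),
                 L * (p - p^2) + L * (L - 1) * (q - q^2), tolerance = 1e-12)
  }
  # deterministic sequences: every term vanishes
  set.seed(13)
  s <- randomPatternSet(3, 12, 6)
  expect_equal(matchVariance(s, homologyModel(1, 1, 100)), 0, tolerance = 1e-9)
  # random sets against the independent R summation
  for (k in 1:15) {
    msk <- unique(replicate(sample(1:3, 1), randMask(sample(6:12, 1), 5)))
    md <- homologyModel(runif(1, 0.4, 0.95), 0.25, sample(50:500, 1))
    expect_equal(matchVariance(msk, md),
                 oracleVariance(msk, md@p, md@q, md@L),
                 tolerance = 1e-10)
    expect_gte(matchVariance(msk, md), 0)
  }
  expect_error(matchVariance(s, homologyModel(0.7, 0.25, 5)), "below")
})

test_that("variance components scale linearly / quadratically in L", {
  set.seed(14)
  s <- randomPatternSet(3, 10, 6)
  l <- maxLength(s)
  v1 <- varianceComponents(s, homologyModel(0.8, 0.25, 100))
  v2 <- varianceComponents(s, homologyModel(0.8, 0.25, 1000))
  expect_equal(v2$homologous / v1$homologous,
               (1000 - l + 1) / (100 - l + 1), tolerance = 1e-12)
  expect_equal(v2$background / v1$background,
               (1000 - l + 1) * (1000 - l) / ((100 - l + 1) * (100 - l)),
               tolerance = 1e-12)
  expect_equal(v1$homologous + v1$background, v1$total, tolerance = 1e-12)
})

test_that("surrogate ranking agrees with the variance ranking", {
  set.seed(15)
  md <- homologyModel(0.75, 0.25, 2000)
  for (k in 1:10) {
    a <- masks(randomPatternSet(3, 14, 7))
    b <- masks(randomPatternSet(3, 14, 7))
    expect_identical(matchVariance(a, md) < matchVariance(b, md),
                     varianceSurrogate(a, md) < varianceSurrogate(b, md))
  }
  expect_equal(varianceSurrogate("1", homologyModel(0.5, 0.25, 2)), 0.75,
               tolerance = 1e-12)
})

test_that("OC and variance are invariant under reversal and permutation", {
  set.seed(16)
  md <- homologyModel(0.8, 0.25, 500)
  for (k in 1:10) {
    msk <- masks(randomPatternSet(4, c(8, 10, 12, 14), 6))
    expect_identical(overlapComplexity(msk), overlapComplexity(reverseMasks(msk)))
    expect_equal(matchVariance(msk, md), matchVariance(reverseMasks(msk), md),
                 tolerance = 1e-12)
    perm <- sample(length(msk))
    expect_identical(overlapComplexity(msk[perm]), overlapComplexity(msk))
    expect_equal(matchVariance(msk[perm], md), matchVariance(msk, md),
                 tolerance = 1e-12)
  }
})

test_that("contributions sum to twice the objective minus self terms", {
  set.seed(17)
  md <- homologyModel(0.75, 0.25, 1000)
  for (k in 1:10) {
    s <- randomPatternSet(sample(2:5, 1), sample(8:14, 1), 6)
    msk <- masks(s)
    for (obj in c("oc", "variance")) {
      C <- patternContributions(s, obj, model = md)
      selfSum <- sum(vapply(seq_along(msk), function(r) {
        if (obj == "oc") cpp <- seedforge:::cpp_oc(msk[r], TRUE)$value
        else cpp <- seedforge:::cpp_var(msk[r], md@p, md@q, md@L)$alphaSum
        cpp
      }, numeric(1)))
      total <- if (obj == "oc") overlapComplexity(s)
               else seedforge:::cpp_var(msk, md@p, md@q, md@L)$alphaSum
      expect_equal(sum(C), 2 * total - selfSum, tolerance = 1e-9)
    }
  }
  # single pattern: the contribution is the whole objective
  expect_equal(patternContributions("11001", "oc"),
               overlapComplexity("11001"), tolerance = 0)
})

test_that("incremental swap evaluation equals from-scratch recomputation", {
  set.seed(18)
  md <- homologyModel(0.75, 0.25, 1000)
  for (k in 1:60) {
    s <- randomPatternSet(sample(2:4, 1), sample(8:14, 1), 6)
    msk <- masks(s)
    r <- sample(length(msk), 1)
    bits <- strsplit(msk[r], "")[[1]]
    ones <- setdiff(which(bits == "1"), c(1, length(bits)))
    zeros <- setdiff(which(bits == "0"), c(1, length(bits)))
    if (!length(ones) || !length(zeros)) next
    i <- sample(ones, 1); j <- sample(zeros, 1)
    bits[i] <- "0"; bits[j] <- "1"
    swapped <- msk
    swapped[r] <- paste(bits, collapse = "")
    if (anyDuplicated(swapped)) next  # the set invariant forbids this move
    expect_identical(masks(swapPositions(s, r, i, j)), swapped)
    for (obj in 0:1) {
      inc <- seedforge:::cpp_swap_update(msk, r - 1L, i - 1L, j - 1L,
                                         obj, TRUE, md@p, md@q, md@L)
      scratch <- if (obj == 0) seedforge:::cpp_oc(swapped, TRUE)$value
                 else seedforge:::cpp_var(swapped, md@p, md@q, md@L)$alphaSum
      expect_identical(inc$value, scratch)  # bit-identical by construction
      # swap back restores the original objective bit-identically
      back <- seedforge:::cpp_swap_update(swapped, r - 1L, j - 1L, i - 1L,
                                          obj, TRUE, md@p, md@q, md@L)
      orig <- if (obj == 0) seedforge:::cpp_oc(msk, TRUE)$value
              else seedforge:::cpp_var(msk, md@p, md@q, md@L)$alphaSum
      expect_identical(back$value, orig)
    }
    expect_error(swapPositions(s, r, 1, j), "anchor")
  }
})

test_that("self-pair range conventions differ exactly by the negative shifts", {
  msk <- c("110101")
  full <- overlapComplexity(msk, selfRange = "full")
  rest <- overlapComplexity(msk, selfRange = "restricted")
  l <- nchar(msk)
  neg <- sum(vapply((1 - l):(-1), function(s) 2^oracleShared(msk, msk, s),
                    numeric(1)))
  expect_identical(full - rest, neg)
})
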