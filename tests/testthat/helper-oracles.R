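# Slow, independent R implementations used as oracles by the test suite.
# They share no code with the package's C++ core.

# match-position indices of a mask
.mp <- function(mask) which(strsplit(mask, "")[[1]] == "1")

# union / shared match columns with b shifted s to the right of a
oracleShared <- function(a, b, s) length(intersect(.mp(a), .mp(b) + s))
oracleUnion <- function(a, b, s) length(union(.mp(a), .mp(b) + s))

# overlap complexity by direct shift enumeration (full symmetric self range)
oracleOC <- function(masks) {
  tot <- 0
  m <- length(masks)
  for (r in seq_len(m)) for (rp in r:m) {
    la <- nchar(masks[r]); lb <- nchar(masks[rp])
    for (s in (1 - lb):(la - 1))
      tot <- tot + 2^oracleShared(masks[r], masks[rp], s)
  }
  tot
}

# half-power sum: (1/2)^n over the same pairs and shifts
oracleHalfPow <- function(masks) {
  tot <- 0
  m <- length(masks)
  for (r in seq_len(m)) for (rp in r:m) {
    la <- nchar(masks[r]); lb <- nchar(masks[rp])
    for (s in (1 - lb):(la - 1))
      tot <- tot + 0.5^oracleUnion(masks[r], masks[rp], s)
  }
  tot
}

# closed-form variance by direct summation over R(r, r') shift ranges
oracleVariance <- function(masks, p, q, L) {
  l <- max(nchar(masks))
  w <- length(.mp(masks[1]))
  m <- length(masks)
  hom <- 0; bg <- 0
  for (r in seq_len(m)) for (rp in r:m) {
    la <- nchar(masks[r]); lb <- nchar(masks[rp])
    shifts <- if (r == rp) 0:(la - 1) else (1 - lb):(la - 1)
    for (s in shifts) {
      n <- oracleUnion(masks[r], masks[rp], s)
      hom <- hom + p^n - p^(2 * w)
      bg <- bg + q^n - q^(2 * w)
    }
  }
  (L - l + 1) * hom + (L - l + 1) * (L - l) * bg
}

# hit probability by enumeration over all 2^H binary strings, in R
oracleSensitivity <- function(masks, H, p) {
  stopifnot(H <= 16)
  mps <- lapply(masks, .mp)
  lens <- nchar(masks)
  tot <- 0
  for (x in 0:(2^H - 1)) {
    bits <- as.integer(intToBits(x))[seq_len(H)]
    hit <- FALSE
    for (r in seq_along(masks)) {
      if (lens[r] > H) next
      for (o in 0:(H - lens[r])) {
        if (all(bits[o + mps[[r]]] == 1L)) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) tot <- tot + p^sum(bits) * (1 - p)^(H - sum(bits))
  }
  tot
}

# all-window spaced-word match count, pure R
oracleCountMatches <- function(s1, s2, masks) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  N <- 0
  for (msk in masks) {
    mp <- .mp(msk); l <- nchar(msk)
    for (i in seq_len(length(c1) - l + 1))
      for (j in seq_len(length(c2) - l + 1))
        if (all(c1[i + mp - 1] == c2[j + mp - 1])) N <- N + 1
  }
  N
}

reverseMasks <- function(masks)
  vapply(strsplit(masks, ""), function(b) paste(rev(b), collapse = ""),
         character(1))

# random valid mask of given length/weight (anchored)
randMask <- function(len, w) {
  bits <- rep("0", len)
  if (len == 1) return("1")
  bits[c(1, len)] <- "1"
  if (w > 2) bits[1 + sample(len - 2, w - 2)] <- "1"
  paste(bits, collapse = "")
}
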