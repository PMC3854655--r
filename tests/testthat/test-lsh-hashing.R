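specFor <- function(indices, w = 1L, nEff = max(indices) + (w - 1L) %/% 2L) {
  new("HashFunctionSpec", k = length(indices), w = as.integer(w),
      indices = as.integer(indices), nEff = as.integer(nEff),
      seed = NA_integer_)
}

keyFor <- function(seq, indices, w = 1L, nEff = nchar(seq)) {
  extractKey(seq, specFor(indices, w, nEff))
}

test_that("index sampling covers admissible centers and is reproducible", {
  # exhaustive case: sampling without replacement uses every position
  sp <- sampleIndices(10, k = 10, w = 1, seed = 1)
  expect_identical(sp@indices, 1:10)

  # wide windows shrink the admissible range to [1+h, nEff-h]
  sp <- sampleIndices(100, k = 30, w = 3, seed = 5)
  expect_length(sp@indices, 30L)
  expect_false(anyDuplicated(sp@indices) > 0)
  expect_true(min(sp@indices) >= 2 && max(sp@indices) <= 99)

  expect_identical(sampleIndices(100, 30, 3, seed = 7)@indices,
                   sampleIndices(100, 30, 3, seed = 7)@indices)
  expect_error(sampleIndices(10, k = 11, w = 1, seed = 1), "k too large")
  expect_error(sampleIndices(100, k = 40, w = 3, seed = 1), "k \\* w")
  expect_error(sampleIndices(100, k = 10, w = 4, seed = 1), "odd")
})

test_that("key extraction reads the w-mer centered at each index", {
  expect_identical(keyFor("ACGTACGT", c(2, 6), w = 1)@symbols, c("C", "C"))
  expect_identical(keyFor("ACGTACGT", c(2, 6), w = 3)@symbols,
                   c("ACG", "ACG"))
  # w=1, k=nEff spells out the sequence in index order
  s <- "GATTACA"
  expect_identical(paste(keyFor(s, 1:7)@symbols, collapse = ""), s)
  expect_error(keyFor("ACG", c(2, 6), nEff = 8), "sequence too short")
})

test_that("vectorized key matrix agrees with per-record extraction", {
  set.seed(3)
  seqs <- randomSeqs(10, 40)
  names(seqs) <- paste0("s", 1:10)
  sp <- sampleIndices(40, k = 8, w = 3, seed = 9)
  km <- lshOTU:::.keyMatrix(seqs, sp)
  for (i in seq_along(seqs))
    expect_identical(unname(km[, i]), extractKey(seqs[i], sp)@symbols)
})

test_that("mismatch allowance is floor(p * k)", {
  expect_identical(allowedMismatches(64, 0.10), 6L)
  expect_identical(allowedMismatches(64, 0), 0L)
  expect_identical(allowedMismatches(30, 0.10), 3L)
  expect_error(allowedMismatches(30, 1.2), "\\[0, 1\\]")
})

test_that("mismatch counting is positionwise whole-symbol comparison", {
  a <- keyFor("ACGGTTAA", c(1, 3, 5, 7))
  expect_identical(mismatchCount(a, a), 0L)

  k1 <- keyFor("AAAA", 1:4)
  k2 <- keyFor("CCCC", 1:4)
  expect_identical(mismatchCount(k1, k2), 4L)  # antipodal

  b1 <- new("HashKey", symbols = c("AC", "GG", "TT", "AA"), k = 4L, w = 2L,
            owner = "x")
  b2 <- new("HashKey", symbols = c("AC", "GA", "TT", "AA"), k = 4L, w = 2L,
            owner = "y")
  expect_identical(mismatchCount(b1, b2), 1L)
  expect_error(mismatchCount(k1, b1), "incompatible keys")
})

test_that("mismatch count is a metric on keys of a common spec", {
  # enumerate all k=3 keys over {A,C,G}: identity, symmetry, triangle
  syms <- expand.grid(c("A", "C", "G"), c("A", "C", "G"), c("A", "C", "G"),
                      stringsAsFactors = FALSE)
  keys <- lapply(seq_len(nrow(syms)), function(i)
    new("HashKey", symbols = unlist(syms[i, ]), k = 3L, w = 1L, owner = "e"))
  n <- length(keys)
  d <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- mismatchCount(keys[[i]], keys[[j]])
  expect_true(all(diag(d) == 0L))
  expect_true(all(d == t(d)))
  ok <- TRUE
  for (i in seq_len(n))
    for (j in seq_len(n))
      ok <- ok && all(d[i, ] <= d[i, j] + d[j, ])
  expect_true(ok)  # triangle inequality over all 27^3 triples
})

test_that("similarity filter applies the allowance symmetrically", {
  k1 <- keyFor("AAAAAAAA", 1:8)
  expect_true(isSimilar(k1, k1, p = 0))

  mk <- function(nDiff) {
    s <- rep("A", 64)
    if (nDiff > 0) s[seq_len(nDiff)] <- "C"
    new("HashKey", symbols = s, k = 64L, w = 1L, owner = "z")
  }
  base <- mk(0)
  expect_true(isSimilar(base, mk(6), p = 0.10))   # 6 of 64 allowed
  expect_false(isSimilar(base, mk(7), p = 0.10))  # 7 is one too many
  expect_false(isSimilar(base, mk(1), p = 0))
  expect_identical(isSimilar(mk(6), base, p = 0.10),
                   isSimilar(base, mk(6), p = 0.10))
})

test_that("filter at w=1, p=0 equals direct agreement at sampled positions", {
  set.seed(21)
  for (rep in 1:40) {
    nEff <- sample(4:12, 1)
    k <- sample.int(nEff, 1)
    x <- randomSeqs(1, nEff, alphabet = c("A", "C"))
    y <- randomSeqs(1, nEff, alphabet = c("A", "C"))
    sp <- sampleIndices(nEff, k, w = 1)
    got <- isSimilar(extractKey(x, sp), extractKey(y, sp), p = 0)
    direct <- all(substring(x, sp@indices, sp@indices) ==
                  substring(y, sp@indices, sp@indices))
    expect_identical(got, direct)
  }
})

test_that("wider windows are strictly more stringent at fixed centers", {
  set.seed(31)
  for (rep in 1:40) {
    x <- randomSeqs(1, 30)
    # y: near-copy of x so that collisions actually occur
    chars <- strsplit(x, "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      pos <- sample.int(30, nmut)
      chars[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    y <- paste(chars, collapse = "")
    centers <- sort(sample(3:28, 5))
    collide <- function(w) {
      sp <- specFor(centers, w = w, nEff = 30)
      isSimilar(extractKey(x, sp), extractKey(y, sp), p = 0)
    }
    c1 <- collide(1); c3 <- collide(3); c5 <- collide(5)
    expect_true(c1 >= c3 && c3 >= c5)  # collision at w+2 implies at w
  }
})

test_that("collision bound is exact for k = 1 and bounds the MC frequency", {
  expect_equal(collisionProbabilityBound(100, 30, 0), 1.0)
  expect_equal(collisionProbabilityBound(100, 30, 3), 0.97^30)

  # k=1 exact: enumerate all n single-index draws for strings with m diffs
  n <- 6
  for (m in 0:3) {
    x <- paste(rep("A", n), collapse = "")
    y <- paste(c(rep("C", m), rep("A", n - m)), collapse = "")
    hits <- sum(vapply(1:n, function(i)
      substr(x, i, i) == substr(y, i, i), logical(1)))
    expect_equal(hits / n, collisionProbabilityBound(n, 1, m))
  }

  # under independent index draws (the bound's own sampling model) the
  # MC frequency stays above the bound minus 3 SE (small version)
  set.seed(41)
  n <- 100; k <- 30; m <- 3
  x <- strsplit(randomSeqs(1, n), "")[[1]]
  y <- x; flip <- sample.int(n, m)
  y[flip] <- vapply(y[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  draws <- 10000
  collIndep <- vapply(seq_len(draws), function(i) {
    idx <- sample.int(n, k, replace = TRUE)
    all(x[idx] == y[idx])
  }, logical(1))
  bound <- collisionProbabilityBound(n, k, m)
  se <- sqrt(bound * (1 - bound) / draws)
  expect_gte(mean(collIndep), bound - 3 * se)

  # the package's sampler draws *without* replacement: collisions follow
  # the exact hypergeometric probability, strictly below the bound
  exact <- collisionProbabilityExact(n, k, m)
  expect_lt(exact, bound)
  collDistinct <- vapply(seq_len(draws), function(i) {
    idx <- sample.int(n, k)
    all(x[idx] == y[idx])
  }, logical(1))
  seEx <- sqrt(exact * (1 - exact) / draws)
  expect_lt(abs(mean(collDistinct) - exact), 4 * seEx)
})

test_that("cutoff-to-mismatch mapping reduces to ~d at w=1 and grows with w", {
  expect_lt(abs(cutoffToMismatch(0.05, k = 10000, w = 1) - 0.05), 0.005)
  expect_gt(cutoffToMismatch(0.04, 30, 3), cutoffToMismatch(0.04, 30, 1))
  expect_identical(cutoffToMismatch(0, 30, 3), 0)
  expect_error(cutoffToMismatch(1.5, 30, 3), "cutoff")
})
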