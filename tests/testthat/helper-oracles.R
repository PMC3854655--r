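# Independent reference implementations and fixture builders used across
# the suite. The oracles deliberately avoid the package's data structures:
# literal string slicing, dense connectivity closure, hand-rolled DP.

writeFastaFixture <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

randomSeqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""),
    character(1))
}

# canonical form of a partition: sorted list of sorted member-id groups
canonicalPartition <- function(labels) {
  groups <- lapply(split(names(labels), unname(labels)), sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

# Literal replay of the greedy + union procedure, sharing the package's
# RNG stream (same per-iteration seed derivation and draw order) but using
# direct substring comparisons and a dense reachability closure instead of
# hash-key matrices and union-find.
greedyOracle <- function(seqs, k, w, iterations, p, seed,
                         seedingMode = "random") {
  N <- length(seqs)
  nEff <- min(nchar(seqs))
  h <- (w - 1) %/% 2
  allowed <- floor(p * k)
  co <- diag(TRUE, N)
  for (t in seq_len(iterations)) {
    st <- as.integer((seed * 7919 + t * 104729) %% 2147483646) + 1L
    set.seed(st)
    adm <- seq.int(1L + h, nEff - h)
    centers <- sort(adm[sample.int(length(adm), k)])
    ord <- if (seedingMode == "random") sample.int(N) else seq_len(N)
    pool <- ord
    while (length(pool)) {
      s <- pool[1L]
      keep <- integer(0)
      members <- s
      for (y in pool[-1L]) {
        mm <- 0L
        for (c in centers) {
          if (substr(seqs[s], c - h, c + h) != substr(seqs[y], c - h, c + h))
            mm <- mm + 1L
        }
        if (mm <= allowed) members <- c(members, y) else keep <- c(keep, y)
      }
      co[members, members] <- TRUE
      pool <- keep
    }
  }
  # transitive closure by repeated boolean multiplication
  repeat {
    nxt <- (co %*% co) > 0
    if (identical(nxt, co > 0)) break
    co <- nxt
  }
  comp <- integer(N)
  cur <- 0L
  for (i in seq_len(N)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[which(co[i, ] > 0)] <- cur
    }
  }
  structure(paste0("G", comp), names = names(seqs))
}

# Quadratic unit-cost edit distance (Levenshtein) by hand DP.
editDistanceOracle <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  la <- length(x); lb <- length(y)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la))
    for (j in seq_len(lb))
      d[i + 1L, j + 1L] <- min(d[i, j] + (x[i] != y[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
  d[la + 1L, lb + 1L]
}

# small simulated dataset matching the package generator's conditions
smallSimulation <- function(numSpecies = 8, len = 120, readsPerRef = 6,
                            errorRate = 0.03, seed = 42) {
  refs <- generateReferences(numSpecies, len, minDivergence = 0.20,
                             seed = seed)
  simulateReads(refs, readsPerRef, errorRate, seed = seed + 1)
}
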