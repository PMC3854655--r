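## Exact pairwise distances (global alignment and k-mer profile) and the
## post-hoc cutoff validation: the clustering itself never computes these
## all-pairs quantities; this module measures, after the fact, how far
## apart the reads inside each OTU really are.

## Unit-cost scoring over {A,C,G,T,N}: match 0, mismatch -1, and N
## mismatches everything including another N (ambiguity must never look
## like identity).
.nwSubstMat <- local({
  m <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 0
  m["N", "N"] <- -1
  m
})

.nwAlign <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = "global",
    substitutionMatrix = .nwSubstMat,
    gapOpening = 0, gapExtension = 1)
}

#' Needleman-Wunsch global-alignment distance
#'
#' Aligns two sequences globally under unit edit costs (match 0, mismatch
#' 1, gap 1, no end-gap discount) and returns
#' (mismatches + gap columns) / alignment length, a distance in
#' \code{[0, 1]} that is 0 iff the sequences are identical. \code{a} may be
#' a set of sequences, in which case each is aligned against the single
#' \code{b} and a vector is returned.
#'
#' @param a a character string / vector or \code{DNAStringSet}.
#' @param b a single sequence.
#' @return numeric distance(s) in \code{[0, 1]}.
#' @examples
#' nwDistance("ACGT", "ACGA")  # 0.25
#' nwDistance("ACGT", "ACG")   # 0.25: one gap column out of 4
#' @export
nwDistance <- function(a, b) {
  if (is(a, "XStringSet")) a <- as.character(a)
  if (is(b, "XStringSet") || is(b, "XString")) b <- as.character(b)
  b <- b[1L]
  if (any(!nzchar(a)) || !nzchar(b)) stop("empty sequence")
  # co-optimal alignments can differ in length (a mismatch traded for two
  # gap columns at equal cost), so each pair is aligned in a canonical
  # (lexicographic) argument order to keep the normalization symmetric
  res <- numeric(length(a))
  fwd <- a <= b
  if (any(fwd)) {
    aln <- .nwAlign(a[fwd], b)
    res[fwd] <- -Biostrings::score(aln) /
      Biostrings::width(Biostrings::alignedPattern(aln))
  }
  for (i in which(!fwd)) {
    aln <- .nwAlign(b, a[i])
    res[i] <- -Biostrings::score(aln) /
      Biostrings::width(Biostrings::alignedPattern(aln))
  }
  unname(res)
}

#' k-mer profile distance
#'
#' One minus the fraction of shared k-mers:
#' \deqn{1 - \frac{\sum_v \min(c_a(v), c_b(v))}{\min(L_a, L_b) - k + 1}}
#' where \eqn{c_x(v)} counts occurrences of k-mer \eqn{v} in sequence x.
#' Zero for identical sequences, one when no k-mer is shared.
#'
#' @param a,b sequences (character or \code{DNAStringSet} elements), both
#'   at least \code{kmerSize} long.
#' @param kmerSize word length (default 6).
#' @return distance in \code{[0, 1]}.
#' @examples
#' kmerDistance("AAAA", "AAAT", kmerSize = 2)  # 1 - 2/3
#' @export
kmerDistance <- function(a, b, kmerSize = 6) {
  x <- Biostrings::DNAStringSet(c(as.character(a)[1L], as.character(b)[1L]))
  if (any(Biostrings::width(x) < kmerSize))
    stop("sequence shorter than kmerSize")
  counts <- Biostrings::oligonucleotideFrequency(x, width = kmerSize)
  shared <- sum(pmin(counts[1L, ], counts[2L, ]))
  denom <- min(Biostrings::width(x)) - kmerSize + 1
  1 - shared / denom
}

## All within-group pairwise distances for one OTU, returning the maximum.
## For nw, alignments are vectorized one member against all later members.
.maxPairDist <- function(seqs, metric, kmerSize, maxPairs) {
  m <- length(seqs)
  if (m < 2L) return(c(max = 0, sampled = 0))
  pairs <- utils::combn(m, 2L)
  sampled <- FALSE
  if (is.finite(maxPairs) && ncol(pairs) > maxPairs) {
    pairs <- pairs[, sample.int(ncol(pairs), maxPairs), drop = FALSE]
    sampled <- TRUE
  }
  if (metric == "nw") {
    best <- 0
    if (!sampled) {
      # scan members in lexicographic order so every vectorized call
      # aligns pattern <= subject (keeps nwDistance fully vectorized)
      seqsSorted <- sort(unname(seqs), method = "radix")
      for (j in 2:m) {
        d <- nwDistance(seqsSorted[seq_len(j - 1L)], seqsSorted[j])
        best <- max(best, d)
      }
    } else {
      for (j in seq_len(ncol(pairs)))
        best <- max(best, nwDistance(seqs[pairs[1L, j]], seqs[pairs[2L, j]]))
    }
  } else {
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = kmerSize)
    lens <- nchar(seqs)
    best <- 0
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      shared <- sum(pmin(counts[i1, ], counts[i2, ]))
      best <- max(best, 1 - shared / (min(lens[i1], lens[i2]) - kmerSize + 1))
    }
  }
  c(max = best, sampled = as.numeric(sampled))
}

#' Validate a distance cutoff against a clustering
#'
#' For every OTU, computes all pairwise distances between its member reads
#' under an exact metric and reports the maximum; the clustering satisfies
#' the cutoff when the global maximum over OTUs is at or below it.
#' Singleton OTUs contribute 0.
#'
#' @param assignment an [OTUAssignment-class] covering the sample.
#' @param x the reads, a named \code{DNAStringSet} containing every
#'   assigned id.
#' @param metric \code{"nw"} (global alignment, the default) or
#'   \code{"kmer"}.
#' @param cutoff the target maximum distance d.
#' @param kmerSize word length for the k-mer metric (default 6).
#' @param maxPairs cap on the number of within-OTU pairs evaluated per OTU;
#'   when an OTU exceeds it, a uniform sample of pairs is scored instead
#'   and the report is flagged as a sampled lower bound (default
#'   \code{Inf}: exact).
#' @return a [DistanceReport-class].
#' @examples
#' reads <- Biostrings::DNAStringSet(c(r1 = "ACGT", r2 = "ACGA"))
#' a <- OTUAssignment(c(r1 = "OTU_1", r2 = "OTU_1"))
#' validateCutoff(a, reads, metric = "nw", cutoff = 0.10)
#' @export
validateCutoff <- function(assignment, x, metric = c("nw", "kmer"), cutoff,
                           kmerSize = 6, maxPairs = Inf) {
  metric <- match.arg(metric)
  ids <- names(assignment@labels)
  if (!all(ids %in% names(x)))
    stop("assignment contains ids missing from the sequence set")
  seqs <- as.character(x)[ids]
  groups <- split(seqs, assignment@labels[ids])
  res <- vapply(groups, .maxPairDist, numeric(2),
                metric = metric, kmerSize = kmerSize, maxPairs = maxPairs)
  perOTU <- res["max", ]
  globalMax <- if (length(perOTU)) max(perOTU) else 0
  new("DistanceReport", metric = metric, perOTUMax = perOTU,
      globalMax = globalMax, cutoff = cutoff,
      satisfied = globalMax <= cutoff,
      sampled = any(res["sampled", ] > 0))
}

#' Tabulate a distance report
#'
#' @param report a [DistanceReport-class].
#' @return a data.frame with one row per OTU: \code{otu_id},
#'   \code{max_distance}.
#' @export
distanceReportTable <- function(report) {
  data.frame(otu_id = names(report@perOTUMax),
             max_distance = unname(report@perOTUMax),
             row.names = NULL)
}
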