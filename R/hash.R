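## The randomized, w-mer-enriched locality-sensitive hash and its
## similarity filter. A hash function is k window centers sampled uniformly
## without replacement; the hash of a sequence is the tuple of w-mers read
## at those centers; two sequences pass the filter when at most
## floor(p * k) of the k symbols differ. Wider windows (w > 1) make the
## filter strictly more stringent and cut false positives; mismatches
## *within* a w-mer are never allowed.

#' Draw a randomized hash function
#'
#' Samples \code{k} distinct window centers uniformly without replacement
#' from the admissible positions of a length-\code{nEff} sequence (those
#' where the full \code{w}-window fits), returned sorted ascending. The
#' admissible centers are \code{(w+1)/2 .. nEff-(w-1)/2}, i.e.
#' \code{nEff - w + 1} positions.
#'
#' @param nEff effective sequence length the hash is drawn for; when
#'   clustering, the length of the shortest read in the sample.
#' @param k number of centers to sample; at most \code{nEff - w + 1}, and
#'   \code{k * w} must not exceed \code{nEff}.
#' @param w odd window width in nucleotides (default 1: single-nucleotide
#'   sampling).
#' @param seed optional integer seed making the draw reproducible; when
#'   \code{NULL} the ambient RNG stream is used (and advanced).
#' @return a [HashFunctionSpec-class].
#' @examples
#' sampleIndices(100, k = 30, w = 3, seed = 1)
#' @export
sampleIndices <- function(nEff, k, w = 1L, seed = NULL) {
  nEff <- as.integer(nEff); k <- as.integer(k); w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("w must be an odd positive integer")
  if (nEff < w) stop("nEff must be at least w")
  h <- (w - 1L) %/% 2L
  admissible <- seq.int(1L + h, nEff - h)
  if (k > length(admissible))
    stop("k too large for read length: ", k, " > ", length(admissible),
         " admissible centers")
  if (as.double(k) * w > nEff)
    stop("k * w exceeds nEff (", k, " * ", w, " > ", nEff, ")")
  if (!is.null(seed)) set.seed(seed)
  centers <- sort(admissible[sample.int(length(admissible), k)])
  new("HashFunctionSpec", k = k, w = w, indices = as.integer(centers),
      nEff = nEff, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Extract the hash key of one sequence
#'
#' Reads the \code{w}-mer centered at each sampled index of \code{spec}
#' from a sequence; the ordered tuple of those symbols is the sequence's
#' hash value. Deterministic given the spec.
#'
#' @param record a single sequence: a character string, a named length-1
#'   character vector, or a length-1 \code{DNAStringSet} element.
#' @param spec a [HashFunctionSpec-class].
#' @param id identifier recorded as the key's owner (taken from names when
#'   absent).
#' @return a [HashKey-class].
#' @examples
#' sp <- new("HashFunctionSpec", k = 2L, w = 1L, indices = c(2L, 6L),
#'           nEff = 8L, seed = NA_integer_)
#' extractKey("ACGTACGT", sp)
#' @export
extractKey <- function(record, spec, id = NULL) {
  if (is(record, "XStringSet") || is(record, "XString"))
    record <- as.character(record)
  if (is.null(id))
    id <- if (!is.null(names(record))) names(record)[1L] else "<unnamed>"
  seq <- unname(record[1L])
  if (nchar(seq) < spec@nEff)
    stop("sequence too short: '", id, "' has ", nchar(seq),
         " nt, spec requires ", spec@nEff)
  h <- (spec@w - 1L) %/% 2L
  symbols <- substring(seq, spec@indices - h, spec@indices + h)
  new("HashKey", symbols = symbols, k = spec@k, w = spec@w,
      owner = as.character(id))
}

## Vectorized key extraction: k x N character matrix of w-mer symbols,
## one column per sequence. The clustering hot path; provably equivalent
## to extractKey column by column (tested).
.keyMatrix <- function(seqs, spec) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (any(nchar(seqs) < spec@nEff))
    stop("sequence too short for hash spec (nEff=", spec@nEff, ")")
  h <- (spec@w - 1L) %/% 2L
  m <- vapply(seq_len(spec@k), function(j)
    substr(seqs, spec@indices[j] - h, spec@indices[j] + h),
    character(length(seqs)))
  m <- matrix(m, nrow = length(seqs), ncol = spec@k,
              dimnames = list(names(seqs), NULL))
  t(m)
}

#' Mismatch allowance of the similarity filter
#'
#' The filter accepts a pair of keys when at most \code{floor(p * k)} of
#' the k sampled symbols differ; with \code{k = 64} and \code{p = 0.10}
#' that is 6 symbols, and \code{p = 0} demands exact equality of all k.
#'
#' @param k number of sampled symbols.
#' @param p allowed mismatch fraction in \code{[0, 1]}.
#' @return integer, the maximum number of differing symbols accepted.
#' @examples
#' allowedMismatches(64, 0.10)  # 6
#' @export
allowedMismatches <- function(k, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]")
  as.integer(floor(p * k))
}

#' Compare two hash keys
#'
#' \code{mismatchCount} counts the positions at which the two keys' w-mer
#' symbols differ (whole-symbol comparison, no partial credit within a
#' w-mer); it is a metric on keys of a common spec. \code{isSimilar}
#' applies the allowance: \code{TRUE} iff at most \code{floor(p * k)}
#' symbols differ; symmetric in its arguments.
#'
#' @param a,b [HashKey-class] objects built from the same spec (same k
#'   and w).
#' @param p allowed mismatch fraction in \code{[0, 1]}.
#' @return \code{mismatchCount}: integer in \code{0..k};
#'   \code{isSimilar}: logical.
#' @export
mismatchCount <- function(a, b) {
  if (a@k != b@k || a@w != b@w)
    stop("incompatible keys: specs differ (k or w)")
  sum(a@symbols != b@symbols)
}

#' @rdname mismatchCount
#' @export
isSimilar <- function(a, b, p) {
  mismatchCount(a, b) <= allowedMismatches(a@k, p)
}

#' Lower bound on the collision probability
#'
#' For two length-\code{n} sequences differing at no more than \code{m}
#' nucleotides, the probability (over the random draw of \code{k} indices,
#' single-nucleotide windows) that their hash values are identical is at
#' least \code{(1 - m/n)^k}. For \code{k = 1} the bound is exact.
#'
#' @param n sequence length.
#' @param k number of sampled indices.
#' @param m maximum number of differing nucleotides, \code{0 <= m <= n}.
#' @return the lower bound, a probability.
#' @examples
#' collisionProbabilityBound(100, 30, 3)  # 0.97^30
#' @export
collisionProbabilityBound <- function(n, k, m) {
  if (m < 0 || m > n) stop("m must lie in [0, n]")
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  (1 - m / n)^k
}

#' Exact collision probability under without-replacement sampling
#'
#' [sampleIndices()] draws the k centers *without* replacement, so for two
#' sequences differing at exactly \code{m} positions the probability that
#' all k sampled positions avoid the differences is hypergeometric,
#' \deqn{\prod_{i=0}^{m-1} \frac{n-k-i}{n-i} = \binom{n-m}{k} / \binom{n}{k},}
#' which is strictly below the independent-draw value \eqn{(1-m/n)^k} of
#' [collisionProbabilityBound()] whenever \code{k > 1} and \code{m > 0}:
#' distinct indices cannot re-test an already-matching position, so the
#' filter is slightly harsher than the classical bound suggests.
#'
#' @inheritParams collisionProbabilityBound
#' @return the exact collision probability at p = 0, w = 1.
#' @examples
#' collisionProbabilityExact(100, 30, 3)  # < 0.97^30
#' @export
collisionProbabilityExact <- function(n, k, m) {
  if (m < 0 || m > n) stop("m must lie in [0, n]")
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  if (k > n - m) return(0)
  if (m == 0) return(1)
  prod((n - k - seq_len(m) + 1) / (n - seq_len(m) + 1))
}

#' Map a distance cutoff to a mismatch fraction
#'
#' The clustering cutoff \code{d} is a *nucleotide* divergence (e.g. 0.04
#' means sequences in one OTU are at most 4\% apart), but the hash filter
#' counts whole \code{w}-mer *symbols*: a pair of sequences at divergence
#' \code{d} corrupts, in expectation, a fraction \eqn{q = 1-(1-d)^w} of the
#' windows, and the k sampled windows add binomial noise around that mean.
#' The returned mismatch fraction is \eqn{q + \sqrt{q(1-q)/k}} — the
#' expected corrupted-symbol fraction plus one sampling standard error —
#' so that a pair at the nominal divergence passes the filter in a typical
#' iteration. For \code{w = 1} and large \code{k} this reduces to
#' approximately \code{d}.
#'
#' @param cutoff target maximum nucleotide divergence d in \code{[0, 1)}.
#' @param k,w the hash parameters the fraction will be used with.
#' @return mismatch fraction p suitable for [isSimilar()]/[clusterOTUs()].
#' @examples
#' cutoffToMismatch(0.04, k = 30, w = 3)
#' @export
cutoffToMismatch <- function(cutoff, k, w) {
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)")
  q <- 1 - (1 - cutoff)^w
  min(1, q + sqrt(q * (1 - q) / k))
}
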