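#' @import methods
NULL

#' Randomized hash function specification
#'
#' One iteration's locality-sensitive hash: \code{k} distinct sampled window
#' centers over an effective sequence length \code{nEff}, each the center of a
#' \code{w}-nucleotide window (\code{w} odd so the window is symmetric). The
#' hash of a sequence is the tuple of \code{w}-mers read at the sampled
#' centers; two sequences collide when at most a permitted number of those
#' symbols differ.
#'
#' @slot k integer, number of sampled window centers.
#' @slot w integer, odd window width in nucleotides.
#' @slot indices integer vector of k distinct 1-based centers, sorted
#'   ascending; every window fits inside \code{[1, nEff]}.
#' @slot nEff integer, effective sequence length the spec was drawn for
#'   (the shortest read of the sample when used for clustering).
#' @slot seed integer, RNG seed that produced the indices (NA when the spec
#'   was drawn from the ambient RNG stream).
#'
#' @seealso [sampleIndices()], [extractKey()]
#' @export
setClass("HashFunctionSpec",
  representation(k = "integer", w = "integer", indices = "integer",
                 nEff = "integer", seed = "integer"))

setValidity("HashFunctionSpec", function(object) {
  h <- (object@w - 1L) %/% 2L
  msg <- character(0)
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@w) != 1L || object@w < 1L || object@w %% 2L == 0L)
    msg <- c(msg, "w must be a single odd positive integer")
  if (length(object@indices) != object@k)
    msg <- c(msg, "length(indices) must equal k")
  if (anyDuplicated(object@indices))
    msg <- c(msg, "indices must be distinct")
  if (is.unsorted(object@indices))
    msg <- c(msg, "indices must be sorted ascending")
  if (length(object@indices) &&
      (min(object@indices) - h < 1L || max(object@indices) + h > object@nEff))
    msg <- c(msg, "every w-window must fit inside [1, nEff]")
  if (length(msg) == 0 && as.double(object@k) * object@w > object@nEff)
    msg <- c(msg, "k * w must not exceed nEff")
  if (length(msg)) msg else TRUE
})

#' Hash key of a single sequence
#'
#' The ordered tuple of \code{k} \code{w}-mers extracted at a
#' [HashFunctionSpec-class]'s sampled centers. Keys are comparable only when
#' built from the same specification (same \code{k} and \code{w}).
#'
#' @slot symbols character vector of k strings, each of length w.
#' @slot k,w the spec dimensions the key was built under.
#' @slot owner id of the sequence the key was extracted from.
#'
#' @seealso [extractKey()], [mismatchCount()], [isSimilar()]
#' @export
setClass("HashKey",
  representation(symbols = "character", k = "integer", w = "integer",
                 owner = "character"))

setValidity("HashKey", function(object) {
  if (length(object@symbols) != object@k)
    return("number of symbols must equal k")
  if (any(nchar(object@symbols) != object@w))
    return("every symbol must have length w")
  TRUE
})

#' OTU assignment of a set of sequences
#'
#' A total partition of sequence identifiers into OTU labels, the central
#' output of the clustering module. Labels are \code{"OTU_<integer>"} in
#' order of cluster creation. Each sequence also carries the id of the
#' sample it came from, so that joint clusterings of several samples can be
#' split back for beta-diversity comparison.
#'
#' @slot labels named character vector, sequence id -> OTU label.
#' @slot sample named character vector over the same ids, sequence id ->
#'   sample id.
#' @slot metadata list of run metadata (parameters, per-iteration OTU
#'   counts, seeds) when produced by [clusterOTUs()].
#'
#' @seealso [clusterOTUs()], [otuLabels()], [otuCount()]
#' @export
setClass("OTUAssignment",
  representation(labels = "character", sample = "character",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("OTUAssignment", function(object) {
  ids <- names(object@labels)
  msg <- character(0)
  if (length(object@labels) < 1L) msg <- c(msg, "no assignments")
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    msg <- c(msg, "every sequence id must be a non-empty name")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate sequence id")
  if (anyNA(object@labels) || any(!nzchar(object@labels)))
    msg <- c(msg, "every sequence must carry an OTU label")
  if (!identical(names(object@sample), ids))
    msg <- c(msg, "sample ids must be named by the same sequence ids")
  if (length(msg)) msg else TRUE
})

#' OTU size profile
#'
#' The abundance histogram that feeds every richness estimator:
#' \code{sizeCounts[i]} is the number of OTUs containing exactly \code{i}
#' sequences, \code{SObs} the number of OTUs and \code{N} the total number
#' of sequences, with \eqn{\sum_i n_i = S_{obs}} and
#' \eqn{\sum_i i\, n_i = N}.
#'
#' @slot sizeCounts integer vector named by OTU size i, values n_i > 0.
#' @slot SObs integer, observed OTU count.
#' @slot N integer, total sequence count.
#'
#' @seealso [sizeProfile()], [chao1()], [shannon()], [ace()]
#' @export
setClass("OTUSizeProfile",
  representation(sizeCounts = "integer", SObs = "integer", N = "integer"))

setValidity("OTUSizeProfile", function(object) {
  sizes <- as.integer(names(object@sizeCounts))
  msg <- character(0)
  if (anyNA(sizes) || any(sizes < 1L))
    msg <- c(msg, "sizeCounts must be named by positive OTU sizes")
  if (any(object@sizeCounts < 0L)) msg <- c(msg, "all n_i must be >= 0")
  if (sum(object@sizeCounts) != object@SObs)
    msg <- c(msg, "sum(n_i) must equal SObs")
  if (sum(as.double(sizes) * object@sizeCounts) != object@N)
    msg <- c(msg, "sum(i * n_i) must equal N")
  if (length(msg)) msg else TRUE
})

#' ACE estimator components
#'
#' All intermediate quantities of the abundance-based coverage estimator,
#' exposed for audit: the rare/abundant split at the \code{abund} threshold,
#' the rare-sequence total \code{NRare}, the sample coverage \code{CAce},
#' the coefficient of variation \code{gammaSq} and the final estimate
#' \code{SAce}.
#'
#' @seealso [ace()]
#' @export
setClass("AceComponents",
  representation(abund = "integer", SRare = "integer", SAbund = "integer",
                 NRare = "integer", CAce = "numeric", gammaSq = "numeric",
                 SAce = "numeric"))

#' Intra-OTU distance validation report
#'
#' Post-hoc check that a clustering respects a distance cutoff: the maximum
#' pairwise distance inside each OTU under an exact metric, its maximum over
#' all OTUs, and whether that global maximum stays at or below the cutoff.
#' Singleton OTUs contribute 0.
#'
#' @slot metric "nw" (global-alignment) or "kmer".
#' @slot perOTUMax named numeric, OTU label -> max within-OTU distance.
#' @slot globalMax numeric in [0, 1].
#' @slot cutoff the target maximum distance d.
#' @slot satisfied logical, \code{globalMax <= cutoff}.
#' @slot sampled logical, TRUE when pair sampling made the maxima lower
#'   bounds rather than exact values.
#'
#' @seealso [validateCutoff()]
#' @export
setClass("DistanceReport",
  representation(metric = "character", perOTUMax = "numeric",
                 globalMax = "numeric", cutoff = "numeric",
                 satisfied = "logical", sampled = "logical"))

setValidity("DistanceReport", function(object) {
  msg <- character(0)
  if (length(object@perOTUMax) &&
      (min(object@perOTUMax) < 0 || max(object@perOTUMax) > 1))
    msg <- c(msg, "all distances must lie in [0, 1]")
  expected <- if (length(object@perOTUMax)) max(object@perOTUMax) else 0
  if (!isTRUE(all.equal(object@globalMax, expected)))
    msg <- c(msg, "globalMax must equal the maximum per-OTU distance")
  if (length(msg)) msg else TRUE
})

#' Simulated amplicon dataset with ground truth
#'
#' Reads drawn from species-specific reference sequences with a bounded
#' number of substitution errors per read, plus the read-to-reference truth
#' labels used for recovery scoring.
#'
#' @slot references DNAStringSet of reference ("species") sequences.
#' @slot reads DNAStringSet of simulated reads, named by read id.
#' @slot truth named character vector, read id -> reference id.
#' @slot errorRate maximum per-read substitution fraction.
#' @slot seed integer RNG seed the dataset was generated from.
#'
#' @seealso [simulateReads()], [recoveryScore()]
#' @export
setClass("SimulatedDataset",
  representation(references = "DNAStringSet", reads = "DNAStringSet",
                 truth = "character", errorRate = "numeric",
                 seed = "integer"))

setValidity("SimulatedDataset", function(object) {
  msg <- character(0)
  if (!identical(names(object@truth), names(object@reads)))
    msg <- c(msg, "truth must be named by the read ids, in read order")
  if (!all(object@truth %in% names(object@references)))
    msg <- c(msg, "every truth label must name an existing reference")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "HashFunctionSpec", function(object) {
  cat(sprintf(
    "HashFunctionSpec: k=%d sampled centers, w=%d, nEff=%d (seed %s)\n",
    object@k, object@w, object@nEff,
    ifelse(is.na(object@seed), "ambient", object@seed)))
  cat("  centers:", paste(utils::head(object@indices, 12L), collapse = " "),
      if (object@k > 12L) "..." else "", "\n")
})

setMethod("show", "HashKey", function(object) {
  cat(sprintf("HashKey for '%s' (k=%d, w=%d): %s%s\n", object@owner,
              object@k, object@w,
              paste(utils::head(object@symbols, 8L), collapse = "|"),
              if (object@k > 8L) "|..." else ""))
})

setMethod("show", "OTUAssignment", function(object) {
  cat(sprintf("OTUAssignment: %d sequences in %d OTUs across %d sample(s)\n",
              length(object@labels), otuCount(object),
              length(unique(object@sample))))
  sizes <- sort(table(object@labels), decreasing = TRUE)
  cat("  largest OTUs:",
      paste(sprintf("%s(%d)", utils::head(names(sizes), 5L),
                    utils::head(as.integer(sizes), 5L)), collapse = " "),
      "\n")
})

setMethod("show", "OTUSizeProfile", function(object) {
  cat(sprintf("OTUSizeProfile: S_obs=%d OTUs over N=%d sequences\n",
              object@SObs, object@N))
  n1 <- if ("1" %in% names(object@sizeCounts)) object@sizeCounts[["1"]] else 0L
  n2 <- if ("2" %in% names(object@sizeCounts)) object@sizeCounts[["2"]] else 0L
  cat(sprintf("  singletons n1=%d, doubletons n2=%d\n", n1, n2))
})

setMethod("show", "AceComponents", function(object) {
  cat(sprintf(
    "ACE (abund=%d): S_rare=%d S_abund=%d N_rare=%d C_ACE=%.4f gamma^2=%.4f\n",
    object@abund, object@SRare, object@SAbund, object@NRare, object@CAce,
    object@gammaSq))
  cat(sprintf("  S_ACE = %.4f\n", object@SAce))
})

setMethod("show", "DistanceReport", function(object) {
  cat(sprintf(
    "DistanceReport (%s metric): global max %.4f vs cutoff %.4f -> %s%s\n",
    object@metric, object@globalMax, object@cutoff,
    if (object@satisfied) "satisfied" else "VIOLATED",
    if (object@sampled) " [sampled lower bound]" else ""))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(
    "SimulatedDataset: %d reads from %d references (max error %.1f%%, seed %d)\n",
    length(object@reads), length(object@references),
    100 * object@errorRate, object@seed))
})

## ---- accessors --------------------------------------------------------

#' Accessors for OTU assignments
#'
#' @param x an [OTUAssignment-class].
#' @return \code{otuLabels}: named character vector mapping sequence id to
#'   OTU label. \code{otuCount}: the number of distinct OTUs.
#'   \code{sampleIds}: named character vector mapping sequence id to sample
#'   id.
#' @examples
#' a <- OTUAssignment(c(r1 = "OTU_1", r2 = "OTU_1", r3 = "OTU_2"), "s1")
#' otuCount(a)
#' @export
otuLabels <- function(x) x@labels

#' @rdname otuLabels
#' @export
otuCount <- function(x) length(unique(x@labels))

#' @rdname otuLabels
#' @export
sampleIds <- function(x) x@sample

#' Construct an OTU assignment
#'
#' @param labels named character vector, sequence id -> OTU label.
#' @param sample sample id(s): a single string recycled over all sequences,
#'   or a named character vector parallel to \code{labels}.
#' @param metadata optional list of run metadata.
#' @return an [OTUAssignment-class].
#' @export
OTUAssignment <- function(labels, sample = "sample1", metadata = list()) {
  labels <- structure(as.character(labels), names = names(labels))
  if (length(sample) == 1L && is.null(names(sample)))
    sample <- structure(rep(sample, length(labels)), names = names(labels))
  new("OTUAssignment", labels = labels,
      sample = structure(as.character(sample), names = names(sample)),
      metadata = metadata)
}
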