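## Greedy, seed-based OTU assignment under the LSH similarity filter,
## repeated for l iterations with a fresh randomized hash each time, and
## merged with a union (transitive-closure) operation: two reads share a
## final OTU iff they were co-clustered in at least one iteration, directly
## or through intermediates.

## Deterministic per-iteration seed stream derived from the master seed.
## Exact integer arithmetic in doubles (< 2^53), result in [1, 2^31-2].
.iterationSeed <- function(seed, t) {
  as.integer((as.double(seed) * 7919 + as.double(t) * 104729) %% 2147483646) + 1L
}

.sampleIdOf <- function(x) {
  if (!is(x, "Annotated")) return("sample1")
  sid <- S4Vectors::metadata(x)$sampleId
  if (is.null(sid)) "sample1" else sid
}

#' One greedy assignment pass under a fixed hash function
#'
#' Scans the sequence pool in the given order: the first unassigned
#' sequence seeds a new OTU, every remaining unassigned sequence whose hash
#' key differs from the seed's at no more than \code{floor(p * k)} symbols
#' joins it, assigned sequences leave the pool, and the scan repeats until
#' the pool is empty. Every sequence ends up labeled exactly once.
#'
#' @param x a named \code{DNAStringSet} (or character vector) of reads.
#' @param spec the iteration's [HashFunctionSpec-class].
#' @param p mismatch fraction in \code{[0, 1]}.
#' @param scanOrder permutation of \code{seq_along(x)} giving the order in
#'   which seeds are picked (default: input order).
#' @return an [OTUAssignment-class].
#' @seealso [clusterOTUs()] for the full iterated procedure.
#' @export
assignIteration <- function(x, spec, p, scanOrder = seq_along(x)) {
  N <- length(x)
  if (N == 0L) stop("no sequences")
  if (!setequal(scanOrder, seq_len(N)))
    stop("scanOrder must be a permutation of seq_along(x)")
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_len(N))
  keys <- .keyMatrix(x, spec)
  allowed <- allowedMismatches(spec@k, p)
  lab <- integer(N)
  pool <- as.integer(scanOrder)
  cur <- 0L
  while (length(pool)) {
    s <- pool[1L]
    mm <- colSums(keys[, pool, drop = FALSE] != keys[, s])
    cur <- cur + 1L
    lab[pool[mm <= allowed]] <- cur
    pool <- pool[mm > allowed]
  }
  OTUAssignment(structure(paste0("OTU_", lab), names = ids),
                .sampleIdOf(x))
}

#' Merge per-iteration assignments by union
#'
#' Two sequences share a final OTU iff they are connected in the graph
#' whose edges join sequences co-clustered in at least one iteration
#' (transitive closure, computed with a disjoint-set union). The merged
#' OTU count is therefore never larger than the smallest per-iteration
#' count. Labels are reassigned \code{"OTU_<i>"} in order of first
#' appearance along the input sequence order.
#'
#' @param assignments a list of [OTUAssignment-class] objects covering the
#'   same sequence ids.
#' @return an [OTUAssignment-class].
#' @export
unionMerge <- function(assignments) {
  if (!length(assignments)) stop("no assignments to merge")
  ids <- names(assignments[[1L]]@labels)
  for (a in assignments)
    if (!setequal(names(a@labels), ids))
      stop("assignment mismatch: iterations cover different sequence ids")
  N <- length(ids)
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (a in assignments) {
    lab <- a@labels[ids]
    for (members in split(seq_len(N), lab)) {
      r <- find(members[1L])
      for (m in members[-1L]) {
        rm <- find(m)
        if (rm != r) parent[rm] <- r
      }
    }
  }
  comp <- vapply(seq_len(N), find, integer(1))
  newLabel <- integer(N)
  newLabel[unique(comp)] <- seq_along(unique(comp))
  OTUAssignment(structure(paste0("OTU_", newLabel[comp]), names = ids),
                assignments[[1L]]@sample[ids])
}

#' Cluster reads into OTUs by iterated LSH filtering
#'
#' The full procedure: draw \code{iterations} independent hash functions
#' from a seeded stream, run one greedy assignment pass per hash (with the
#' sequence pool shuffled by that iteration's stream under the default
#' random seeding), and merge the per-iteration partitions with
#' [unionMerge()]. Fully reproducible given the parameters, seed and input
#' order. More iterations repair false negatives of the random sampling
#' (similar reads that one hash happened to separate) at the cost of more
#' false-positive merges, so the merged OTU count is non-increasing in the
#' number of iterations.
#'
#' @param x reads: a named \code{DNAStringSet}, a named character vector,
#'   or a named list of \code{DNAStringSet}s (one per sample) for a joint
#'   multi-sample clustering.
#' @param k number of sampled window centers per hash (default 30).
#' @param w odd window width in nucleotides (default 3).
#' @param iterations number of hash functions l (default 4).
#' @param p mismatch fraction of the filter, the fraction of the k symbols
#'   allowed to differ (default 0: exact key equality).
#' @param distanceCutoff optional target maximum nucleotide divergence d
#'   within an OTU; when given, \code{p} is derived from it with
#'   [cutoffToMismatch()] and the \code{p} argument is ignored.
#' @param seed master RNG seed (default 1).
#' @param seedingMode \code{"random"} (shuffle the pool each iteration with
#'   the iteration's RNG stream; the default) or \code{"input_order"}
#'   (deterministic scan in input order, useful for debugging).
#' @return an [OTUAssignment-class]; its \code{metadata} records the
#'   parameters, the effective mismatch fraction, per-iteration seeds and
#'   per-iteration OTU counts.
#' @examples
#' reads <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
#'                                     c = "TTTTTTTTTT"))
#' otuLabels(clusterOTUs(reads, k = 4, w = 1, iterations = 2, seed = 1))
#' @export
clusterOTUs <- function(x, k = 30, w = 3, iterations = 4, p = 0,
                        distanceCutoff = NULL, seed = 1,
                        seedingMode = c("random", "input_order")) {
  seedingMode <- match.arg(seedingMode)
  if (is.list(x) && !is(x, "XStringSet")) {
    sampleMap <- unlist(lapply(names(x), function(s)
      structure(rep(s, length(x[[s]])), names = names(x[[s]]))))
    seqs <- do.call(c, lapply(x, as.character))
    names(seqs) <- names(sampleMap)
    if (anyDuplicated(names(seqs)))
      stop("duplicate identifier across samples")
    x <- Biostrings::DNAStringSet(seqs)
    S4Vectors::metadata(x)$sampleMap <- sampleMap
  }
  if (!is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  N <- length(x)
  if (N == 0L) stop("no sequences")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.null(distanceCutoff)) p <- cutoffToMismatch(distanceCutoff, k, w)
  nEff <- min(Biostrings::width(x))
  iterSeeds <- vapply(seq_len(iterations), .iterationSeed,
                      integer(1), seed = seed)
  parts <- vector("list", iterations)
  for (t in seq_len(iterations)) {
    spec <- sampleIndices(nEff, k, w, seed = iterSeeds[t])
    ord <- if (seedingMode == "random") sample.int(N) else seq_len(N)
    parts[[t]] <- assignIteration(x, spec, p, scanOrder = ord)
  }
  merged <- unionMerge(parts)
  sampleMap <- S4Vectors::metadata(x)$sampleMap
  if (!is.null(sampleMap))
    merged@sample <- sampleMap[names(merged@labels)]
  else
    merged@sample[] <- .sampleIdOf(x)
  merged@metadata <- list(
    params = list(k = k, w = w, iterations = iterations, p = p,
                  distanceCutoff = distanceCutoff, seed = seed,
                  seedingMode = seedingMode, nEff = nEff),
    iterationSeeds = iterSeeds,
    perIterationOTUs = vapply(parts, otuCount, integer(1)))
  merged
}
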