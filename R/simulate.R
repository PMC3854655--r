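## Synthetic amplicon data with ground truth: reads drawn from
## species-specific reference sequences with a bounded number of
## substitution errors per read ("up to x%": the error count of each read
## is uniform on 0..floor(x * length)). Substitution-only — the hash
## filter is position-based, so indel noise is a different regime and is
## deliberately not emulated.

.BASES <- c("A", "C", "G", "T")

#' Generate divergent reference sequences
#'
#' Draws \code{numSpecies} uniform-random sequences of the given length,
#' rejecting candidates whose Hamming divergence to any accepted reference
#' falls below \code{minDivergence}; references are named
#' \code{"ref_<i>"}.
#'
#' @param numSpecies number of reference ("species") sequences.
#' @param length reference length in bp.
#' @param minDivergence minimum pairwise Hamming divergence as a fraction
#'   of \code{length} (default 0.20).
#' @param seed RNG seed.
#' @param maxTries rejection-sampling attempts per reference before
#'   giving up (default 1000).
#' @return a named \code{DNAStringSet}.
#' @examples
#' generateReferences(3, 100, minDivergence = 0.3, seed = 1)
#' @export
generateReferences <- function(numSpecies, length, minDivergence = 0.20,
                               seed = 1, maxTries = 1000) {
  if (numSpecies < 1L) stop("numSpecies must be >= 1")
  if (minDivergence < 0 || minDivergence > 1)
    stop("minDivergence must lie in [0, 1]")
  set.seed(seed)
  accepted <- matrix(character(0), nrow = length, ncol = 0)
  while (ncol(accepted) < numSpecies) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cand <- sample(.BASES, length, replace = TRUE)
      if (ncol(accepted) == 0L ||
          min(colMeans(accepted != cand)) >= minDivergence) {
        accepted <- cbind(accepted, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("divergence unsatisfiable after ", maxTries, " tries")
  }
  refs <- Biostrings::DNAStringSet(apply(accepted, 2, paste, collapse = ""))
  names(refs) <- paste0("ref_", seq_len(numSpecies))
  refs
}

#' Simulate error-bounded reads from references
#'
#' For each reference, draws \code{readsPerRef} full-length copies; each
#' read carries an independently drawn number of substitutions, uniform on
#' \code{0..floor(errorRate * length)}, at uniformly chosen positions,
#' each substituted to a different base. Read ids are
#' \code{"<ref>_read<j>"} and the truth map records every read's source.
#'
#' @param references a named \code{DNAStringSet} (e.g. from
#'   [generateReferences()]).
#' @param readsPerRef reads per reference.
#' @param errorRate maximum per-read substitution fraction ("up to" this
#'   error), in \code{[0, 1)}.
#' @param seed RNG seed.
#' @return a [SimulatedDataset-class].
#' @examples
#' refs <- generateReferences(2, 60, seed = 1)
#' simulateReads(refs, readsPerRef = 3, errorRate = 0.05, seed = 2)
#' @export
simulateReads <- function(references, readsPerRef, errorRate, seed = 1) {
  if (errorRate < 0 || errorRate >= 1)
    stop("errorRate must lie in [0, 1)")
  if (readsPerRef < 1L) stop("readsPerRef must be >= 1")
  set.seed(seed)
  refSeqs <- as.character(references)
  reads <- character(0)
  truth <- character(0)
  for (ref in names(references)) {
    chars <- strsplit(refSeqs[[ref]], "")[[1L]]
    L <- length(chars)
    maxErr <- floor(errorRate * L)
    for (j in seq_len(readsPerRef)) {
      m <- sample.int(maxErr + 1L, 1L) - 1L
      readChars <- chars
      if (m > 0L) {
        pos <- sample.int(L, m)
        for (q in pos)
          readChars[q] <- sample(setdiff(.BASES, readChars[q]), 1L)
      }
      id <- sprintf("%s_read%d", ref, j)
      reads[id] <- paste(readChars, collapse = "")
      truth[id] <- ref
    }
  }
  readSet <- Biostrings::DNAStringSet(reads)
  S4Vectors::metadata(readSet)$sampleId <- "simulated"
  new("SimulatedDataset", references = references, reads = readSet,
      truth = truth, errorRate = errorRate, seed = as.integer(seed))
}

#' Score a clustering against simulation ground truth
#'
#' \code{numOTUs} is the number of distinct OTU labels; \code{purity} is
#' the fraction of reads whose OTU's majority truth label matches their
#' own. Over-splitting is pure (all-singleton clustering has purity 1);
#' under-merging shows up as purity loss.
#'
#' @param assignment an [OTUAssignment-class] covering all simulated
#'   reads.
#' @param truth named character vector read id -> reference id, or a
#'   [SimulatedDataset-class].
#' @return list with elements \code{numOTUs} and \code{purity}.
#' @export
recoveryScore <- function(assignment, truth) {
  if (is(truth, "SimulatedDataset")) truth <- truth@truth
  ids <- names(assignment@labels)
  if (!setequal(ids, names(truth)))
    stop("truth and assignment cover different read ids")
  correct <- unlist(lapply(split(ids, assignment@labels[ids]), function(g) {
    tab <- table(truth[g])
    truth[g] == names(tab)[which.max(tab)]
  }), use.names = FALSE)
  list(numOTUs = otuCount(assignment), purity = mean(correct))
}
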