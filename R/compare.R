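## Beta-diversity comparison of samples that were clustered jointly: each
## sample is reduced to the set of OTU labels its reads fall in, samples
## are compared by the Jaccard index of those label sets, and the
## similarity matrix is grouped by average-linkage agglomeration on the
## complement distance 1 - J.

#' Per-sample OTU label sets
#'
#' @param assignment an [OTUAssignment-class] from a joint clustering of
#'   several samples (each sequence carries its sample id).
#' @return named list, sample id -> character vector of OTU labels with at
#'   least one read from that sample.
#' @export
otuSets <- function(assignment) {
  lapply(split(assignment@labels, assignment@sample), function(l)
    sort(unique(unname(l))))
}

#' Jaccard similarity of two OTU label sets
#'
#' \eqn{|a \cap b| / |a \cup b|}: the proportion of shared OTUs between
#' two samples, ignoring abundance. Higher means more similar communities.
#'
#' @param a,b character vectors of OTU labels; at least one non-empty.
#' @return similarity in \code{[0, 1]}.
#' @examples
#' jaccardIndex(c("O1", "O2", "O3"), c("O2", "O3", "O4"))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("undefined similarity: both sets empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix
#'
#' @param sets a named list of OTU label sets (as from [otuSets()]), or an
#'   [OTUAssignment-class] covering at least two samples.
#' @return square symmetric matrix with unit diagonal, dimnames = sample
#'   ids.
#' @export
similarityMatrix <- function(sets) {
  if (is(sets, "OTUAssignment")) sets <- otuSets(sets)
  n <- length(sets)
  if (n < 2L) stop("need at least 2 samples")
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- jaccardIndex(sets[[i]], sets[[j]])
  m
}

#' Hierarchically group samples from a similarity matrix
#'
#' Agglomerates samples on the distance \code{1 - J} (average linkage by
#' default); merge heights are on the Jaccard-distance scale, so two
#' samples sharing every OTU merge at 0 and fully disjoint samples at 1.
#'
#' @param m similarity matrix from [similarityMatrix()].
#' @param linkage agglomeration criterion passed to
#'   \code{\link[stats]{hclust}} (default \code{"average"}).
#' @return an \code{hclust} tree.
#' @seealso [writeNewick()] to serialize the tree.
#' @export
clusterSamples <- function(m, linkage = "average") {
  if (nrow(m) < 2L) stop("need at least 2 samples")
  stats::hclust(stats::as.dist(1 - m), method = linkage)
}

#' Serialize a sample tree as Newick
#'
#' @param tree an \code{hclust} from [clusterSamples()].
#' @param path output path; when \code{NULL} the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
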