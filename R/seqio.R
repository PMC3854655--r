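## FASTA input and the tab-separated OTU table: the only file formats the
## tool touches. All text is UTF-8 with Unix newlines.

#' Read a multi-FASTA sample
#'
#' Reads one sample's 16S reads from a (possibly line-wrapped) multi-FASTA
#' file into a named \code{DNAStringSet}, preserving file order. Sequences
#' are uppercased and RNA-style \code{U} is mapped to \code{T}; after that
#' normalization only \code{A,C,G,T,N} are accepted. Identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @param sampleId sample identifier attached to the returned set (defaults
#'   to the file name without extension).
#' @return a \code{DNAStringSet} named by sequence id, with
#'   \code{S4Vectors::metadata(x)$sampleId} set.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "AC", "GT", ">r2", "acgn"), fa)
#' readSampleFasta(fa)
#' @export
readSampleFasta <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(ids))
    stop("duplicate identifier: ", ids[anyDuplicated(ids)])
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid alphabet in record '", ids[which(bad)[1L]],
         "': only A,C,G,T,N allowed after normalization")
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  S4Vectors::metadata(x)$sampleId <- sampleId
  x
}

#' Write a sample as multi-FASTA
#'
#' @param x a named \code{DNAStringSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSampleFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write OTU assignment tables
#'
#' The on-disk form of an [OTUAssignment-class] is a TSV with the header
#' \code{sequence_id<TAB>otu_id<TAB>sample_id} and one row per sequence.
#' \code{writeOTUTable} followed by \code{readOTUTable} is the identity.
#'
#' @param x an [OTUAssignment-class].
#' @param path path of the table.
#' @return \code{readOTUTable}: an [OTUAssignment-class];
#'   \code{writeOTUTable}: invisibly, \code{path}.
#' @examples
#' a <- OTUAssignment(c(r1 = "OTU_1", r2 = "OTU_1"), "s1")
#' tsv <- tempfile(fileext = ".tsv")
#' writeOTUTable(a, tsv)
#' readOTUTable(tsv)
#' @export
writeOTUTable <- function(x, path) {
  stopifnot(is(x, "OTUAssignment"))
  df <- data.frame(sequence_id = names(x@labels),
                   otu_id = unname(x@labels),
                   sample_id = unname(x@sample))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeOTUTable
#' @export
readOTUTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no assignments in ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("sequence_id", "otu_id", "sample_id")))
    stop("parse error at line 1: expected header ",
         "'sequence_id\\totu_id\\tsample_id'")
  if (length(lines) == 1L) stop("no assignments in ", path)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("parse error at line ", which(nf != 3L)[1L] + 1L,
         ": expected 3 tab-separated fields")
  m <- do.call(rbind, fields)
  if (any(!nzchar(m)))
    stop("parse error at line ", which(rowSums(!nzchar(m)) > 0)[1L] + 1L,
         ": empty field")
  OTUAssignment(structure(m[, 2L], names = m[, 1L]),
                structure(m[, 3L], names = m[, 1L]))
}
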