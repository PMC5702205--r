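#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' contract used throughout the package: identifiers are the first
#' whitespace-delimited token of each header, sequences are uppercased, and
#' malformed files (no leading header, empty sequences, duplicate ids) are
#' rejected with an informative error.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; the full header line (minus
#'   the id) is kept in `S4Vectors::mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: ", path, " is empty")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA parse error at line ", first,
         ": expected '>' header before sequence data")
  }
  x <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(x) == 0L)) {
    bad <- names(x)[Biostrings::width(x) == 0L][1L]
    stop("FASTA parse error: record '", bad, "' has an empty sequence")
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  x
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}
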