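# FASTA input/output, via Biostrings.

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]: sequences are
#' uppercased, ids truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("FASTA file is empty: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence lines (<= 120).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}
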