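#' Read a FASTA file into a named character vector
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header. Sequences are uppercased and U is normalized to T, so downstream
#' scoring code works over a single DNA alphabet.
#'
#' @param path path to a FASTA file.
#' @return named character vector, id -> sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- normalize_seq(as.character(ss))
  names(out) <- ids
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector, id -> sequence.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
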