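#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and converts U to T so every scoring routine sees one alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector over A/C/G/T/N.
#' @keywords internal
normalize_seq <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

#' Reverse complement of DNA strings
#' @param x character vector of sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## all k-mers of a string, in order (empty character if too short)
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## deterministic RNG scope: runs `expr` under a seed without disturbing the
## caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## sample() without the length-1 surprise
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
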