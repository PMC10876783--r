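## in-frame hexamers (step 3) of a sequence starting at frame 0
inframe_hexamers <- function(sequence) {
  n <- nchar(sequence)
  if (n < 6L) return(character(0))
  pos <- seq.int(1L, n - 5L, by = 3L)
  substring(sequence, pos, pos + 5L)
}

all_hexamers <- function() {
  g <- expand.grid(BASES, BASES, BASES, BASES, BASES, BASES,
                   stringsAsFactors = FALSE)
  ## vary the first base slowest for a stable, readable order
  apply(g[, 6:1], 1L, paste0, collapse = "")
}

#' Train hexamer usage tables from coding and non-coding sequences
#'
#' Coding sequences contribute in-frame hexamers of their longest ORF;
#' non-coding sequences contribute hexamers stepped by 3 from their start.
#' Frequencies carry a pseudocount floor so every hexamer has positive
#' probability in both tables.
#'
#' @param coding_seqs character vector of coding transcript sequences.
#' @param noncoding_seqs character vector of non-coding sequences.
#' @param pseudocount added to every hexamer count.
#' @return list with numeric vectors `coding` and `noncoding` (length 4096,
#'   named by hexamer, each summing to 1).
#' @export
train_hexamer_tables <- function(coding_seqs, noncoding_seqs,
                                 pseudocount = 1) {
  hx <- all_hexamers()
  count_set <- function(seqs, use_orf) {
    cnt <- setNames(rep(pseudocount, length(hx)), hx)
    for (s in seqs) {
      s <- normalize_seq(s)
      if (use_orf) s <- orf_sequence(s)
      h <- inframe_hexamers(s)
      h <- h[h %in% hx]   # drop hexamers containing N
      if (length(h)) {
        t <- table(h)
        cnt[names(t)] <- cnt[names(t)] + as.numeric(t)
      }
    }
    cnt / sum(cnt)
  }
  list(coding = count_set(coding_seqs, use_orf = TRUE),
       noncoding = count_set(noncoding_seqs, use_orf = FALSE))
}

#' Hexamer usage-bias score of a sequence
#'
#' Mean log-ratio log(f_coding / f_noncoding) over the in-frame hexamers of
#' the sequence's longest ORF. Positive values indicate coding-like codon
#' context; 0 is returned when the ORF is shorter than 6 nt.
#'
#' @param sequence a single DNA string.
#' @param tables as returned by [train_hexamer_tables()].
#' @return numeric score.
#' @export
hexamer_score <- function(sequence, tables) {
  orf <- orf_sequence(sequence)
  if (nchar(orf) < 6L) return(0)
  h <- inframe_hexamers(orf)
  h <- h[h %in% names(tables$coding)]
  if (!length(h)) return(0)
  mean(log(tables$coding[h] / tables$noncoding[h]))
}
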