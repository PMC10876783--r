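BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12-column tab-separated hits as produced by
#' `blastn -outfmt 6`. Query/subject sequence lengths are not part of this
#' format; supply them separately (e.g. from the FASTA inputs) to
#' [call_conservation()].
#'
#' @param path path to an outfmt-6 file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`.
#' @export
read_blast6 <- function(path) {
  if (!file.exists(path)) stopf("BLAST file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- BLAST6_COLS
    return(out)
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L)) {
    stopf("BLAST outfmt-6 line %d has %d columns (expected 12)",
          which(nf != 12L)[1L], nf[nf != 12L][1L])
  }
  out <- read.delim(text = lines, header = FALSE, col.names = BLAST6_COLS,
                    stringsAsFactors = FALSE)
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stopf("percent identity outside [0, 100]")
  if (any(out$evalue < 0)) stopf("negative E-value")
  out
}
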