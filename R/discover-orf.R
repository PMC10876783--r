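#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward reading frames for ATG...stop ORFs (stop codon
#' included in the length). Assembled transcripts are taken as
#' orientation-resolved, so reverse frames are not scanned by default. Ties
#' are broken by the leftmost start position.
#'
#' @param sequence a single DNA string (ACGT).
#' @param reverse also scan the reverse complement (off by default).
#' @return list with `orf_length` (nt, 0 if none), `orf_coverage`
#'   (orf_length / sequence length), `frame` (0, 1 or 2; NA if none),
#'   `start` (0-based position of the A of ATG; NA if none).
#' @export
longest_orf <- function(sequence, reverse = FALSE) {
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  best <- list(orf_length = 0L, orf_coverage = 0, frame = NA_integer_,
               start = NA_integer_)
  scan_one <- function(s) {
    res <- list(len = 0L, frame = NA_integer_, start = NA_integer_)
    ns <- nchar(s)
    for (f in 0:2) {
      ncod <- (ns - f) %/% 3L
      if (ncod < 2L) next
      pos <- f + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, pos, pos + 2L)
      starts <- which(codons == "ATG")
      stops <- which(codons %in% STOP_CODONS)
      if (!length(starts) || !length(stops)) next
      ## first stop at or after each start
      idx <- findInterval(starts - 1L, stops) + 1L
      ok <- idx <= length(stops)
      if (!any(ok)) next
      lens <- integer(length(starts))
      lens[ok] <- (stops[idx[ok]] - starts[ok] + 1L) * 3L
      j <- which.max(lens)
      if (lens[j] > res$len ||
          (lens[j] == res$len && !is.na(res$start) &&
           pos[starts[j]] - 1L < res$start)) {
        res <- list(len = lens[j], frame = f, start = pos[starts[j]] - 1L)
      }
    }
    res
  }
  fwd <- scan_one(sequence)
  if (fwd$len > best$orf_length) {
    best <- list(orf_length = fwd$len, orf_coverage = fwd$len / n,
                 frame = fwd$frame, start = fwd$start)
  }
  if (reverse) {
    rev <- scan_one(revcomp(sequence))
    if (rev$len > best$orf_length) {
      best <- list(orf_length = rev$len, orf_coverage = rev$len / n,
                   frame = rev$frame, start = NA_integer_)
    }
  }
  best
}

#' Extract the longest-ORF subsequence
#' @param sequence a single DNA string.
#' @return the ORF nucleotide sequence including the stop codon, or "" if
#'   the sequence has no ORF.
#' @export
orf_sequence <- function(sequence) {
  o <- longest_orf(sequence)
  if (o$orf_length == 0L) return("")
  substring(normalize_seq(sequence), o$start + 1L, o$start + o$orf_length)
}
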