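## Karlin-Altschul parameters for ungapped nucleotide alignment with
## match +1 / mismatch -2 (blastn defaults for ungapped statistics)
KA_LAMBDA <- 1.28
KA_K <- 0.46

#' Seed-and-extend nucleotide homology search
#'
#' A zero-dependency aligner playing the role of BLASTN for conservation
#' calls: exact `word_size`-mer seeds, ungapped X-drop extension with
#' +1/-2 scoring, best HSP per query/subject pair, and E-values from the
#' Karlin-Altschul formula over the query x database search space. An
#' external blastn run (outfmt 6, via [read_blast6()]) can stand in for
#' this engine where full BLAST sensitivity is wanted.
#'
#' @param queries named character vector of query sequences.
#' @param subjects named character vector of subject sequences.
#' @param word_size exact seed length.
#' @param match,mismatch scoring.
#' @param xdrop stop extension when the score drops this far below the
#'   running maximum.
#' @param max_evalue report hits at or below this E-value.
#' @return data.frame in outfmt-6 shape (see [read_blast6()]) with one
#'   best HSP per query/subject pair.
#' @export
homology_search <- function(queries, subjects, word_size = 11L,
                            match = 1, mismatch = -2, xdrop = 20,
                            max_evalue = 10) {
  if (!length(queries) || !length(subjects))
    return(read_blast6_empty())
  db_len <- sum(nchar(subjects))
  subj_chars <- lapply(subjects, seq_chars)
  subj_kmers <- lapply(subjects, function(s) {
    km <- seq_kmers(s, word_size)
    split(seq_along(km), km)
  })
  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    q_ch <- seq_chars(q)
    qk <- seq_kmers(q, word_size)
    uqk <- unique(qk)
    for (sn in names(subjects)) {
      smap <- subj_kmers[[sn]]
      shared <- intersect(uqk, names(smap))
      if (!length(shared)) next
      ## one seed per diagonal (the first along the query)
      seen_diag <- integer(0)
      best <- NULL
      for (km in shared) {
        qpos <- which(qk == km)
        spos <- smap[[km]]
        for (qp in qpos) for (sp in spos) {
          dg <- sp - qp
          if (dg %in% seen_diag) next
          seen_diag <- c(seen_diag, dg)
          hsp <- extend_seed(q_ch, subj_chars[[sn]], qp, sp, word_size,
                             match, mismatch, xdrop)
          if (is.null(best) || hsp$score > best$score) best <- hsp
        }
      }
      if (is.null(best)) next
      evalue <- KA_K * nchar(q) * db_len * exp(-KA_LAMBDA * best$score)
      if (evalue > max_evalue) next
      bits <- (KA_LAMBDA * best$score - log(KA_K)) / log(2)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qn, subject_id = sn,
        percent_identity = 100 * best$matches / best$length,
        alignment_length = best$length,
        mismatches = best$length - best$matches, gap_opens = 0L,
        q_start = best$q_start, q_end = best$q_end,
        s_start = best$s_start, s_end = best$s_end,
        evalue = evalue, bit_score = bits, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(read_blast6_empty())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_blast6_empty <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = 12))
  names(out) <- BLAST6_COLS
  out
}

## ungapped X-drop extension of an exact seed, both directions
extend_seed <- function(q, s, qp, sp, w, match, mismatch, xdrop) {
  ## seed itself
  score <- w * match
  ## extend right from the seed end
  right_ext <- xdrop_extend(q, s, qp + w, sp + w, +1L, match, mismatch,
                            xdrop)
  left_ext <- xdrop_extend(q, s, qp - 1L, sp - 1L, -1L, match, mismatch,
                           xdrop)
  q_start <- qp - left_ext$steps
  q_end <- qp + w - 1L + right_ext$steps
  s_start <- sp - left_ext$steps
  s_end <- sp + w - 1L + right_ext$steps
  len <- q_end - q_start + 1L
  matches <- w + left_ext$matches + right_ext$matches
  list(score = score + left_ext$score + right_ext$score,
       matches = matches, length = len,
       q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end)
}

## walk one direction until the score falls `xdrop` below its maximum;
## returns the extension up to the maximal-scoring point
xdrop_extend <- function(q, s, qi, si, step, match, mismatch, xdrop) {
  best_score <- 0; best_steps <- 0L; best_matches <- 0L
  score <- 0; steps <- 0L; matches <- 0L
  nq <- length(q); ns <- length(s)
  while (qi >= 1L && qi <= nq && si >= 1L && si <= ns) {
    if (q[qi] == s[si]) {
      score <- score + match
      matches <- matches + 1L
    } else {
      score <- score + mismatch
    }
    steps <- steps + 1L
    if (score > best_score) {
      best_score <- score; best_steps <- steps; best_matches <- matches
    }
    if (score <= best_score - xdrop) break
    qi <- qi + step
    si <- si + step
  }
  list(score = best_score, steps = best_steps, matches = best_matches)
}
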