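## penalty weights of the plant miRNA target rule
MIRNA_MISMATCH <- 1
MIRNA_WOBBLE <- 0.5
MIRNA_BULGE <- 1
MIRNA_SEED_RANGE <- 2:13   # penalties doubled at these miRNA positions
MIRNA_MAX_SCORE <- 4

#' Plant-rule miRNA target scoring
#'
#' Scores every ungapped register of the miRNA's reverse complement along
#' the target, plus registers carrying at most one single-nucleotide
#' target bulge. Penalties per miRNA position (5'->3'): mismatch 1, G:U
#' wobble 0.5, target bulge 1, all doubled at positions 2-13. The best
#' (minimum-penalty) site is reported; the interaction counts as a hit at
#' score <= `max_score` (4, the default cutoff of plant target finders).
#' `perfect` means a full-length Watson-Crick duplex with no wobble and no
#' bulge (score 0 in an ungapped register).
#'
#' @param mirna_seq miRNA sequence, 18-26 nt (RNA or DNA alphabet).
#' @param target_seq target RNA sequence.
#' @param max_score report a hit only at or below this penalty.
#' @param allow_bulge also scan one-bulge registers.
#' @return one-row data.frame (`score`, `site_start` 1-based on the
#'   target, `site_end`, `perfect`, `hit`), or NULL when the target is
#'   shorter than the miRNA.
#' @export
plant_target_score <- function(mirna_seq, target_seq,
                               max_score = MIRNA_MAX_SCORE,
                               allow_bulge = TRUE) {
  mi <- seq_chars(normalize_seq(mirna_seq))
  tg <- seq_chars(normalize_seq(target_seq))
  k <- length(mi)
  if (k < 18L || k > 26L) stopf("miRNA must be 18-26 nt (got %d)", k)
  n <- length(tg)
  if (n < k) return(NULL)
  mult <- ifelse(seq_len(k) %in% MIRNA_SEED_RANGE, 2, 1)
  ## weighted penalty of miRNA position i facing target base p
  pw <- matrix(0, nrow = k, ncol = n)
  for (i in seq_len(k)) {
    wc <- (mi[i] == "A" & tg == "T") | (mi[i] == "T" & tg == "A") |
      (mi[i] == "C" & tg == "G") | (mi[i] == "G" & tg == "C")
    gu <- (mi[i] == "G" & tg == "T") | (mi[i] == "T" & tg == "G")
    pw[i, ] <- ifelse(wc, 0, ifelse(gu, MIRNA_WOBBLE, MIRNA_MISMATCH)) *
      mult[i]
  }
  ## ungapped registers: at 1-based register o, miRNA position i faces
  ## target position o + k - i (antiparallel pairing)
  n_reg <- n - k + 1L
  u_score <- numeric(n_reg)
  for (i in seq_len(k)) {
    u_score <- u_score + pw[i, (k - i + 1L):(k - i + n_reg)]
  }
  o_best <- which.min(u_score)
  best <- list(score = u_score[o_best], start = o_best,
               end = o_best + k - 1L, perfect = FALSE)
  ## perfect = full-length Watson-Crick, no wobble, no bulge: with wobble
  ## weighted > 0 this is exactly an ungapped score of 0
  best$perfect <- best$score == 0
  ## one single-nt target bulge (site length k + 1): a bulge between
  ## miRNA positions j and j+1 takes the doubling status of position j+1;
  ## positions 1..j face target o+k+1-i, positions j+1..k face o+k-i
  if (allow_bulge && n >= k + 1L) {
    n_reg2 <- n - k
    s_b <- numeric(n_reg2)
    d <- matrix(0, nrow = k, ncol = n_reg2)
    for (i in seq_len(k)) {
      b_i <- pw[i, (k - i + 1L):(k - i + n_reg2)]
      a_i <- pw[i, (k - i + 2L):(k - i + n_reg2 + 1L)]
      s_b <- s_b + b_i
      d[i, ] <- a_i - b_i
    }
    cum <- apply(d, 2L, cumsum)               # k x n_reg2
    bp <- MIRNA_BULGE * ifelse((2:k) %in% MIRNA_SEED_RANGE, 2, 1)
    with_bulge <- cum[seq_len(k - 1L), , drop = FALSE] + bp
    j_min <- apply(with_bulge, 2L, which.min)
    b_score <- s_b + with_bulge[cbind(j_min, seq_len(n_reg2))]
    ob <- which.min(b_score)
    if (b_score[ob] < best$score) {
      best <- list(score = b_score[ob], start = ob, end = ob + k,
                   perfect = FALSE)
    }
  }
  data.frame(score = best$score, site_start = best$start,
             site_end = best$end, perfect = best$perfect,
             hit = best$score <= max_score)
}

#' Score a miRNA set against a set of RNAs
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param rnas named character vector of target sequences.
#' @param rna_class label recorded for the targets ("lncRNA" or "mRNA").
#' @param max_score hit cutoff.
#' @return data.frame of hits: `mirna_id`, `rna_id`, `rna_class`,
#'   `score`, `site_start`, `site_end`, `perfect`.
#' @export
scan_mirna_targets <- function(mirnas, rnas, rna_class = "lncRNA",
                               max_score = MIRNA_MAX_SCORE) {
  rows <- list()
  for (m in names(mirnas)) {
    for (r in names(rnas)) {
      h <- plant_target_score(mirnas[[m]], rnas[[r]], max_score)
      if (!is.null(h) && h$hit) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(mirna_id = m, rna_id = r, rna_class = rna_class,
                     stringsAsFactors = FALSE),
          h[, c("score", "site_start", "site_end", "perfect")])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), rna_id = character(0),
                      rna_class = character(0), score = numeric(0),
                      site_start = integer(0), site_end = integer(0),
                      perfect = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
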