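## Fickett (1982) TESTCODE lookup tables. For each base, a position
## parameter (codon-phase asymmetry) and a content parameter (composition)
## are mapped through ten-interval probability tables and combined as a
## weighted sum of the eight probabilities.

FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.33, T = 0.14)
FICKETT_POSITION_CUTS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)

FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_CUTS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0.0)

fickett_lookup <- function(value, cuts, probs) {
  probs[which(value >= cuts)[1L]]
}

#' Fickett position parameters of a sequence
#'
#' For each base, counts occurrences in the three codon phases and returns
#' max-count / (min-count + 1).
#'
#' @param sequence a single DNA string.
#' @return named numeric vector (A, C, G, T).
#' @export
fickett_position_params <- function(sequence) {
  ch <- seq_chars(normalize_seq(sequence))
  phase <- (seq_along(ch) - 1L) %% 3L
  vapply(BASES, function(b) {
    cnt <- vapply(0:2, function(p) sum(ch == b & phase == p), numeric(1))
    max(cnt) / (min(cnt) + 1)
  }, numeric(1))
}

#' Fickett TESTCODE score of a sequence
#'
#' The weighted sum of the eight looked-up probabilities (four position,
#' four content). Higher values indicate coding-like periodicity and
#' composition.
#'
#' @param sequence a single DNA string, ideally >= 200 nt.
#' @return numeric score.
#' @export
fickett_score <- function(sequence) {
  sequence <- normalize_seq(sequence)
  pos <- fickett_position_params(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  score <- 0
  for (b in BASES) {
    score <- score + FICKETT_POSITION_WEIGHT[[b]] *
      fickett_lookup(pos[[b]], FICKETT_POSITION_CUTS,
                     FICKETT_POSITION_PROB[[b]])
    score <- score + FICKETT_CONTENT_WEIGHT[[b]] *
      fickett_lookup(sum(ch == b) / n, FICKETT_CONTENT_CUTS,
                     FICKETT_CONTENT_PROB[[b]])
  }
  unname(score)
}
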