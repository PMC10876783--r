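## sequence-level building blocks of the simulator

## sense codons weighted for the GC-rich third position typical of grass
## coding regions; this plants both the codon-phase periodicity (Fickett)
## and the hexamer usage bias the scorers rely on
codon_weights <- function() {
  b <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  codons <- paste0(b[, 3], b[, 2], b[, 1])
  codons <- setdiff(codons, STOP_CODONS)
  w <- ifelse(substr(codons, 3, 3) %in% c("G", "C"), 3, 1)
  ## mild first-position bias as well
  w <- w * ifelse(substr(codons, 1, 1) %in% c("G", "A"), 1.5, 1)
  setNames(w / sum(w), codons)
}
CODON_WEIGHTS <- codon_weights()

## iid background with the given base composition
random_seq <- function(n, prob = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)) {
  paste0(sample_vec(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

## first-order Markov chain, slightly AT-rich, used for non-coding
## transcript bodies ("Markov-shuffled" background)
MARKOV_TRANS <- local({
  m <- matrix(c(
    0.32, 0.20, 0.22, 0.26,
    0.30, 0.24, 0.18, 0.28,
    0.26, 0.22, 0.24, 0.28,
    0.30, 0.20, 0.22, 0.28), nrow = 4, byrow = TRUE,
    dimnames = list(BASES, BASES))
  m / rowSums(m)
})

markov_seq <- function(n, trans = MARKOV_TRANS) {
  cum <- t(apply(trans, 1L, cumsum))
  u <- runif(n)
  out <- integer(n)
  out[1L] <- sample.int(4L, 1L)
  for (i in 2:n) {
    out[i] <- findInterval(u[i], cum[out[i - 1L], ]) + 1L
  }
  paste0(BASES[out], collapse = "")
}

## open reading frame with biased codon usage (ATG ... stop, length in nt
## divisible by 3, stop included)
random_orf <- function(n_nt) {
  n_codons <- max(2L, round(n_nt / 3)) - 2L
  body <- sample_vec(names(CODON_WEIGHTS), n_codons, replace = TRUE,
                     prob = CODON_WEIGHTS)
  paste0("ATG", paste0(body, collapse = ""), sample_vec(STOP_CODONS, 1L))
}

## an 11-mer carrying a stop codon in all three reading frames (at
## offsets 0, 4 and 8), so stamping it anywhere interrupts every frame
STOP_MOTIF <- "TAAATAAATAA"

## destroy every ORF >= max_orf nt by stamping the all-frame stop motif
## into its middle; each stamp splits the current longest ORF whatever
## its frame, so the loop always terminates
kill_orfs <- function(seq, max_orf = 149L,
                      max_iter = 60L + nchar(seq) %/% 50L) {
  for (i in seq_len(max_iter)) {
    o <- longest_orf(seq)
    if (o$orf_length <= max_orf) return(seq)
    mid <- o$start + o$orf_length %/% 2L
    mid <- min(mid, nchar(seq) - nchar(STOP_MOTIF))
    substr(seq, mid + 1L, mid + nchar(STOP_MOTIF)) <- STOP_MOTIF
  }
  stopf("could not remove all long ORFs after %d iterations", max_iter)
}

## point substitutions at the given per-base rate (homolog divergence)
mutate_seq <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample_vec(setdiff(BASES, ch[i]), 1L)
  paste0(ch, collapse = "")
}

## reserve a window of `width` inside a transcript, avoiding previously
## reserved intervals; returns the 1-based start, or errors after
## `max_try` collisions
place_window <- function(len, width, reserved, max_try = 50L) {
  if (len < width) stopf("transcript too short for a %d-nt window", width)
  for (i in seq_len(max_try)) {
    s <- sample.int(len - width + 1L, 1L)
    e <- s + width - 1L
    clash <- any(vapply(reserved, function(iv) s <= iv[2L] && e >= iv[1L],
                        logical(1)))
    if (!clash) return(s)
  }
  stopf("site placement collision persisted after %d tries", max_try)
}
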