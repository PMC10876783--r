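## RNA/RNA dinucleotide stack free energies (kcal/mol, 37 C). Watson-Crick
## stacks from Xia et al. (1998) Biochemistry 37:14719 nearest-neighbour
## parameters; G:U wobble stacks from Mathews et al. (1999) JMB 288:911
## (representative values). Sequences are handled in the DNA alphabet, so
## U appears as T: pairs are A:T, C:G and the G:T wobble.

## key: four bases "ab|cd" = 5'-ab-3' on one strand stacked on the
## antiparallel partner bases c (pairs a) and d (pairs b), read as the
## partner of a followed by the partner of b.
rna_stack_table <- function() {
  wc <- c(
    "AA|TT" = -0.93, "AT|TA" = -1.10, "TA|AT" = -1.33,
    "CT|GA" = -2.08, "CA|GT" = -2.11, "GT|CA" = -2.24,
    "GA|CT" = -2.35, "CG|GC" = -2.36, "GG|CC" = -3.26,
    "GC|CG" = -3.42, "TT|AA" = -0.93, "TG|AC" = -2.11,
    "TC|AG" = -2.35, "AG|TC" = -2.08, "AC|TG" = -2.24,
    "CC|GG" = -3.26)
  gu <- c(
    ## one or both pairs wobble (G:T); Mathews et al. (1999) Table 4
    "AG|TT" = -0.55, "AT|TG" = -1.36, "CG|GT" = -1.41, "CT|GG" = -2.11,
    "GG|CT" = -1.53, "GT|CG" = -2.51, "TG|AT" = -1.27, "TT|AG" = -1.00,
    "GA|TT" = -1.27, "GC|TG" = -2.51, "GG|TC" = -2.11, "GT|TA" = -1.36,
    "TA|GT" = -1.00, "TC|GG" = -1.53, "TG|GC" = -1.41, "TT|GA" = -0.55,
    "GG|TT" = -0.50, "GT|TG" = +0.47, "TG|GT" = -0.57, "TT|GG" = -0.50)
  c(wc, gu)
}

NDG_STACKS <- rna_stack_table()

## can base a (on the short strand) pair with base b (on the long strand)?
## Watson-Crick or G:T wobble, DNA alphabet.
base_pairs_ok <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

## 16 x 16 matrix: row = short-strand dinucleotide (a1, a2), column =
## long-strand descending dinucleotide (b1, b2) where b1 faces a1
ndg_stack_mat <- function(stacks) {
  m <- matrix(0, 16L, 16L)
  for (key in names(stacks)) {
    a1 <- match(substr(key, 1, 1), BASES)
    a2 <- match(substr(key, 2, 2), BASES)
    b1 <- match(substr(key, 4, 4), BASES)
    b2 <- match(substr(key, 5, 5), BASES)
    m[(a1 - 1L) * 4L + a2, (b1 - 1L) * 4L + b2] <- stacks[[key]]
  }
  m
}
NDG_STACK_MAT <- ndg_stack_mat(NDG_STACKS)

seq_codes <- function(x) match(seq_chars(x), BASES)

#' Normalized RNA-RNA hybridization free energy (ndG)
#'
#' Slides the shorter sequence along the longer at every full-overlap
#' offset, pairing the two strands antiparallel without gaps. At each
#' offset the duplex energy is the sum of nearest-neighbour stack energies
#' over runs of consecutive paired positions (Watson-Crick and G:U
#' allowed; a mismatch breaks the stack run). dG is the minimum offset
#' energy and ndG = dG / L with L the length of the shorter sequence, so
#' more negative means stronger predicted binding. A duplex with no
#' possible pairs scores 0.
#'
#' @param lncrna_seq,target_seq DNA strings (>= 20 nt).
#' @param stacks stack energy table (kcal/mol).
#' @return numeric ndG (kcal/mol per nt).
#' @export
ndg_score <- function(lncrna_seq, target_seq, stacks = NDG_STACKS) {
  a <- normalize_seq(lncrna_seq)
  b <- normalize_seq(target_seq)
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stopf("ndG: sequences must be over ACGT after normalization")
  if (nchar(a) < 20L || nchar(b) < 20L)
    stopf("ndG: both sequences must be >= 20 nt")
  if (nchar(a) <= nchar(b)) {
    s <- seq_codes(a); l <- seq_codes(b)
  } else {
    s <- seq_codes(b); l <- seq_codes(a)
  }
  L <- length(s)
  if (L < 2L) return(0)
  n <- length(l)
  n_off <- n - L + 1L
  emat <- if (identical(stacks, NDG_STACKS)) NDG_STACK_MAT else
    ndg_stack_mat(stacks)
  ## position i of the short strand (5'->3', antiparallel, ungapped)
  ## pairs long-strand position o + L - i at 1-based offset o; the stack
  ## between short positions (i, i+1) reads long positions
  ## (o+L-i, o+L-i-1). The per-offset energy
  ##   E(o) = sum_i W[ds(i), dl(o+L-i)]
  ## is a convolution over the 16 short-strand dinucleotide channels,
  ## with dl(j) the descending long-strand dinucleotide (l[j], l[j-1]);
  ## the stack table is zero wherever either face is unpaired, so runs
  ## broken by mismatches contribute nothing.
  ds <- (s[-L] - 1L) * 4L + s[-1L]          # i = 1..L-1
  dl <- c(1L, (l[-1L] - 1L) * 4L + l[-n])   # j = 2..n at index j
  nfft <- stats::nextn(L + n - 2L)
  acc <- complex(nfft)
  for (a_ch in unique(ds)) {
    m <- emat[a_ch, dl]
    m[1L] <- 0                               # dl undefined at j = 1
    if (all(m == 0)) next
    u <- as.numeric(ds == a_ch)
    acc <- acc + stats::fft(c(u, numeric(nfft - length(u)))) *
      stats::fft(c(m, numeric(nfft - length(m))))
  }
  energies <- Re(stats::fft(acc, inverse = TRUE)) / nfft
  ## E(o) = (u * m)[o + L - 1]
  off_e <- energies[(L:(L + n_off - 1L))]
  dg <- min(c(off_e, 0))
  dg / L
}
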