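## Independent brute-force oracles. These deliberately reimplement the
## contracts in the most naive way possible and share no code with the
## package internals.

## Benjamini-Hochberg step-up by definition: q_i = min_{j >= rank(i)}
## p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(adj[i:m]))
  q
}

## longest ORF by stepping codon-by-codon from every ATG
oracle_orf <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in seq_len(max(0L, n - 5L))) {
    if (!(ch[s] == "A" && ch[s + 1] == "T" && ch[s + 2] == "G")) next
    p <- s
    while (p + 5L <= n) {
      p <- p + 3L
      cod <- paste0(ch[p], ch[p + 1], ch[p + 2])
      if (cod %in% stops) {
        best <- max(best, p + 2L - s + 1L)
        break
      }
    }
  }
  best
}

## plant miRNA penalty by enumerating every register and bulge position;
## per-register penalties computed straight from the rule table
oracle_plant_score <- function(mirna, target) {
  mi <- strsplit(mirna, "")[[1]]
  tg <- strsplit(target, "")[[1]]
  k <- length(mi); n <- length(tg)
  if (n < k) return(NULL)
  pens <- function(faced) {
    duo <- paste0(mi, faced)
    p <- ifelse(duo %in% c("AT", "TA", "CG", "GC"), 0,
                ifelse(duo %in% c("GT", "TG"), 0.5, 1))
    p * ifelse(seq_len(k) %in% 2:13, 2, 1)
  }
  best <- Inf
  for (o in 0:(n - k)) {
    best <- min(best, sum(pens(rev(tg[(o + 1):(o + k)]))))
  }
  if (n >= k + 1) {
    for (o in 0:(n - k - 1)) {
      rsite <- rev(tg[(o + 1):(o + k + 1)])
      for (j in 1:(k - 1)) {
        faced <- c(rsite[seq_len(j)], rsite[(j + 2):(k + 1)])
        sc <- sum(pens(faced)) + (if ((j + 1) %in% 2:13) 2 else 1)
        best <- min(best, sc)
      }
    }
  }
  best
}

## ndG by explicit per-offset loops over the stack table
oracle_ndg <- function(a, b, stacks = pollenlnc:::NDG_STACKS) {
  if (nchar(a) <= nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
  sc <- strsplit(s, "")[[1]]; lc <- strsplit(l, "")[[1]]
  L <- length(sc); n <- length(lc)
  can_pair <- function(x, y) paste0(x, y) %in%
    c("AT", "TA", "CG", "GC", "GT", "TG")
  best <- 0
  for (o in 1:(n - L + 1)) {
    e <- 0
    for (i in 1:(L - 1)) {
      p1 <- o + L - i
      if (can_pair(sc[i], lc[p1]) && can_pair(sc[i + 1], lc[p1 - 1])) {
        key <- paste0(sc[i], sc[i + 1], "|", lc[p1], lc[p1 - 1])
        if (!is.na(stacks[key])) e <- e + stacks[[key]]
      }
    }
    if (e < best) best <- e
  }
  best / L
}

## hypergeometric upper-tail by pmf summation
oracle_hyper_tail <- function(x, m, n, k) {
  xs <- x:min(m, k)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
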