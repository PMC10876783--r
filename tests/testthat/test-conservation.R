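test_that("the aligner finds identical sequences and misses unrelated ones", {
  set.seed(71)
  s <- random_dna(600)
  hits <- homology_search(c(q = s), c(subj = s))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$alignment_length, 600)
  expect_lt(hits$evalue, 1e-50)
  ## sequences sharing no 11-mer produce nothing
  h2 <- homology_search(c(q = strrep("AC", 100)), c(s = strrep("GT", 100)))
  expect_equal(nrow(h2), 0)
  expect_equal(nrow(homology_search(character(0), c(s = s))), 0)
})

test_that("internal aligner identity tracks blastn within 5 points", {
  ## panel regenerated deterministically; blastn identities recorded once
  ## from blast 2.17.0 in tests/testthat/blastn_panel.tsv
  set.seed(424)
  qs <- character(0); ss <- character(0)
  for (i in 1:20) {
    rate <- runif(1, 0.02, 0.30)
    q <- pollenlnc:::markov_seq(sample(600:1500, 1))
    qs[sprintf("q%02d", i)] <- q
    ss[sprintf("s%02d", i)] <- pollenlnc:::mutate_seq(q, rate)
  }
  fix <- read.delim(test_path("blastn_panel.tsv"))
  for (i in seq_len(nrow(fix))) {
    h <- homology_search(qs[fix$query_id[i]], ss[fix$subject_id[i]])
    h <- h[which.max(h$bit_score), ]
    expect_lt(abs(h$percent_identity - fix$percent_identity[i]), 5)
  }
})

test_that("conservation thresholds are strict on E and inclusive on the rest", {
  mk <- function(pident, len, evalue) data.frame(
    query_id = "q", subject_id = "s", percent_identity = pident,
    alignment_length = len, mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = len, s_start = 1, s_end = len,
    evalue = evalue, bit_score = 50, stringsAsFactors = FALSE)
  lens <- c(q = 1000, s = 2000)
  ## all thresholds passed
  expect_true(call_conservation(mk(65, 350, 1e-6), lens, lens)$conserved)
  ## E-value rule is strict: high identity cannot rescue a weak E
  expect_false(call_conservation(mk(90, 900, 1e-4), lens, lens)$conserved)
  ## boundaries inclusive: exactly 60% identity over exactly 30%
  expect_true(call_conservation(mk(60, 300, 1e-6), lens, lens)$conserved)
  expect_false(call_conservation(mk(59.9, 300, 1e-6), lens, lens)$conserved)
  expect_false(call_conservation(mk(60, 299, 1e-6), lens, lens)$conserved)
  expect_error(call_conservation(mk(60, 300, 1e-6), c(x = 1), lens),
               "unknown")
})

test_that("conservation calls are monotone in identity, coverage and E", {
  set.seed(72)
  lens <- c(q = 1000, s = 1000)
  mk <- function(pident, len, evalue) data.frame(
    query_id = "q", subject_id = "s", percent_identity = pident,
    alignment_length = len, mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = len, s_start = 1, s_end = len,
    evalue = evalue, bit_score = 50, stringsAsFactors = FALSE)
  for (i in 1:50) {
    pid <- runif(1, 40, 100); len <- sample(100:1000, 1)
    ev <- 10^runif(1, -20, 0)
    base <- call_conservation(mk(pid, len, ev), lens, lens)$conserved
    better <- call_conservation(mk(min(100, pid + 10),
                                   min(1000, len + 100), ev / 10),
                                lens, lens)$conserved
    expect_true(!base || better)
  }
})

test_that("E-value decreases with alignment score at fixed search space", {
  set.seed(73)
  q <- random_dna(500)
  near <- pollenlnc:::mutate_seq(q, 0.02)
  far <- pollenlnc:::mutate_seq(q, 0.2)
  h <- homology_search(c(q = q), c(near = near, far = far))
  expect_equal(nrow(h), 2)
  hn <- h[h$subject_id == "near", ]; hf <- h[h$subject_id == "far", ]
  expect_gt(hn$bit_score, hf$bit_score)
  expect_lt(hn$evalue, hf$evalue)
})

test_that("sub-genome assignment and planted pair recovery", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  lnc_tx <- paste0(sim$lnc_loci$gene_id, ".1")
  seqs <- setNames(sim$seqs[lnc_tx], sim$lnc_loci$gene_id)
  loci <- data.frame(gene_id = sim$lnc_loci$gene_id,
                     chrom = sim$lnc_loci$chrom, stringsAsFactors = FALSE)
  sub <- subgenome_conservation(loci, seqs)
  ## "U" scaffolds are excluded
  expect_setequal(sub$excluded,
                  loci$gene_id[loci$chrom == "U"])
  ## every planted pair is counted in the right sub-genome overlap
  sub_of <- function(id) substr(loci$chrom[loci$gene_id == id],
                                nchar(loci$chrom[loci$gene_id == id]),
                                nchar(loci$chrom[loci$gene_id == id]))
  own <- setNames(vapply(loci$gene_id, sub_of, character(1)),
                  loci$gene_id)
  for (i in seq_len(nrow(gt$subgenome_pairs))) {
    a <- gt$subgenome_pairs$a[i]; b <- gt$subgenome_pairs$b[i]
    expect_true(own[[b]] %in% sub$membership[[a]] ||
                  own[[a]] %in% sub$membership[[b]],
                info = paste(a, b))
  }
})

test_that("NJ recovers the additive four-taxon topology", {
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- nj_from_dist(d)
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_from_dist(d)
  ## a = (dAB + dAC - dBC) / 2, etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(bl["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(bl["C"]), (5 + 6 - 3) / 2)
})

test_that("NJ on ultrametric distances recovers the generating topology", {
  set.seed(74)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    ref <- ape::rcoal(n, tip.label = paste0("t", 1:n))
    d <- ape::cophenetic.phylo(ref)
    tr <- nj_from_dist(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  set.seed(75)
  anc <- random_dna(400)
  seqs <- c(wheat = anc,
            sp1 = pollenlnc:::mutate_seq(anc, 0.05),
            sp2 = pollenlnc:::mutate_seq(anc, 0.10),
            sp3 = pollenlnc:::mutate_seq(anc, 0.20),
            sp4 = pollenlnc:::mutate_seq(anc, 0.30))
  r1 <- nj_tree(seqs, bootstrap = 50, seed = 9)
  r2 <- nj_tree(seqs, bootstrap = 50, seed = 9)
  expect_equal(r1$support, r2$support)
  expect_equal(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  ## the root label carries no bipartition, hence may be NA
  expect_true(all(r1$support >= 0 & r1$support <= 100, na.rm = TRUE))
  expect_error(nj_tree(seqs[1:2]), ">= 3")
})
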