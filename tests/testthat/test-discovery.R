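test_that("candidate selection keeps exactly the i/o/u/x class codes", {
  mk <- function(codes) transcript_set(data.frame(
    transcript_id = paste0("t", seq_along(codes)),
    gene_id = paste0("g", seq_along(codes)),
    chrom = "1A", start = 0, end = 300, strand = "+",
    class_code = codes,
    exon_starts = I(as.list(rep(0, length(codes)))),
    exon_ends = I(as.list(rep(300, length(codes)))),
    stringsAsFactors = FALSE))
  ts <- mk(c("=", "u", "x", "i", "o", "j", "c"))
  expect_setequal(select_candidates(ts)$class_code, c("u", "x", "i", "o"))
  expect_equal(nrow(select_candidates(mk(c("=", "=", "=")))), 0)
  expect_equal(nrow(select_candidates(ts[0, ])), 0)
})

test_that("length filter removes below 200 nt, strict on the removal side", {
  ts <- transcript_set(data.frame(
    transcript_id = c("short", "exact", "long"),
    gene_id = c("g1", "g2", "g3"), chrom = "1A",
    start = 0, end = c(199, 200, 2400), strand = "+", class_code = "u",
    exon_starts = I(list(0, 0, 0)), exon_ends = I(list(199, 200, 2400)),
    stringsAsFactors = FALSE))
  kept <- length_filter(ts)$transcript_id
  expect_false("short" %in% kept)
  expect_true(all(c("exact", "long") %in% kept))
})

test_that("longest ORF scan matches the codon-stepping oracle", {
  o <- longest_orf("ATGAAATAG")
  expect_equal(o$orf_length, 9)
  expect_equal(o$orf_coverage, 1)
  expect_equal(longest_orf("CCCCCC")$orf_length, 0)
  set.seed(201)
  for (i in 1:25) {
    s <- random_dna(sample(100:600, 1))
    expect_equal(longest_orf(s)$orf_length, oracle_orf(s), info = s)
  }
})

test_that("Fickett position parameters match direct phase counting", {
  s <- "ACGTACGTACGTACGTACGTACGT"   # period-4 repeat over 24 nt
  p <- fickett_position_params(s)
  ## by hand: each base occupies each phase exactly 2 times -> 2/(2+1)
  expect_equal(unname(p), rep(2 / 3, 4))
  s2 <- strrep("ATG", 10)
  p2 <- fickett_position_params(s2)
  expect_equal(unname(p2["A"]), 10 / 1)   # all A in phase 0
  expect_identical(fickett_score(s2), fickett_score(s2))
})

test_that("Fickett separates codon-biased ORFs from shuffled sequence", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  coding <- sim$seqs[head(gt$coding_ids, 40)]
  nc <- sim$seqs[head(gt$noncoding_ids, 40)]
  expect_gt(mean(vapply(coding, fickett_score, numeric(1))),
            mean(vapply(nc, fickett_score, numeric(1))))
})

test_that("hexamer score is 0 without an ORF and 0 under uniform tables", {
  uni <- list(coding = setNames(rep(1 / 4096, 4096),
                                pollenlnc:::all_hexamers()),
              noncoding = setNames(rep(1 / 4096, 4096),
                                   pollenlnc:::all_hexamers()))
  expect_equal(hexamer_score("CCCCCCCCCC", uni), 0)   # no ORF
  expect_equal(hexamer_score("ATGAAACCCGGGTTTACGTGA", uni), 0)
})

test_that("trained hexamer tables separate the planted classes", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  tables <- train_hexamer_tables(sim$seqs[head(gt$coding_ids, 40)],
                                 sim$seqs[head(gt$noncoding_ids, 40)])
  hc <- vapply(sim$seqs[head(gt$coding_ids, 30)], hexamer_score,
               numeric(1), tables = tables)
  hn <- vapply(sim$seqs[head(gt$noncoding_ids, 30)], hexamer_score,
               numeric(1), tables = tables)
  expect_gt(mean(hc), 0)
  expect_lt(mean(hn), 0)
})

test_that("coding model honours fixed cutoffs and the two-graph ROC", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  tables <- train_hexamer_tables(sim$seqs[gt$coding_ids],
                                 sim$seqs[gt$noncoding_ids])
  set.seed(88)
  n_cod <- min(60, length(gt$coding_ids))
  nc_seqs <- sim$seqs[gt$noncoding_ids]
  ## pad the non-coding class with composition-preserving shuffles
  while (length(nc_seqs) < n_cod) {
    s <- sample(gt$coding_ids, 1)
    nc_seqs[paste0("shuf_", length(nc_seqs))] <- paste0(
      sample(strsplit(sim$seqs[[s]], "")[[1]]), collapse = "")
  }
  seqs <- c(sim$seqs[head(gt$coding_ids, n_cod)], head(nc_seqs, n_cod))
  feat <- coding_features(seqs, tables)
  labels <- rep(c(1, 0), c(n_cod, n_cod))
  m <- fit_coding_model(feat, labels)
  prob <- coding_probability(m, feat)
  sens <- mean(prob[labels == 1] >= m$cutoff)
  spec <- mean(prob[labels == 0] < m$cutoff)
  expect_lt(abs(sens - spec), 0.05)
  ## perfectly separated training data is classified perfectly
  expect_equal(mean((prob >= m$cutoff) == (labels == 1)), 1)
  m2 <- fit_coding_model(feat, labels, fixed_cutoff = 0.365)
  expect_equal(m2$cutoff, 0.365)
  expect_error(fit_coding_model(feat, rep(1, nrow(feat))), "both classes")
  few <- c(1:30, n_cod + 1:30)
  expect_error(fit_coding_model(feat[few, ], labels[few]), ">= 50")
})

test_that("the cascade is non-increasing and drop counts are consistent", {
  run <- small_discovery()
  sc <- run$stage_counts
  expect_true(all(diff(sc) <= 0))
  ## the three-way intersection contains the retained set
  expect_gte(run$venn[["all_three"]], sc[["domain_veto"]])
  expect_equal(sum(run$venn), sc[["length"]])
})

test_that("consensus requires all three scorers to call non-coding", {
  run <- small_discovery()
  rep <- run$report
  all_nc <- rep$call_logistic == "noncoding" &
    rep$call_orf_rule == "noncoding" & rep$call_hexamer == "noncoding"
  expect_equal(rep$consensus == "noncoding", all_nc)
  ## anything called non-coding by only two scorers is dropped
  two_of_three <- !all_nc &
    (rep$call_logistic == "noncoding") + (rep$call_orf_rule == "noncoding") +
    (rep$call_hexamer == "noncoding") == 2
  expect_false(any(rep$transcript_id[two_of_three] %in% run$retained))
})

test_that("the domain veto removes exactly the planted domain carriers", {
  sim <- small_corpus()
  run <- small_discovery()
  expect_setequal(run$removed_by_veto, sim$ground_truth$domain_planted)
})

test_that("domain veto keeps ORF-less transcripts and removes exact copies", {
  db <- c(p1 = "MKLVNWQRSTAPGHEDCYFMKLVNWQRSTAPGHEDCYF")
  orf_nt <- paste0("ATG", paste(rep("AAA", 50), collapse = ""), "TAA")
  ## transcript whose ORF translates to a DB protein
  orf_match <- paste0("ATG",
    paste(c("AAA", "CTT", "GTT", "AAT", "TGG", "CAA", "AGA", "TCT",
            "ACT", "GCT", "CCT", "GGT", "CAT", "GAA", "GAT", "TGT",
            "TAT", "TTT", "ATG", "AAA", "CTT", "GTT", "AAT", "TGG",
            "CAA", "AGA", "TCT", "ACT", "GCT", "CCT", "GGT", "CAT",
            "GAA", "GAT", "TGT", "TAT", "TTT"), collapse = ""), "TAA")
  seqs <- c(hit = paste0("CCGTCC", orf_match, "CCGTAA"),
            noorf = strrep("C", 300),
            other = paste0("CCGTCC", orf_nt, "CCGTAA"))
  res <- domain_veto(names(seqs), seqs, db)
  expect_true("hit" %in% res$removed)
  expect_true(all(c("noorf", "other") %in% res$kept))
  res2 <- domain_veto(names(seqs), seqs, db,
                      external_hits = c("noorf", "absent"))
  expect_equal(res2$removed, "noorf")
})
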