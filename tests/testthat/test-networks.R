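test_that("cis windows return 10 genes either side in genomic order", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:25), chrom = "1A",
                      start = seq(0, by = 10000, length.out = 25),
                      end = seq(2000, by = 10000, length.out = 25),
                      stringsAsFactors = FALSE)
  ## lncRNA between genes 12 and 13
  lnc <- list(chrom = "1A", start = 113000, end = 114000)
  win <- cis_window(lnc, genes, k = 10)
  expect_setequal(win$gene_id, sprintf("g%02d", 3:22))
  expect_equal(sum(win$side == "upstream"), 10)
  expect_equal(sum(win$side == "downstream"), 10)
  expect_true(all(win$distance_bp[win$side == "upstream"] <= 0))
  ## lncRNA before the first gene: 10 genes, all downstream
  win2 <- cis_window(list(chrom = "1A", start = -5000, end = -4000),
                     genes, k = 10)
  expect_equal(nrow(win2), 10)
  expect_true(all(win2$side == "downstream"))
  ## overlapping gene at distance 0
  win3 <- cis_window(list(chrom = "1A", start = 500, end = 1500), genes)
  expect_equal(win3$distance_bp[win3$gene_id == "g01"], 0)
  ## chromosome with no coding genes
  expect_equal(nrow(cis_window(list(chrom = "9Z", start = 0, end = 1),
                               genes)), 0)
})

test_that("Pearson test matches cor.test and handles exact correlation", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, x)$p, 0)
  expect_equal(pearson_test(x, -x)$r, -1)
  expect_null(pearson_test(x, rep(2, 6)))
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(length(a))
    got <- pearson_test(a, b)
    ref <- cor.test(a, b)
    expect_equal(got$r, unname(ref$estimate))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("|r| = 0.81 is the p < 0.05 boundary at n = 6", {
  set.seed(42)
  x <- rnorm(6)
  y_hi <- pair_with_r(x, 0.812)
  y_lo <- pair_with_r(x, 0.80)
  expect_lt(pearson_test(x, y_hi)$p, 0.05)
  expect_gt(pearson_test(x, y_lo)$p, 0.05)
  expect_equal(critical_r(6), 0.8114, tolerance = 5e-4)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(43)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.1, 1.4)), "outside")
})

test_that("ndG equals brute-force offset enumeration", {
  set.seed(44)
  for (i in 1:20) {
    a <- random_dna(sample(20:50, 1))
    b <- random_dna(sample(50:110, 1))
    expect_equal(ndg_score(a, b), oracle_ndg(a, b), tolerance = 1e-8)
  }
})

test_that("ndG extremes: perfect duplex is minimal, no pairing is zero", {
  set.seed(45)
  a <- random_dna(40)
  perfect <- ndg_score(a, revcomp(a))
  expect_equal(perfect, oracle_ndg(a, revcomp(a)), tolerance = 1e-8)
  ## perturbing the duplex can only weaken it
  b <- revcomp(a)
  substr(b, 20, 20) <- chartr("ACGT", "CAAC", substr(b, 20, 20))
  expect_gte(ndg_score(a, b), perfect)
  expect_equal(ndg_score(strrep("A", 30), strrep("A", 60)), 0)
  ## symmetric in argument order
  c2 <- random_dna(80)
  expect_equal(ndg_score(a, c2), ndg_score(c2, a))
  expect_error(ndg_score("ACGTN", strrep("A", 30)), "ACGT")
  expect_error(ndg_score("ACGT", strrep("A", 30)), ">= 20")
})

test_that("all Watson-Crick stacks carry negative energy", {
  st <- pollenlnc:::NDG_STACKS
  wc <- names(st)[!grepl("(G.\\|T)|(T.\\|G)|(.G\\|.T)|(.T\\|.G)", names(st))]
  ## filter to stacks whose both faces are Watson-Crick pairs
  is_wc_pair <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  both_wc <- vapply(names(st), function(k) {
    is_wc_pair(substr(k, 1, 1), substr(k, 4, 4)) &&
      is_wc_pair(substr(k, 2, 2), substr(k, 5, 5))
  }, logical(1))
  expect_true(all(st[both_wc] < 0))
})

test_that("cis and trans edge sets are disjoint and respect the ndG cutoff", {
  sim <- small_corpus()
  em <- small_expression()
  counts <- aggregate_to_locus(sim$counts, sim$tx2gene)
  bt <- setNames(sim$biotype[rownames(em$counts)], rownames(em$counts))
  r <- noiseq_de(em, "wk", "meiosis", biotype = bt)
  rl <- r[r$biotype == "lncRNA", ]
  locus_seq <- sim$seqs
  names(locus_seq) <- sim$tx2gene[names(locus_seq)]
  locus_seq <- locus_seq[!duplicated(names(locus_seq))]
  edges <- build_cis_trans(rl, sim$lnc_loci, sim$gene_loci, em,
                           seqs = locus_seq)
  key <- paste(edges$lncrna_id, edges$gene_id)
  expect_equal(anyDuplicated(paste(key, edges$mode)), 0)
  cis_keys <- key[edges$mode == "cis"]
  trans_keys <- key[edges$mode == "trans"]
  expect_length(intersect(cis_keys, trans_keys), 0)
  ## every retained trans edge passed the hybridization filter
  expect_true(all(edges$ndg[edges$mode == "trans"] <= -0.15))
  expect_true(all(edges$p[edges$mode == "cis"] < 0.05))
  expect_true(all(edges$q[edges$mode == "trans"] < 0.05, na.rm = TRUE))
})

test_that("a correlated non-neighbour without hybridization is excluded", {
  ## two loci with engineered perfect co-expression on different
  ## chromosomes: kept only when their sequences hybridize
  d <- expand.grid(replicate = 1:3, condition = c("control", "heat"),
                   stage = "meiosis", cultivar = "cr",
                   stringsAsFactors = FALSE)
  d$sample <- paste0("s", 1:6)
  set.seed(46)
  shared <- round(2^rnorm(6, 8, 1))
  counts <- rbind(LNCx = shared, GENEy = shared + 3,
                  matrix(rnbinom(40 * 6, mu = 100, size = 10), ncol = 6,
                         dimnames = list(paste0("bg", 1:40), NULL)))
  colnames(counts) <- d$sample
  em <- tmm_normalize(expression_matrix(counts, d))
  lnc_loci <- data.frame(gene_id = "LNCx", chrom = "1A", start = 0,
                         end = 1000, stringsAsFactors = FALSE)
  gene_loci <- data.frame(gene_id = c("GENEy", paste0("bg", 1:40)),
                          chrom = "2B",
                          start = seq(0, by = 5000, length.out = 41),
                          end = seq(1000, by = 5000, length.out = 41),
                          stringsAsFactors = FALSE)
  de <- data.frame(gene_id = "LNCx", cultivar = "cr", stage = "meiosis",
                   log2fc = 1, d_stat = 1, de_probability = 1,
                   p_value = 0.001, fdr = 0.001, direction = "up",
                   biotype = "lncRNA", stringsAsFactors = FALSE)
  lseq <- random_dna(500)
  ## no hybridization: poly-purine lncRNA vs poly-purine gene
  seqs_no <- c(LNCx = strrep("AG", 250), GENEy = strrep("GA", 400))
  e1 <- build_cis_trans(de, lnc_loci, gene_loci, em, seqs = seqs_no)
  expect_false(any(e1$gene_id == "GENEy"))
  ## with a planted antisense segment the same edge is retained
  gseq <- random_dna(800)
  lseq2 <- paste0(substr(lseq, 1, 200), revcomp(substr(gseq, 200, 500)),
                  substr(lseq, 201, 400))
  e2 <- build_cis_trans(de, lnc_loci, gene_loci, em,
                        seqs = c(LNCx = lseq2, GENEy = gseq))
  expect_true(any(e2$gene_id == "GENEy" & e2$mode == "trans"))
})
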