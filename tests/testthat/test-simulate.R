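test_that("the corpus is a deterministic function of the config", {
  cfg <- small_config(seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ground_truth$de_table, b$ground_truth$de_table)
  expect_identical(a$mirnas, b$mirnas)
})

test_that("config validation rejects infeasible settings", {
  expect_error(simulation_config(de_log2fc_range = c(0.3, 2)),
               "above 0.5")
  expect_error(simulation_config(class_code_fractions =
                                   c(i = 0.5, o = 0.5, u = 0.5, x = 0)),
               "sum to 1")
  expect_error(simulation_config(de_fraction = 1.4), "\\[0, 1\\]")
  ## more planted roles than loci
  expect_error(simulate_genome(simulation_config(
    n_lncrna_loci = 10, n_sponge = 5, n_precursor = 5, n_cis_pairs = 5,
    n_trans_pairs = 5, n_subgenome_pairs = 3)), "exhausted")
})

test_that("class-code fractions are honoured at the extremes", {
  cfg <- simulation_config(seed = 3, n_coding_genes = 20,
                           n_lncrna_loci = 15, n_sponge = 2,
                           n_precursor = 1, n_cis_pairs = 2,
                           n_trans_pairs = 1, n_subgenome_pairs = 1,
                           n_domain_planted = 1, n_nonconserved = 1,
                           class_code_fractions =
                             c(i = 0, o = 0, u = 1, x = 0))
  sim <- simulate_genome(cfg)
  lnc <- sim$transcripts[startsWith(sim$transcripts$gene_id, "LNC"), ]
  expect_true(all(lnc$class_code == "u"))
})

test_that("planted coding ORFs and non-coding ORF limits hold", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  orf <- function(id) longest_orf(sim$seqs[[id]])$orf_length
  coding_orfs <- vapply(head(gt$coding_ids, 30), orf, numeric(1))
  expect_true(all(coding_orfs >= 300))
  ## sequence lengths centre near the configured means
  lnc_len <- nchar(sim$seqs[paste0(sim$lnc_loci$gene_id, ".1")])
  cod_len <- nchar(sim$seqs[paste0(sim$gene_loci$gene_id, ".1")])
  expect_gt(mean(cod_len), mean(lnc_len))
  expect_equal(mean(lnc_len), sim$config$lnc_mean_len, tolerance = 0.25)
  expect_equal(mean(cod_len), sim$config$coding_mean_len, tolerance = 0.25)
})

test_that("planted fold changes are recovered by direct NB sampling", {
  ## two-condition design with many replicates: the empirical log2 fold
  ## change of a planted lfc = 2 gene lands within +/- 0.3
  cfg <- simulation_config(seed = 5, n_coding_genes = 20,
                           n_lncrna_loci = 15, n_sponge = 2,
                           n_precursor = 1, n_cis_pairs = 2,
                           n_trans_pairs = 1, n_subgenome_pairs = 1,
                           n_domain_planted = 1, n_nonconserved = 1,
                           replicates = 200, cultivars = "cr",
                           stages = "meiosis",
                           de_log2fc_range = c(1.999, 2.001))
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth
  counts <- aggregate_to_locus(sim$counts, sim$tx2gene)
  d <- sim$design
  for (i in seq_len(min(5, nrow(gt$de_table)))) {
    r <- gt$de_table[i, ]
    h <- counts[r$gene_id, d$sample[d$condition == "heat"]]
    c0 <- counts[r$gene_id, d$sample[d$condition == "control"]]
    lfc <- log2(mean(h) / mean(c0)) * (if (r$direction == "up") 1 else -1)
    expect_equal(lfc, 2, tolerance = 0.15)
  }
})

test_that("planted pairs correlate above the n = 6 threshold", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  counts <- aggregate_to_locus(sim$counts, sim$tx2gene)
  em <- tmm_normalize(expression_matrix(counts, sim$design))
  expr <- log2(cpm_matrix(em) + 1)
  d <- sim$design
  pairs <- rbind(gt$cis_pairs[, c("lncrna_id", "gene_id", "cultivar",
                                  "stage")],
                 setNames(gt$trans_pairs[, c("lncrna_id", "gene_id",
                                             "cultivar", "stage")],
                          c("lncrna_id", "gene_id", "cultivar", "stage")))
  rs <- vapply(seq_len(nrow(pairs)), function(i) {
    cols <- d$sample[d$cultivar == pairs$cultivar[i] &
                       d$stage == pairs$stage[i]]
    cor(expr[pairs$lncrna_id[i], cols], expr[pairs$gene_id[i], cols])
  }, numeric(1))
  expect_gte(mean(rs > 0.81), 0.75)
})

test_that("planted miRNA sites score as designed", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  ## precursor lncRNAs embed the exact complement: plant score 0
  for (i in seq_len(nrow(gt$precursor_triples))) {
    tr <- gt$precursor_triples[i, ]
    mid <- gt$mirnas$mirna_id[gt$mirnas$role == "precursor" &
                                gt$mirnas$lncrna_id == tr$lncrna_id][1]
    h <- plant_target_score(sim$mirnas[[mid]],
                            sim$seqs[[paste0(tr$lncrna_id, ".1")]])
    expect_equal(h$score, 0)
    expect_true(h$perfect)
  }
  ## sponge sites on lncRNA and mRNA both score at or below the cutoff
  for (i in seq_len(nrow(gt$sponge_triples))) {
    tr <- gt$sponge_triples[i, ]
    mid <- gt$mirnas$mirna_id[gt$mirnas$role == "sponge" &
                                gt$mirnas$lncrna_id == tr$lncrna_id][1]
    hl <- plant_target_score(sim$mirnas[[mid]],
                             sim$seqs[[paste0(tr$lncrna_id, ".1")]])
    hm <- plant_target_score(sim$mirnas[[mid]],
                             sim$seqs[[paste0(tr$mrna_id, ".1")]])
    expect_lte(hl$score, 4)
    expect_lte(hm$score, 4)
  }
})

test_that("homolog divergence matches the configured mutation rate", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  hm <- gt$homolog_map
  near <- hm[hm$rate < 0.3, ][1:4, ]
  for (i in seq_len(nrow(near))) {
    q <- sim$seqs[paste0(near$lncrna_id[i], ".1")]
    s <- sim$species_sets[[near$species[i]]][near$homolog_id[i]]
    h <- homology_search(q, s)
    h <- h[which.max(h$bit_score), ]
    ## identity ~ 90% +/- 3 at a 10% substitution rate
    expect_equal(h$percent_identity, 90, tolerance = 0.034)
  }
})

test_that("ground truth is internally consistent and on-disk complete", {
  sim <- small_corpus()
  gt <- sim$ground_truth
  ## sponge and precursor triples are disjoint
  sk <- paste(gt$sponge_triples$lncrna_id, gt$sponge_triples$mrna_id)
  pk <- paste(gt$precursor_triples$lncrna_id, gt$precursor_triples$mrna_id)
  expect_length(intersect(sk, pk), 0)
  ## every planted id exists among the emitted transcripts
  ids <- names(sim$seqs)
  expect_true(all(gt$noncoding_ids %in% ids))
  expect_true(all(gt$coding_ids %in% ids))
  expect_true(all(gt$domain_planted %in% ids))
  expect_true(all(paste0(gt$de_table$gene_id, ".1") %in% ids))
  expect_true(all(gt$homolog_map$lncrna_id %in% sim$lnc_loci$gene_id))
  ## written corpus carries every input the pipeline reads
  out <- tempfile("corpus")
  write_ok <- simulate_study(small_config(seed = 12), outdir = out)
  files <- c("annotation.gtf", "transcripts.fa", "counts.tsv",
             "design.tsv", "mirnas.fa", "proteins.fa", "gene2go.tsv",
             "ontology.obo")
  expect_true(all(file.exists(file.path(out, files))))
  expect_gt(length(list.files(file.path(out, "species"))), 0)
})
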