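test_that("perfect complements score 0 and are flagged perfect", {
  set.seed(51)
  mi <- random_dna(21)
  target <- paste0(random_dna(60), revcomp(mi), random_dna(60))
  h <- plant_target_score(mi, target)
  expect_equal(h$score, 0)
  expect_true(h$perfect)
  expect_true(h$hit)
  expect_equal(h$site_start, 61)
})

test_that("penalties follow the position-weighted plant rule", {
  set.seed(52)
  mi <- random_dna(21)
  site <- revcomp(mi)
  ## mismatch at miRNA position 10 (inside 2-13): site position 21-10+1
  s2 <- site
  sp <- 21 - 10 + 1
  old <- substr(s2, sp, sp)
  ## replace with a base that neither Watson-Crick- nor wobble-pairs
  mi10 <- substr(mi, 10, 10)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", mi10),
                   if (mi10 == "G") "T", if (mi10 == "T") "G"))[1]
  substr(s2, sp, sp) <- bad
  h2 <- plant_target_score(mi, paste0(strrep("C", 30), s2, strrep("C", 30)),
                           allow_bulge = FALSE)
  expect_equal(h2$score, 2)   # mismatch 1 doubled in positions 2-13
  ## G:U wobble at position 1: make miRNA position 1 a G facing a T
  mi3 <- mi
  substr(mi3, 1, 1) <- "G"
  s3 <- revcomp(mi3)
  substr(s3, 21, 21) <- "T"   # faces miRNA position 1
  h3 <- plant_target_score(mi3, paste0(strrep("C", 30), s3, strrep("C", 30)))
  expect_equal(h3$score, 0.5)
  expect_true(h3$hit)
  expect_false(h3$perfect)
})

test_that("targets shorter than the miRNA yield no hit", {
  expect_null(plant_target_score(random_dna(21), random_dna(15)))
  expect_error(plant_target_score(random_dna(10), random_dna(50)),
               "18-26")
})

test_that("the scanner equals brute-force register enumeration", {
  set.seed(53)
  for (i in 1:20) {
    mi <- random_dna(sample(18:24, 1))
    tg <- random_dna(200)
    got <- plant_target_score(mi, tg, max_score = Inf)
    expect_equal(got$score, oracle_plant_score(mi, tg), info = i)
  }
})

test_that("score 0 occurs only for full-length Watson-Crick duplexes", {
  set.seed(54)
  mi <- random_dna(21)
  site <- revcomp(mi)
  for (pos in c(1, 7, 14, 21)) {
    s <- site
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    h <- plant_target_score(mi, paste0(strrep("C", 25), s, strrep("C", 25)))
    expect_gt(h$score, 0)
    expect_false(h$perfect)
  }
})

test_that("module classification follows the trend rules", {
  hits <- function(rna, perfect, class) data.frame(
    mirna_id = "miRx", rna_id = rna, rna_class = class, score = 1,
    site_start = 1, site_end = 21, perfect = perfect,
    stringsAsFactors = FALSE)
  de <- function(gene, dir) data.frame(
    gene_id = gene, cultivar = "cr", stage = "meiosis", log2fc = 2,
    d_stat = 1, de_probability = 1, p_value = 0.001, fdr = 0.001,
    direction = dir, biotype = NA, stringsAsFactors = FALSE)
  ## concordant trends -> sponge
  m1 <- classify_modules(hits("lnc1", FALSE, "lncRNA"),
                         hits("mrna1", FALSE, "mRNA"),
                         rbind(de("lnc1", "up"), de("mrna1", "up")))
  expect_equal(m1$role, "sponge")
  ## opposite trends with perfect complementarity -> precursor
  m2 <- classify_modules(hits("lnc1", TRUE, "lncRNA"),
                         hits("mrna1", FALSE, "mRNA"),
                         rbind(de("lnc1", "up"), de("mrna1", "down")))
  expect_equal(m2$role, "precursor")
  ## opposite trends without perfect complementarity -> nothing
  m3 <- classify_modules(hits("lnc1", FALSE, "lncRNA"),
                         hits("mrna1", FALSE, "mRNA"),
                         rbind(de("lnc1", "up"), de("mrna1", "down")))
  expect_equal(nrow(m3), 0)
  ## different contrasts -> nothing
  de2 <- de("mrna1", "up"); de2$stage <- "tetrad"
  m4 <- classify_modules(hits("lnc1", FALSE, "lncRNA"),
                         hits("mrna1", FALSE, "mRNA"),
                         rbind(de("lnc1", "up"), de2))
  expect_equal(nrow(m4), 0)
})

test_that("sponge and precursor roles are disjoint per module key", {
  sim <- small_corpus()
  em <- small_expression()
  bt <- setNames(sim$biotype[rownames(em$counts)], rownames(em$counts))
  cells <- unique(sim$design[, c("cultivar", "stage")])
  all_de <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    noiseq_de(em, cells$cultivar[i], cells$stage[i], biotype = bt)))
  de_ids <- unique(all_de$gene_id[all_de$direction != "ns"])
  locus_seq <- sim$seqs
  names(locus_seq) <- sim$tx2gene[names(locus_seq)]
  locus_seq <- locus_seq[!duplicated(names(locus_seq))]
  lh <- scan_mirna_targets(sim$mirnas,
                           locus_seq[intersect(de_ids, sim$lnc_loci$gene_id)])
  mh <- scan_mirna_targets(sim$mirnas,
                           locus_seq[intersect(de_ids, sim$gene_loci$gene_id)],
                           rna_class = "mRNA")
  mods <- classify_modules(lh, mh, all_de)
  key <- paste(mods$lncrna_id, mods$mirna_id, mods$mrna_id,
               mods$cultivar, mods$stage)
  roles_per_key <- tapply(mods$role, key, function(x) length(unique(x)))
  expect_true(all(roles_per_key == 1))
  s <- module_summary(mods)
  expect_equal(sum(s$per_cultivar$n), nrow(mods))
  empty <- module_summary(mods[0, ])
  expect_true(all(empty$counts == 0))
})
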