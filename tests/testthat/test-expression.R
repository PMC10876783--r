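toy_design <- function(n_rep = 3) {
  d <- expand.grid(replicate = seq_len(n_rep),
                   condition = c("control", "heat"),
                   stage = "meiosis", cultivar = "cr",
                   stringsAsFactors = FALSE)
  d$sample <- paste0("s", seq_len(nrow(d)))
  d[, c("sample", "cultivar", "stage", "condition", "replicate")]
}

test_that("locus aggregation sums member transcripts", {
  m <- matrix(c(10, 5, 7, 2, 1, 9), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  map <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  agg <- aggregate_to_locus(m, map)
  expect_equal(agg["gA", ], c(s1 = 15, s2 = 3))
  expect_equal(agg["gB", ], c(s1 = 7, s2 = 9))
  ## single-transcript locus is the identity
  expect_equal(agg["gB", ], m["t3", ])
  ## permuting transcript rows changes nothing
  expect_equal(aggregate_to_locus(m[c(3, 1, 2), ], map), agg)
  expect_error(aggregate_to_locus(m, map[1:2]), "unmapped")
})

test_that("TMM factors are 1 for identical samples and scale-invariant", {
  set.seed(31)
  counts <- matrix(rnbinom(200 * 4, mu = 100, size = 10), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(tmm_factors(same), rep(1, 3))
  ## multiplying every count by a constant leaves factors unchanged
  expect_equal(tmm_factors(counts), tmm_factors(counts * 7))
})

test_that("TMM separates composition shift from pure library size", {
  set.seed(32)
  a <- rnbinom(500, mu = 200, size = 20) + 1
  ## B = 2A elementwise is pure sequencing depth: same composition, so
  ## both factors are 1 and the library sizes absorb the doubling
  expect_equal(unname(tmm_factors(cbind(s1 = a, s2 = 2 * a))), c(1, 1))
  ## a uniform composition shift: B equals A on the shared genes but
  ## half its library goes to one gene absent from A, so every shared
  ## gene's M is exactly -1 and the closed-form factor ratio is 2^-1
  ## (no trimming effect: all M identical)
  counts <- cbind(s1 = c(a, 0), s2 = c(a, sum(a)))
  f <- tmm_factors(counts)
  expect_equal(f[2] / f[1], 0.5, tolerance = 1e-10)
})

test_that("TMM factors agree with the edgeR reference within 1e-6", {
  set.seed(33)
  counts <- matrix(rnbinom(2000 * 6, mu = rep(exp(rnorm(2000, 4, 1)), 6),
                           size = 5), ncol = 6,
                   dimnames = list(NULL, paste0("s", 1:6)))
  counts[sample(length(counts), 500)] <- 0
  ours <- tmm_factors(counts)
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("CPM filtering keeps boundary CPM 1 and drops silent genes", {
  d <- toy_design(2)
  counts <- rbind(zero = c(0, 0, 0, 0),
                  boundary = c(1, 1, 1, 1),
                  high = c(10, 10, 10, 10))
  pad <- matrix(rep(1e6 - 11, 4), nrow = 1,
                dimnames = list("pad", NULL))
  m <- rbind(counts, pad)
  colnames(m) <- d$sample
  em <- tmm_normalize(expression_matrix(m, d))
  ## library size 1e6 and factors 1, so count 1 is exactly CPM 1
  expect_equal(unname(em$tmm), rep(1, 4))
  kept <- rownames(cpm_filter(em)$counts)
  expect_false("zero" %in% kept)
  expect_true(all(c("boundary", "high") %in% kept))
})

test_that("dominance probability is monotone in |M| and D", {
  set.seed(34)
  nm <- abs(rnorm(500)); nd <- abs(rnorm(500, sd = 10))
  p1 <- pollenlnc:::dominance_probability(c(1, 1.5), c(5, 5), nm, nd)
  expect_lte(p1[1], p1[2])
  p2 <- pollenlnc:::dominance_probability(c(1, 1), c(5, 8), nm, nd)
  expect_lte(p2[1], p2[2])
  ## agreement with the direct double loop
  sig_m <- abs(rnorm(20)); sig_d <- abs(rnorm(20, sd = 10))
  direct <- vapply(seq_along(sig_m), function(i)
    mean(nm < sig_m[i] & nd < sig_d[i]), numeric(1))
  expect_equal(pollenlnc:::dominance_probability(sig_m, sig_d, nm, nd),
               direct)
})

test_that("a gene with equal condition means is never called", {
  d <- toy_design(3)
  set.seed(35)
  counts <- matrix(rnbinom(300 * 6, mu = 80, size = 10), ncol = 6,
                   dimnames = list(paste0("g", 1:300), d$sample))
  em <- tmm_normalize(expression_matrix(counts, d))
  r <- noiseq_de(em, "cr", "meiosis")
  expect_true(all(r$direction == "ns"))
  ## |M| = 0 genes sit at the bottom of the probability ordering
  flat <- which.min(abs(r$log2fc))
  expect_lte(r$de_probability[flat], quantile(r$de_probability, 0.5))
})

test_that("direction calls respect the lncRNA fold-change and FDR rules", {
  sim <- small_corpus()
  em <- small_expression()
  r <- noiseq_de(em, "wk", "tetrad")
  up <- r[r$direction == "up", ]
  down <- r[r$direction == "down", ]
  expect_true(all(up$log2fc > 0.5 & up$fdr <= 0.05))
  expect_true(all(down$log2fc < -0.5 & down$fdr <= 0.05))
})

test_that("DE summaries count overlaps and rank variance correctly", {
  d <- toy_design(3)
  set.seed(36)
  counts <- matrix(rnbinom(5 * 6, mu = c(10, 50, 100, 400, 20), size = 8),
                   ncol = 6, dimnames = list(paste0("g", 1:5), d$sample))
  em <- tmm_normalize(expression_matrix(counts, d))
  fake <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    cultivar = c("cr", "cr", "cr"),
    stage = c("meiosis", "tetrad", "meiosis"),
    log2fc = c(2, 2, -1), d_stat = 1, de_probability = 0.99,
    p_value = 0.01, fdr = 0.01,
    direction = c("up", "up", "down"), biotype = "lncRNA",
    stringsAsFactors = FALSE)
  s <- summarize_de(split(fake, seq_len(3)), em, top_k = 3)
  ## g1 is up in both stages of cr -> concordant stage overlap of 1
  expect_equal(s$stage_overlap_concordant, 1)
  expr <- log2(cpm_matrix(em) + 1)
  v <- sort(apply(expr, 1, var), decreasing = TRUE)
  expect_equal(s$top_variance$gene_id, names(v)[1:3])
  expect_equal(s$top_variance$variance, unname(v[1:3]))
})
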