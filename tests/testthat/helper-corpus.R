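## A small shared corpus, built once per test run. Sized to keep the unit
## suite fast; the acceptance tests build the full default corpus
## themselves.
.corpus_env <- new.env(parent = emptyenv())

small_config <- function(seed = 11) {
  simulation_config(
    seed = seed, n_coding_genes = 60, n_lncrna_loci = 50,
    n_sponge = 4, n_precursor = 3, n_cis_pairs = 5, n_trans_pairs = 3,
    n_subgenome_pairs = 4, n_nonconserved = 3, n_species = 5,
    n_mirnas = 10)
}

small_corpus <- function() {
  if (is.null(.corpus_env$corpus)) {
    .corpus_env$corpus <- simulate_study(small_config())
  }
  .corpus_env$corpus
}

small_discovery <- function() {
  if (is.null(.corpus_env$discovery)) {
    sim <- small_corpus()
    training <- default_training(sim$transcripts, sim$seqs, seed = 1)
    .corpus_env$discovery <- discover_lncrnas(sim$transcripts, sim$seqs,
                                              training, sim$protein_db)
  }
  .corpus_env$discovery
}

small_expression <- function() {
  if (is.null(.corpus_env$em)) {
    sim <- small_corpus()
    counts <- aggregate_to_locus(sim$counts, sim$tx2gene)
    .corpus_env$em <- cpm_filter(tmm_normalize(
      expression_matrix(counts, sim$design)))
  }
  .corpus_env$em
}

## exact-correlation pair: returns y with sample cor(x, y) == r exactly
pair_with_r <- function(x, r) {
  e <- rnorm(length(x))
  xs <- scale(x)[, 1]
  es <- scale(lm(e ~ xs)$residuals)[, 1]
  r * xs + sqrt(1 - r^2) * es
}
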