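#' Simulation configuration for the synthetic study corpus
#'
#' Defaults mirror the study design being emulated: four wheat cultivars
#' (two heat-sensitive, two heat-tolerant) sampled at meiosis and tetrad
#' under control and heat, three replicates per condition cell (so each
#' (cultivar, stage) correlation uses n = 6 samples, where the two-sided
#' p < 0.05 boundary is |r| = 0.81), lncRNA mean length ~2,400 nt vs
#' ~4,200 nt for coding transcripts, mostly intergenic ("u") class codes,
#' planted fold changes entirely above the |log2FC| > 0.5 call threshold,
#' and 13 species for the conservation panel.
#'
#' @param seed integer RNG seed; the whole corpus is a deterministic
#'   function of the config.
#' @param n_chrom_per_subgenome chromosomes per sub-genome (A, B, D).
#' @param n_coding_genes,n_lncrna_loci locus counts.
#' @param class_code_fractions named fractions over c(i, o, u, x),
#'   summing to 1.
#' @param replicates per condition cell.
#' @param de_fraction fraction of lncRNA loci planted as differentially
#'   expressed.
#' @param de_log2fc_range range of planted |log2FC|; must sit entirely
#'   above 0.5.
#' @param nb_dispersion negative-binomial dispersion of unplanted genes.
#' @param n_mirnas,n_sponge,n_precursor miRNA panel and planted triples.
#' @param n_cis_pairs,n_trans_pairs planted co-expression pairs.
#' @param n_species conservation panel size.
#' @param conserved_fraction fraction of lncRNA loci with cross-species
#'   homologs.
#' @param mutation_rate per-base substitution rate of planted homologs.
#' @param nonconserved_rate,n_nonconserved divergence and count of
#'   negative-control homologs (expected to fail the 60% identity rule).
#' @param n_subgenome_pairs planted within-wheat A/B/D homolog pairs.
#' @param n_domain_planted candidate transcripts carrying a protein
#'   domain (to be caught by the veto).
#' @param lnc_mean_len,coding_mean_len mean transcript lengths (nt).
#' @param low_expr_fraction fraction of lncRNAs planted below the CPM
#'   filter.
#' @param cultivars,stages,conditions design levels (first two cultivars
#'   are the heat-sensitive pair).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chrom_per_subgenome = 2L,
    n_coding_genes = 240L,
    n_lncrna_loci = 120L,
    class_code_fractions = c(i = 0.05, o = 0.05, u = 0.85, x = 0.05),
    replicates = 3L,
    de_fraction = 0.4,
    de_log2fc_range = c(2.75, 3.25),
    nb_dispersion = 0.1,
    n_mirnas = 20L,
    n_sponge = 10L,
    n_precursor = 5L,
    n_cis_pairs = 15L,
    n_trans_pairs = 8L,
    n_species = 13L,
    conserved_fraction = 0.3,
    mutation_rate = 0.1,
    nonconserved_rate = 0.5,
    n_nonconserved = 8L,
    n_subgenome_pairs = 10L,
    n_domain_planted = 4L,
    lnc_mean_len = 2400,
    coding_mean_len = 4200,
    low_expr_fraction = 0.1,
    cultivars = c("cr", "wk", "ha", "yo"),
    stages = c("meiosis", "tetrad"),
    conditions = c("control", "heat")) {
  cfg <- as.list(environment())
  if (abs(sum(class_code_fractions) - 1) > 1e-8 ||
      any(class_code_fractions < 0))
    stopf("class_code_fractions must be non-negative and sum to 1")
  if (!setequal(names(class_code_fractions), c("i", "o", "u", "x")))
    stopf("class_code_fractions must be named i, o, u, x")
  if (min(de_log2fc_range) <= 0.5)
    stopf("de_log2fc_range must sit entirely above 0.5")
  for (f in c("de_fraction", "conserved_fraction", "mutation_rate",
              "nonconserved_rate", "low_expr_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must be in [0, 1]", f)
  }
  if (lnc_mean_len < 400 || coding_mean_len < 900)
    stopf("mean lengths too short to hold the planted structure")
  if (n_sponge + n_precursor > n_mirnas)
    stopf("need at least one miRNA per planted triple")
  structure(cfg, class = "sim_config")
}
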