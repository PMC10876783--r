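CONSERVATION_SPECIES <- c(
  "Hordeum_vulgare", "Oryza_sativa", "Brachypodium_distachyon",
  "Zea_mays", "Sorghum_bicolor", "Setaria_italica", "Nicotiana_tabacum",
  "Brassica_napus", "Setaria_viridis", "Glycine_max",
  "Gossypium_barbadense", "Arabidopsis_thaliana", "Pisum_sativum")

#' Simulate miRNAs, cross-species homolog sets and GO annotations
#'
#' Completes the corpus around the genome simulation:
#' \itemize{
#'   \item miRNAs: each precursor triple's miRNA is the exact reverse
#'     complement of a window of its lncRNA (perfect site, plant score
#'     0); each sponge triple's miRNA matches a lncRNA window up to one
#'     G:U wobble and is planted into the partner mRNA's 3' UTR with one
#'     non-seed mismatch (both sites score <= 4); remaining miRNAs are
#'     random 21-mers.
#'   \item homologs: a configured fraction of lncRNA loci get point-
#'     mutated copies (default 10% divergence) in one or more species of
#'     a 13-species panel, with closely related grasses favoured; a few
#'     negative controls diverge at 50% and should fail the conservation
#'     thresholds. Every species set carries random decoys.
#'   \item GO: a small acyclic is_a DAG (depth 3) with genes annotated to
#'     mid/leaf terms, and one term planted as enriched among
#'     up-regulated and one among down-regulated coding genes.
#' }
#'
#' @param config a [simulation_config()].
#' @param sim a `genome_sim` (modified sequences are returned inside the
#'   result).
#' @return the `genome_sim` with added elements `mirnas`,
#'   `species_sets`, `go` (list `dag`, `gene2go`) and an updated
#'   `ground_truth` (`mirnas`, `homolog_map`, `enriched_terms`), and with
#'   sponge/precursor sites embedded in `seqs`.
#' @export
simulate_mirnas_and_homologs <- function(config, sim) {
  with_seed(config$seed + 2L, simulate_extras_impl(config, sim))
}

simulate_extras_impl <- function(cfg, sim) {
  gt <- sim$ground_truth
  seqs <- sim$seqs
  reserved <- sim$reserved
  mir_len <- 21L

  mirnas <- character(0)
  mirna_roles <- list()
  mir_i <- 0L
  next_mirna_id <- function() {
    mir_i <<- mir_i + 1L
    sprintf("miR%03d", mir_i)
  }
  embed_site <- function(tid, site) {
    w <- place_window(nchar(seqs[[tid]]), nchar(site), reserved[[tid]])
    s <- seqs[[tid]]
    substr(s, w, w + nchar(site) - 1L) <- site
    seqs[[tid]] <<- s
    reserved[[tid]] <<- c(reserved[[tid]],
                          list(c(w, w + nchar(site) - 1L)))
    w
  }
  mutate_non_seed <- function(site) {
    ## one mismatch at a miRNA position outside 2-13; the site is the
    ## reverse complement, so miRNA position p maps to site position
    ## len - p + 1
    p <- sample_vec(setdiff(15:mir_len, mir_len), 1L)
    sp <- nchar(site) - p + 1L
    old <- substr(site, sp, sp)
    substr(site, sp, sp) <- sample_vec(setdiff(BASES, old), 1L)
    site
  }

  ## one miRNA per planted triple (the triple tables carry one row per
  ## contrast cell, so dedupe on the lncRNA/mRNA pair)
  uniq_triples <- function(tri) {
    tri[!duplicated(paste(tri$lncrna_id, tri$mrna_id)), , drop = FALSE]
  }
  ## precursor miRNAs: perfect complement of a lncRNA window
  if (!is.null(gt$precursor_triples)) {
    tri_p <- uniq_triples(gt$precursor_triples)
    for (i in seq_len(nrow(tri_p))) {
      tr <- tri_p[i, ]
      ltid <- paste0(tr$lncrna_id, ".1")
      w <- place_window(nchar(seqs[[ltid]]), mir_len, reserved[[ltid]])
      reserved[[ltid]] <- c(reserved[[ltid]], list(c(w, w + mir_len - 1L)))
      mid <- next_mirna_id()
      mirnas[mid] <- revcomp(substr(seqs[[ltid]], w, w + mir_len - 1L))
      embed_site(paste0(tr$mrna_id, ".1"),
                 mutate_non_seed(revcomp(mirnas[mid])))
      mirna_roles[[mid]] <- data.frame(mirna_id = mid, role = "precursor",
                                       lncrna_id = tr$lncrna_id,
                                       mrna_id = tr$mrna_id,
                                       stringsAsFactors = FALSE)
    }
  }
  ## sponge miRNAs: lncRNA window complement with one G:U wobble
  if (!is.null(gt$sponge_triples)) {
    tri_s <- uniq_triples(gt$sponge_triples)
    for (i in seq_len(nrow(tri_s))) {
      tr <- tri_s[i, ]
      ltid <- paste0(tr$lncrna_id, ".1")
      w <- place_window(nchar(seqs[[ltid]]), mir_len, reserved[[ltid]])
      reserved[[ltid]] <- c(reserved[[ltid]], list(c(w, w + mir_len - 1L)))
      mid <- next_mirna_id()
      mi <- revcomp(substr(seqs[[ltid]], w, w + mir_len - 1L))
      ## a G:U wobble against the lncRNA: find a miRNA position outside
      ## the doubled range whose target base is T and set the miRNA base
      ## to G (G pairs T as a wobble)
      site <- substr(seqs[[ltid]], w, w + mir_len - 1L)
      cand <- which(seq_chars(mi) == "A" &
                      rev(seq_chars(site)) == "T")
      cand <- cand[cand > 13L & cand < mir_len]
      if (length(cand)) {
        p <- sample_vec(cand, 1L)
        substr(mi, p, p) <- "G"
      }
      mirnas[mid] <- mi
      embed_site(paste0(tr$mrna_id, ".1"), mutate_non_seed(revcomp(mi)))
      mirna_roles[[mid]] <- data.frame(mirna_id = mid, role = "sponge",
                                       lncrna_id = tr$lncrna_id,
                                       mrna_id = tr$mrna_id,
                                       stringsAsFactors = FALSE)
    }
  }
  ## background miRNAs
  while (length(mirnas) < cfg$n_mirnas) {
    mid <- next_mirna_id()
    mirnas[mid] <- random_seq(mir_len)
    mirna_roles[[mid]] <- data.frame(mirna_id = mid, role = "none",
                                     lncrna_id = NA_character_,
                                     mrna_id = NA_character_,
                                     stringsAsFactors = FALSE)
  }

  ## ---- cross-species homologs ----
  species <- CONSERVATION_SPECIES[seq_len(cfg$n_species)]
  species_weight <- 0.6^(seq_along(species) - 1L)
  lnc_ids <- sim$lnc_loci$gene_id
  eligible <- setdiff(lnc_ids, sub("\\.1$", "", gt$domain_planted))
  conserved <- sample_vec(eligible,
                          round(cfg$conserved_fraction * length(lnc_ids)))
  homolog_rows <- list()
  species_sets <- setNames(vector("list", length(species)), species)
  add_homolog <- function(lnc, sp, rate) {
    src <- seqs[[paste0(lnc, ".1")]]
    hid <- sprintf("%s_h%04d", sp, length(species_sets[[sp]]) + 1L)
    species_sets[[sp]][hid] <<- mutate_seq(src, rate)
    homolog_rows[[length(homolog_rows) + 1L]] <<- data.frame(
      lncrna_id = lnc, species = sp, homolog_id = hid, rate = rate,
      stringsAsFactors = FALSE)
  }
  n_sp_per <- pmin(length(species),
                   1L + rnbinom(length(conserved), size = 1, prob = 0.45))
  for (i in seq_along(conserved)) {
    sps <- sample_vec(species, n_sp_per[i], prob = species_weight)
    for (sp in sps) add_homolog(conserved[i], sp, cfg$mutation_rate)
  }
  ## negative controls must not be sub-genome twins of conserved loci,
  ## or they would inherit indirect homology through their paralog
  neg_pool <- setdiff(eligible, conserved)
  if (!is.null(gt$subgenome_pairs)) {
    neg_pool <- setdiff(neg_pool, c(gt$subgenome_pairs$a,
                                    gt$subgenome_pairs$b))
  }
  nonconserved <- sample_vec(neg_pool,
                             min(cfg$n_nonconserved, length(neg_pool)))
  for (l in nonconserved) {
    add_homolog(l, sample_vec(species, 1L, prob = species_weight),
                cfg$nonconserved_rate)
  }
  ## decoys so every species set is non-trivial
  for (sp in species) {
    for (k in 1:3) {
      hid <- sprintf("%s_decoy%d", sp, k)
      species_sets[[sp]][hid] <- markov_seq(
        round(runif(1, 400, cfg$lnc_mean_len)))
    }
  }

  ## ---- GO ontology and annotations ----
  go <- simulate_go(cfg, sim, gt)

  gt$mirnas <- do.call(rbind, mirna_roles)
  gt$homolog_map <- do.call(rbind, homolog_rows)
  gt$enriched_terms <- go$enriched_terms
  sim$seqs <- seqs
  sim$reserved <- reserved
  sim$mirnas <- mirnas
  sim$species_sets <- species_sets
  sim$go <- list(dag = go$dag, gene2go = go$gene2go)
  sim$ground_truth <- gt
  sim
}

## small three-level is_a DAG plus gene annotations with two planted
## enriched terms (one among up-, one among down-regulated coding genes)
simulate_go <- function(cfg, sim, gt) {
  n1 <- 4L; n2 <- 8L; n3 <- 16L
  ids <- sprintf("GO:%07d", seq_len(1L + n1 + n2 + n3))
  root <- ids[1L]
  lvl1 <- ids[2:(1L + n1)]
  lvl2 <- ids[(2L + n1):(1L + n1 + n2)]
  lvl3 <- ids[(2L + n1 + n2):length(ids)]
  parents <- c(setNames(list(character(0)), root),
               setNames(lapply(lvl1, function(x) root), lvl1),
               setNames(lapply(lvl2, function(x)
                 sample_vec(lvl1, 1L)), lvl2),
               setNames(lapply(lvl3, function(x)
                 sample_vec(lvl2, 1L)), lvl3))
  dag <- structure(list(
    terms = data.frame(id = ids,
                       name = paste("synthetic process", seq_along(ids)),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = parents), class = "go_dag")
  genes <- sim$gene_loci$gene_id
  annot_pool <- c(lvl2, lvl3)
  gene2go <- lapply(setNames(genes, genes), function(g)
    sample_vec(annot_pool, sample(1:3, 1L)))
  de <- gt$de_table[gt$de_table$gene_id %in% genes, , drop = FALSE]
  up_genes <- unique(de$gene_id[de$direction == "up"])
  down_genes <- unique(de$gene_id[de$direction == "down"])
  term_up <- lvl3[1L]; term_down <- lvl3[2L]
  for (g in sample_vec(up_genes, round(0.8 * length(up_genes))))
    gene2go[[g]] <- union(gene2go[[g]], term_up)
  for (g in sample_vec(down_genes, round(0.8 * length(down_genes))))
    gene2go[[g]] <- union(gene2go[[g]], term_down)
  list(dag = dag, gene2go = gene2go,
       enriched_terms = c(up = term_up, down = term_down))
}
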