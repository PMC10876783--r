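#' Pipeline configuration
#'
#' One object carrying every threshold of the workflow, at the published
#' defaults: 200-nt length filter, coding-probability cutoff ("auto" =
#' two-graph ROC, or a fixed value such as 0.365), CPM < 1 low-count
#' filter, |log2FC| > 0.5 with FDR 0.05 for lncRNA calls (|log2FC| > 1
#' for coding genes), 10-gene cis windows at alpha 0.05, ndG cutoff
#' -0.15, plant miRNA score cutoff 4, conservation E-value < 1e-5 with
#' >= 60% identity over >= 30% of the shorter sequence, and 1000
#' bootstrap replicates for the tree.
#'
#' @param seed seed for the stages that resample (tree bootstrap,
#'   training shuffles).
#' @param min_len,coding_cutoff,min_cpm,lnc_lfc,coding_lfc,fdr,k,alpha
#'   thresholds (see description).
#' @param ndg_cutoff,mirna_max_score,evalue,min_ident,min_cov,bootstrap
#'   thresholds (see description).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, min_len = 200L,
                            coding_cutoff = "auto", min_cpm = 1,
                            lnc_lfc = 0.5, coding_lfc = 1, fdr = 0.05,
                            k = 10L, alpha = 0.05, ndg_cutoff = -0.15,
                            mirna_max_score = 4, evalue = 1e-5,
                            min_ident = 60, min_cov = 0.30,
                            bootstrap = 1000L) {
  structure(as.list(environment()), class = "pipeline_config")
}

## composition-preserving per-sequence shuffle used to build the
## non-coding training set from the candidates themselves
shuffle_seq <- function(x) {
  vapply(x, function(s) paste0(sample_vec(seq_chars(s), nchar(s)),
                               collapse = ""), character(1))
}

#' Default coding/non-coding training sets for the discovery model
#'
#' Coding examples are reference-matching ("=") transcripts; non-coding
#' examples are composition-preserving shuffles of the candidate
#' sequences, which destroy codon structure while keeping base content.
#'
#' @param ts a `transcript_set`.
#' @param seqs named character vector of sequences.
#' @param n_max cap per class.
#' @param seed shuffle seed.
#' @return list with `coding` and `noncoding` character vectors.
#' @export
default_training <- function(ts, seqs, n_max = 300L, seed = 1L) {
  with_seed(seed, {
    coding_ids <- ts$transcript_id[ts$class_code == "="]
    cand_ids <- ts$transcript_id[ts$class_code %in% LNCRNA_CLASS_CODES]
    coding_ids <- sample_vec(coding_ids, min(n_max, length(coding_ids)))
    cand_ids <- sample_vec(cand_ids, min(n_max, length(cand_ids)))
    list(coding = unname(seqs[coding_ids]),
         noncoding = unname(shuffle_seq(seqs[cand_ids])))
  })
}

#' Run the full workflow end to end
#'
#' Executes discover -> de -> targets -> mirna -> enrich -> conserve ->
#' tree on a corpus directory written by [simulate_study()] (or any
#' directory with the same file layout), writing plain-file outputs per
#' stage plus a manifest JSON of the seed, thresholds and per-stage
#' record counts. A failing stage halts the run with an error naming the
#' stage.
#'
#' @param indir input corpus directory.
#' @param outdir output directory (created).
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; outputs under `outdir`.
#' @export
run_pipeline <- function(indir, outdir, config = pipeline_config()) {
  for (f in c("annotation.gtf", "transcripts.fa", "counts.tsv",
              "design.tsv", "mirnas.fa", "proteins.fa", "gene2go.tsv",
              "ontology.obo")) {
    if (!file.exists(file.path(indir, f)))
      stopf("missing input: %s", file.path(indir, f))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   thresholds = config[setdiff(names(config), "seed")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }

  ## ---- discover ----
  disc <- stage("discover", {
    ts <- read_gtf(file.path(indir, "annotation.gtf"))
    seqs <- read_fasta(file.path(indir, "transcripts.fa"))
    proteins <- read_fasta(file.path(indir, "proteins.fa"))
    training <- default_training(ts, seqs, seed = config$seed)
    cutoff <- if (identical(config$coding_cutoff, "auto")) NULL else
      config$coding_cutoff
    run <- discover_lncrnas(ts, seqs, training, proteins,
                            min_len = config$min_len,
                            fixed_cutoff = cutoff)
    write_gtf(run$lncrna, file.path(outdir, "lncrna.gtf"))
    write_fasta(seqs[run$lncrna$transcript_id],
                file.path(outdir, "lncrna.fa"))
    write.table(run$report, file.path(outdir, "coding_potential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(run$venn),
                         file.path(outdir, "venn_counts.json"),
                         auto_unbox = TRUE)
    list(run = run, ts = ts, seqs = seqs)
  })
  manifest$stages$discover <- as.list(disc$run$stage_counts)

  ## ---- de ----
  de <- stage("de", {
    counts <- read_counts(file.path(indir, "counts.tsv"))
    design <- read_design(file.path(indir, "design.tsv"))
    tx2gene <- setNames(disc$ts$gene_id, disc$ts$transcript_id)
    gene_counts <- aggregate_to_locus(counts, tx2gene)
    em <- tmm_normalize(expression_matrix(gene_counts, design))
    em <- cpm_filter(em, config$min_cpm)
    lnc_loci_ids <- unique(disc$run$lncrna$gene_id)
    biotype <- setNames(ifelse(rownames(em$counts) %in% lnc_loci_ids,
                               "lncRNA", "coding"), rownames(em$counts))
    cells <- unique(design[, c("cultivar", "stage")])
    results <- lapply(seq_len(nrow(cells)), function(i) {
      r <- noiseq_de(em, cells$cultivar[i], cells$stage[i],
                     lfc_threshold = config$lnc_lfc,
                     fdr_threshold = config$fdr, biotype = biotype)
      ## coding genes need the larger fold change
      coding <- r$biotype == "coding" & abs(r$log2fc) <= config$coding_lfc
      r$direction[coding] <- "ns"
      r
    })
    all_de <- do.call(rbind, results)
    write.table(all_de, file.path(outdir, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summ <- summarize_de(results, em)
    write.table(summ$updown_counts, file.path(outdir, "de_updown.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(em = em, results = results, all = all_de, biotype = biotype,
         summary = summ)
  })
  manifest$stages$de <- list(
    n_genes_tested = nrow(de$em$counts),
    n_de_lncrna = length(unique(
      de$all$gene_id[de$all$direction != "ns" &
                       de$all$biotype == "lncRNA"])),
    n_de_coding = length(unique(
      de$all$gene_id[de$all$direction != "ns" &
                       de$all$biotype == "coding"])))

  ## ---- targets (cis / trans) ----
  targets <- stage("targets", {
    lnc_tbl <- disc$run$lncrna
    lnc_loci <- unique(data.frame(gene_id = lnc_tbl$gene_id,
                                  chrom = lnc_tbl$chrom,
                                  start = lnc_tbl$start,
                                  end = lnc_tbl$end,
                                  stringsAsFactors = FALSE))
    coding_tbl <- disc$ts[disc$ts$class_code == "=", , drop = FALSE]
    gene_loci <- unique(data.frame(gene_id = coding_tbl$gene_id,
                                   chrom = coding_tbl$chrom,
                                   start = coding_tbl$start,
                                   end = coding_tbl$end,
                                   stringsAsFactors = FALSE))
    ## locus-level sequences for the ndG filter (first transcript)
    locus_seq <- disc$seqs
    names(locus_seq) <- disc$ts$gene_id[
      match(names(locus_seq), disc$ts$transcript_id)]
    locus_seq <- locus_seq[!duplicated(names(locus_seq))]
    edges <- list()
    for (r in de$results) {
      rl <- r[r$biotype == "lncRNA", , drop = FALSE]
      if (!any(rl$direction != "ns")) next
      edges[[length(edges) + 1L]] <- build_cis_trans(
        rl, lnc_loci, gene_loci, de$em, seqs = locus_seq,
        k = config$k, alpha = config$alpha,
        ndg_cutoff = config$ndg_cutoff)
    }
    edges <- do.call(rbind, edges)
    write.table(edges, file.path(outdir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    edges
  })
  manifest$stages$targets <- list(
    n_cis = sum(targets$mode == "cis"),
    n_trans = sum(targets$mode == "trans"))

  ## ---- mirna ----
  mir <- stage("mirna", {
    mirnas <- read_fasta(file.path(indir, "mirnas.fa"))
    de_ids <- unique(de$all$gene_id[de$all$direction != "ns"])
    lnc_ids <- de_ids[de$biotype[de_ids] == "lncRNA"]
    mrna_ids <- de_ids[de$biotype[de_ids] == "coding"]
    locus_seq <- disc$seqs
    names(locus_seq) <- disc$ts$gene_id[
      match(names(locus_seq), disc$ts$transcript_id)]
    locus_seq <- locus_seq[!duplicated(names(locus_seq))]
    lnc_hits <- scan_mirna_targets(mirnas, locus_seq[lnc_ids],
                                   rna_class = "lncRNA",
                                   max_score = config$mirna_max_score)
    mrna_hits <- scan_mirna_targets(mirnas, locus_seq[mrna_ids],
                                    rna_class = "mRNA",
                                    max_score = config$mirna_max_score)
    modules <- classify_modules(lnc_hits, mrna_hits, de$all)
    write.table(modules, file.path(outdir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(modules = modules, summary = module_summary(modules))
  })
  manifest$stages$mirna <- list(
    n_sponge = sum(mir$modules$role == "sponge"),
    n_precursor = sum(mir$modules$role == "precursor"))

  ## ---- enrich ----
  enr <- stage("enrich", {
    dag <- read_obo(file.path(indir, "ontology.obo"))
    gene2go <- read_gene2go(file.path(indir, "gene2go.tsv"))
    closure <- propagate_annotations(gene2go, dag)
    population <- intersect(rownames(de$em$counts), names(gene2go))
    study <- intersect(unique(targets$gene_id), population)
    rows <- fisher_enrich(study, population, closure,
                          alpha = config$alpha)
    rows <- rollup_terms(rows, dag)
    write.table(rows, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rows
  })
  manifest$stages$enrich <- list(
    n_terms_tested = nrow(enr),
    n_significant = sum(enr$significant))

  ## ---- conserve ----
  cons <- stage("conserve", {
    lnc_tbl <- disc$run$lncrna
    locus_seq <- disc$seqs[lnc_tbl$transcript_id]
    tx2gene <- setNames(lnc_tbl$gene_id, lnc_tbl$transcript_id)
    sp_files <- list.files(file.path(indir, "species"),
                           full.names = TRUE)
    calls <- list()
    for (f in sp_files) {
      sp <- sub("\\.fa$", "", basename(f))
      subj <- read_fasta(f)
      hits <- homology_search(locus_seq, subj)
      if (!nrow(hits)) next
      cc <- call_conservation(hits, nchar(locus_seq), nchar(subj),
                              max_evalue = config$evalue,
                              min_ident = config$min_ident,
                              min_cov = config$min_cov)
      cc$species <- sp
      calls[[sp]] <- cc
    }
    calls <- do.call(rbind, calls)
    spec <- species_conservation(calls, tx2gene)
    lnc_loci <- unique(data.frame(gene_id = lnc_tbl$gene_id,
                                  chrom = lnc_tbl$chrom,
                                  stringsAsFactors = FALSE))
    one_seq <- locus_seq[!duplicated(tx2gene)]
    names(one_seq) <- tx2gene[!duplicated(tx2gene)]
    sub <- subgenome_conservation(lnc_loci, one_seq,
                                  max_evalue = config$evalue,
                                  min_ident = config$min_ident,
                                  min_cov = config$min_cov)
    write.table(calls, file.path(outdir, "conservation_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(per_species = as.list(spec$per_species),
           n_conserved = spec$n_conserved,
           n_two_or_more = spec$n_two_or_more,
           n_nine_or_more = spec$n_nine_or_more,
           subgenome_overlaps = as.list(sub$overlaps)),
      file.path(outdir, "conservation_summary.json"), auto_unbox = TRUE)
    list(calls = calls, species = spec, subgenome = sub,
         locus_seq = one_seq)
  })
  manifest$stages$conserve <- list(
    n_conserved_loci = cons$species$n_conserved,
    n_two_or_more = cons$species$n_two_or_more)

  ## ---- tree ----
  tree <- stage("tree", {
    cc <- cons$calls[cons$calls$conserved, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    by_q <- table(cc$query_id)
    focal <- names(by_q)[which.max(by_q)]
    hom <- cc[cc$query_id == focal, , drop = FALSE]
    hom <- hom[!duplicated(hom$species), , drop = FALSE]
    if (nrow(hom) < 2L) return(NULL)
    sp_seqs <- character(0)
    for (i in seq_len(nrow(hom))) {
      f <- file.path(indir, "species", paste0(hom$species[i], ".fa"))
      ss <- read_fasta(f)
      sp_seqs[hom$species[i]] <- ss[[hom$subject_id[i]]]
    }
    seqset <- c(setNames(disc$seqs[focal], "Triticum_aestivum"), sp_seqs)
    res <- nj_tree(seqset, bootstrap = config$bootstrap,
                   seed = config$seed)
    write_newick(res$tree, file.path(outdir, "homolog_tree.nwk"))
    res
  })
  manifest$stages$tree <- list(
    n_leaves = if (is.null(tree)) 0L else length(tree$tree$tip.label))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
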