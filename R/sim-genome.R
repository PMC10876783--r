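#' Simulate the annotated toy genome with planted ground truth
#'
#' Generates coding and lncRNA loci on A/B/D sub-genome chromosomes (plus
#' an unassigned "U" scaffold), with sequences built so the discovery
#' cascade has signal to find: coding transcripts carry a long
#' codon-biased ORF (>= 300 nt, GC-rich third positions); non-coding
#' transcripts are first-order-Markov background with every ORF >= 150 nt
#' destroyed; lengths are drawn so lncRNAs average ~2,400 nt against
#' ~4,200 nt for coding. Roles are planted and recorded in the ground
#' truth: differential expression with |log2FC| above the call threshold,
#' cis/trans co-expression partners, sponge/precursor triple members,
#' within-wheat sub-genome homolog pairs, and a handful of candidates
#' carrying a real protein domain for the veto to catch.
#'
#' @param config a [simulation_config()].
#' @return list of class `genome_sim` with `transcripts`
#'   (a `transcript_set`), `seqs`, `tx2gene`, `biotype` (per locus),
#'   `gene_loci`, `lnc_loci`, `layout` (chromosome assembly plan),
#'   `protein_db`, `reserved` (per-transcript reserved windows) and
#'   `ground_truth` (class `ground_truth`).
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  chroms <- c(outer(seq_len(cfg$n_chrom_per_subgenome), c("A", "B", "D"),
                    paste0))
  ## ---- locus ids ----
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_coding_genes))
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrna_loci))

  ## ---- role assignment among lncRNA loci ----
  pool <- sample_vec(lnc_ids, length(lnc_ids))   # shuffled
  take <- function(n) {
    if (n > length(pool)) stopf("lncRNA pool exhausted: config plants more roles than loci")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  domain_ids <- take(cfg$n_domain_planted)
  sponge_lnc <- take(cfg$n_sponge)
  precursor_lnc <- take(cfg$n_precursor)
  cis_lnc <- take(cfg$n_cis_pairs)
  trans_lnc <- take(cfg$n_trans_pairs)
  n_sub <- cfg$n_subgenome_pairs
  sub_a <- take(n_sub)
  sub_b <- take(n_sub)
  low_ids <- take(min(length(pool) %/% 2L,
                      round(cfg$low_expr_fraction * cfg$n_lncrna_loci)))
  free_ids <- pool

  ## ---- chromosome assignment ----
  gene_chrom <- setNames(sample_vec(chroms, cfg$n_coding_genes,
                                    replace = TRUE), gene_ids)
  lnc_chrom <- setNames(sample_vec(chroms, cfg$n_lncrna_loci,
                                   replace = TRUE), lnc_ids)
  ## a slice of the unplanted loci sits on the unassigned scaffold
  u_pick <- sample_vec(c(low_ids, free_ids),
                       max(1L, round(0.05 * cfg$n_lncrna_loci)))
  lnc_chrom[u_pick] <- "U"
  ## sub-genome homolog pairs must sit on different sub-genomes
  sub_of <- function(ch) substr(ch, nchar(ch), nchar(ch))
  for (i in seq_len(n_sub)) {
    a <- sub_a[i]; b <- sub_b[i]
    if (sub_of(lnc_chrom[a]) == sub_of(lnc_chrom[b])) {
      other <- chroms[sub_of(chroms) != sub_of(lnc_chrom[a])]
      lnc_chrom[b] <- sample_vec(other, 1L)
    }
  }
  ## cis-pair lncRNAs need coding neighbours: put each on a chromosome
  ## carrying coding genes
  coding_chroms <- unique(gene_chrom)
  for (l in cis_lnc) {
    if (!(lnc_chrom[l] %in% coding_chroms))
      lnc_chrom[l] <- sample_vec(coding_chroms, 1L)
  }

  ## ---- sequences ----
  seqs <- character(0)
  reserved <- list()
  tx2gene <- character(0)
  tx_rows <- list()
  orf_spans <- list()
  draw_len <- function(mean_len, min_len) {
    max(min_len, round(rgamma(1L, shape = 6, scale = mean_len / 6)))
  }
  ## coding genes; ~10% carry a second (identical-locus) transcript so
  ## locus aggregation has something to sum
  two_tx <- sample_vec(gene_ids, max(0L, round(0.1 * cfg$n_coding_genes)))
  coding_seq <- function() {
    L <- draw_len(cfg$coding_mean_len, 900L)
    utr5 <- max(60L, round(0.10 * L))
    utr3 <- max(150L, round(0.22 * L))
    orf <- L - utr5 - utr3
    orf <- max(303L, (orf %/% 3L) * 3L)
    s <- paste0(random_seq(utr5, c(A = .2, C = .3, G = .3, T = .2)),
                random_orf(orf),
                random_seq(utr3))
    list(seq = s, orf = c(utr5 + 1L, utr5 + orf), utr3 = utr5 + orf + 1L)
  }
  for (g in gene_ids) {
    cs <- coding_seq()
    ntx <- if (g %in% two_tx) 2L else 1L
    for (k in seq_len(ntx)) {
      tid <- paste0(g, ".", k)
      seqs[tid] <- cs$seq
      reserved[[tid]] <- list(cs$orf)
      orf_spans[[tid]] <- cs$orf
      tx2gene[tid] <- g
      tx_rows[[tid]] <- list(transcript_id = tid, gene_id = g,
                             chrom = gene_chrom[[g]], class_code = "=",
                             strand = sample_vec(c("+", "-"), 1L))
    }
  }
  ## lncRNA loci
  lnc_codes <- setNames(sample_vec(names(cfg$class_code_fractions),
                                   cfg$n_lncrna_loci, replace = TRUE,
                                   prob = cfg$class_code_fractions),
                        lnc_ids)
  for (l in lnc_ids) {
    tid <- paste0(l, ".1")
    L <- draw_len(cfg$lnc_mean_len, 400L)
    seqs[tid] <- kill_orfs(markov_seq(L))
    reserved[[tid]] <- list()
    tx2gene[tid] <- l
    strand <- if (lnc_codes[[l]] == "u" && runif(1) < 0.5) "." else
      sample_vec(c("+", "-"), 1L)
    tx_rows[[tid]] <- list(transcript_id = tid, gene_id = l,
                           chrom = lnc_chrom[[l]],
                           class_code = lnc_codes[[l]], strand = strand)
  }
  ## sub-genome homologs: second of each pair becomes a diverged copy
  for (i in seq_len(n_sub)) {
    src <- paste0(sub_a[i], ".1"); dst <- paste0(sub_b[i], ".1")
    seqs[dst] <- kill_orfs(mutate_seq(seqs[[src]], cfg$mutation_rate))
  }
  ## domain-bearing candidates: embed a modest neutral-composition ORF
  ## whose translation sits in the protein database
  protein_db <- character(0)
  for (d in domain_ids) {
    tid <- paste0(d, ".1")
    orf_nt <- 3L * sample(60:80, 1L)
    w <- place_window(nchar(seqs[[tid]]), orf_nt, reserved[[tid]])
    orf <- neutral_orf(orf_nt)
    substr(seqs[[tid]], w, w + orf_nt - 1L) <- orf
    ## re-clean any incidental longer ORF created around the insert,
    ## without touching the insert itself
    reserved[[tid]] <- c(reserved[[tid]], list(c(w, w + orf_nt - 1L)))
    protein_db[paste0("dom_", d)] <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(orf, 1L, orf_nt - 3L))))
  }
  ## decoy proteins from real coding ORFs
  for (g in sample_vec(gene_ids, min(5L, length(gene_ids)))) {
    tid <- paste0(g, ".1")
    sp <- orf_spans[[tid]]
    orf <- substr(seqs[[tid]], sp[1L], sp[2L] - 3L)
    protein_db[paste0("pfam_", g)] <- as.character(
      Biostrings::translate(Biostrings::DNAString(orf)))
  }

  ## ---- placement ----
  all_tx <- names(tx_rows)
  loci <- unique(tx2gene)
  locus_chrom <- vapply(loci, function(g) {
    tx_rows[[match(TRUE, tx2gene == g)]]$chrom
  }, character(1))
  layout <- list()
  locus_coord <- list()
  for (ch in unique(locus_chrom)) {
    members <- sample_vec(loci[locus_chrom == ch],
                          sum(locus_chrom == ch))
    pos <- 0L
    plan <- list()
    for (g in members) {
      gap <- sample(2000:20000, 1L)
      pos <- pos + gap
      tids <- all_tx[tx2gene[all_tx] == g]
      splice_len <- nchar(seqs[[tids[1L]]])
      two_exon <- runif(1) < 0.2 && splice_len > 400L
      if (two_exon) {
        e1 <- round(runif(1, 0.3, 0.7) * splice_len)
        intron <- sample(100:1000, 1L)
        exon_starts <- c(pos, pos + e1 + intron)
        exon_ends <- c(pos + e1, pos + splice_len + intron)
        intron_seq <- random_seq(intron)
      } else {
        exon_starts <- pos
        exon_ends <- pos + splice_len
        intron_seq <- ""
      }
      span <- c(pos, max(exon_ends))
      locus_coord[[g]] <- list(chrom = ch, start = span[1L],
                               end = span[2L])
      for (tid in tids) {
        tx_rows[[tid]]$start <- span[1L]
        tx_rows[[tid]]$end <- span[2L]
        tx_rows[[tid]]$exon_starts <- exon_starts
        tx_rows[[tid]]$exon_ends <- exon_ends
      }
      plan[[length(plan) + 1L]] <- list(gap = gap, gene = g,
                                        intron = intron_seq,
                                        exon_split = if (two_exon)
                                          exon_ends[1L] - exon_starts[1L]
                                        else NA_integer_)
      pos <- span[2L]
    }
    layout[[ch]] <- plan
  }
  ts <- transcript_set(data.frame(
    transcript_id = vapply(tx_rows, `[[`, character(1), "transcript_id"),
    gene_id = vapply(tx_rows, `[[`, character(1), "gene_id"),
    chrom = vapply(tx_rows, `[[`, character(1), "chrom"),
    start = vapply(tx_rows, function(r) as.numeric(r$start), numeric(1)),
    end = vapply(tx_rows, function(r) as.numeric(r$end), numeric(1)),
    strand = vapply(tx_rows, `[[`, character(1), "strand"),
    class_code = vapply(tx_rows, `[[`, character(1), "class_code"),
    exon_starts = I(lapply(tx_rows, `[[`, "exon_starts")),
    exon_ends = I(lapply(tx_rows, `[[`, "exon_ends")),
    stringsAsFactors = FALSE, row.names = NULL))

  locus_df <- function(ids) {
    data.frame(gene_id = ids,
               chrom = vapply(locus_coord[ids], `[[`, character(1), "chrom"),
               start = vapply(locus_coord[ids], function(x)
                 as.numeric(x$start), numeric(1)),
               end = vapply(locus_coord[ids], function(x)
                 as.numeric(x$end), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  gene_loci <- locus_df(gene_ids)
  lnc_loci <- locus_df(lnc_ids)

  ## ---- planted DE table ----
  ## heat response is shared across cultivars and stages for many loci
  ## (as in the study's overlap tabulations): each planted locus is DE
  ## in a drawn set of contrast cells, with one direction throughout
  draw_cells <- function() {
    n_cv <- sample_vec(1:4, 1L, prob = c(0.45, 0.30, 0.15, 0.10))
    cvs <- sample_vec(cfg$cultivars, min(n_cv, length(cfg$cultivars)))
    sts <- if (runif(1) < 0.35) cfg$stages else
      sample_vec(cfg$stages, 1L)
    expand.grid(cultivar = cvs, stage = sts, stringsAsFactors = FALSE)
  }
  de_rows <- list()
  add_de <- function(locus, cells = NULL, dir = NULL, lfc = NULL) {
    if (is.null(cells)) cells <- draw_cells()
    if (is.null(dir)) dir <- sample_vec(c("up", "down"), 1L)
    if (is.null(lfc)) lfc <- runif(1, cfg$de_log2fc_range[1L],
                                   cfg$de_log2fc_range[2L])
    for (i in seq_len(nrow(cells))) {
      de_rows[[length(de_rows) + 1L]] <<- data.frame(
        gene_id = locus, cultivar = cells$cultivar[i],
        stage = cells$stage[i], true_log2fc = lfc, direction = dir,
        stringsAsFactors = FALSE)
    }
    list(cells = cells, dir = dir, lfc = lfc)
  }
  ## planted triples sit in the upper half of the fold-change range so
  ## their calls are solid at three replicates
  triple_lfc <- function() runif(1, mean(cfg$de_log2fc_range),
                                 cfg$de_log2fc_range[2L])
  ## triples: sponge = concordant trends, precursor = opposite trends
  mrna_pool <- sample_vec(gene_ids, length(gene_ids))
  take_mrna <- function(n) {
    out <- mrna_pool[seq_len(n)]; mrna_pool <<- mrna_pool[-seq_len(n)]; out
  }
  sponge_mrna <- take_mrna(cfg$n_sponge)
  precursor_mrna <- take_mrna(cfg$n_precursor)
  sponge_triples <- list()
  for (i in seq_along(sponge_lnc)) {
    e <- add_de(sponge_lnc[i], lfc = triple_lfc())
    add_de(sponge_mrna[i], cells = e$cells, dir = e$dir,
           lfc = triple_lfc())
    sponge_triples[[i]] <- data.frame(
      lncrna_id = sponge_lnc[i], mrna_id = sponge_mrna[i],
      cultivar = e$cells$cultivar, stage = e$cells$stage,
      direction = e$dir, stringsAsFactors = FALSE)
  }
  precursor_triples <- list()
  for (i in seq_along(precursor_lnc)) {
    e <- add_de(precursor_lnc[i], lfc = triple_lfc())
    add_de(precursor_mrna[i], cells = e$cells,
           dir = if (e$dir == "up") "down" else "up",
           lfc = triple_lfc())
    precursor_triples[[i]] <- data.frame(
      lncrna_id = precursor_lnc[i], mrna_id = precursor_mrna[i],
      cultivar = e$cells$cultivar, stage = e$cells$stage,
      direction = e$dir, stringsAsFactors = FALSE)
  }
  ## cis pairs: DE lncRNA plus a coding gene inside its 10-gene window;
  ## the co-expression latent factor lives in one cell
  mrna_used <- function() {
    u <- unique(vapply(de_rows, function(r) r$gene_id, character(1)))
    u[u %in% gene_ids]
  }
  cis_pairs <- list()
  for (l in cis_lnc) {
    e <- add_de(l)
    cell <- e$cells[1L, ]
    win <- cis_window(lnc_loci[lnc_loci$gene_id == l, ][1L, ], gene_loci)
    if (!nrow(win)) stopf("cis lncRNA %s has no coding neighbours", l)
    free_win <- setdiff(win$gene_id, mrna_used())
    partner <- sample_vec(if (length(free_win)) free_win else
      win$gene_id, 1L)
    ## the regulated neighbour shares the heat response, so the pair
    ## co-varies across conditions as well as through the latent factor
    add_de(partner, cells = e$cells, dir = e$dir)
    cis_pairs[[length(cis_pairs) + 1L]] <- data.frame(
      lncrna_id = l, gene_id = partner, cultivar = cell$cultivar,
      stage = cell$stage, stringsAsFactors = FALSE)
  }
  cell <- NULL
  ## trans pairs: DE lncRNA plus a coding gene on another chromosome,
  ## with a complementary segment planted so the ndG filter passes
  trans_pairs <- list()
  trans_targets <- take_mrna(cfg$n_trans_pairs)
  for (i in seq_along(trans_lnc)) {
    l <- trans_lnc[i]; g <- trans_targets[i]
    if (locus_coord[[g]]$chrom == lnc_chrom[[l]]) {
      ## same chromosome: still fine as long as it is outside the window,
      ## but prefer a clean cross-chromosome pair
      alt <- mrna_pool[vapply(mrna_pool, function(x)
        locus_coord[[x]]$chrom != lnc_chrom[[l]], logical(1))]
      if (length(alt)) {
        g <- alt[1L]; mrna_pool <- setdiff(mrna_pool, g)
      }
    }
    e <- add_de(l)
    cell <- e$cells[1L, ]
    add_de(g, cells = e$cells, dir = e$dir)
    ltid <- paste0(l, ".1"); gtid <- paste0(g, ".1")
    seg_len <- 260L
    gseq <- seqs[[gtid]]
    gs <- sample.int(nchar(gseq) - seg_len + 1L, 1L)
    w <- place_window(nchar(seqs[[ltid]]), seg_len, reserved[[ltid]])
    substr(seqs[[ltid]], w, w + seg_len - 1L) <-
      revcomp(substr(gseq, gs, gs + seg_len - 1L))
    reserved[[ltid]] <- c(reserved[[ltid]], list(c(w, w + seg_len - 1L)))
    seqs[[ltid]] <- kill_orfs_outside(seqs[[ltid]], reserved[[ltid]])
    trans_pairs[[length(trans_pairs) + 1L]] <- data.frame(
      lncrna_id = l, gene_id = g, cultivar = cell$cultivar,
      stage = cell$stage, stringsAsFactors = FALSE)
  }
  ## background DE: top up lncRNA DE to the configured fraction, plus a
  ## slice of coding genes
  planted_de <- unique(vapply(de_rows, function(r) r$gene_id, character(1)))
  want <- round(cfg$de_fraction * cfg$n_lncrna_loci)
  extra <- sample_vec(setdiff(free_ids, planted_de),
                      max(0L, min(want - sum(planted_de %in% lnc_ids),
                                  length(setdiff(free_ids, planted_de)))))
  for (l in extra) add_de(l)
  for (g in sample_vec(mrna_pool, round(0.3 * length(mrna_pool))))
    add_de(g)
  de_table <- do.call(rbind, de_rows)
  rownames(de_table) <- NULL

  biotype <- setNames(rep(c("coding", "lncRNA"),
                          c(length(gene_ids), length(lnc_ids))),
                      c(gene_ids, lnc_ids))
  gt <- structure(list(
    noncoding_ids = paste0(setdiff(lnc_ids, domain_ids), ".1"),
    coding_ids = names(seqs)[tx2gene[names(seqs)] %in% gene_ids],
    domain_planted = paste0(domain_ids, ".1"),
    low_expressed = low_ids,
    de_table = de_table,
    cis_pairs = do.call(rbind, cis_pairs),
    trans_pairs = do.call(rbind, trans_pairs),
    sponge_triples = do.call(rbind, sponge_triples),
    precursor_triples = do.call(rbind, precursor_triples),
    subgenome_pairs = if (n_sub) data.frame(
      a = sub_a, b = sub_b, rate = cfg$mutation_rate,
      stringsAsFactors = FALSE) else NULL,
    homolog_map = NULL, mirnas = NULL, enriched_terms = NULL),
    class = "ground_truth")

  structure(list(config = cfg, transcripts = ts, seqs = seqs,
                 tx2gene = tx2gene, biotype = biotype,
                 gene_loci = gene_loci, lnc_loci = lnc_loci,
                 layout = layout, protein_db = protein_db,
                 reserved = reserved, ground_truth = gt),
            class = "genome_sim")
}

## an ORF drawn from the non-coding background composition: a valid
## reading frame with no internal stop, but without codon bias, so the
## hexamer and Fickett scorers still read it as non-coding
neutral_orf <- function(n_nt) {
  n_codons <- n_nt %/% 3L - 2L
  ok <- FALSE
  while (!ok) {
    body <- vapply(seq_len(n_codons), function(i) {
      repeat {
        cd <- random_seq(3L, c(A = .3, C = .2, G = .2, T = .3))
        if (!(cd %in% STOP_CODONS)) return(cd)
      }
    }, character(1))
    ok <- TRUE
  }
  paste0("ATG", paste0(body, collapse = ""), "TAA")
}

## kill long ORFs with the all-frame stop motif, but never stamp into a
## reserved window
kill_orfs_outside <- function(seq, reserved, max_orf = 149L,
                              max_iter = 60L + nchar(seq) %/% 50L) {
  w <- nchar(STOP_MOTIF)
  for (i in seq_len(max_iter)) {
    o <- longest_orf(seq)
    if (o$orf_length <= max_orf) return(seq)
    candidates <- o$start + seq(1L, max(1L, o$orf_length - w))
    candidates <- candidates[candidates + w - 1L <= nchar(seq)]
    ok <- vapply(candidates, function(p) {
      !any(vapply(reserved, function(iv) p <= iv[2L] &&
                    p + w - 1L >= iv[1L], logical(1)))
    }, logical(1))
    if (!any(ok)) return(seq)   # ORF lives inside a reserved window
    p <- candidates[ok][ceiling(sum(ok) / 2)]
    substr(seq, p, p + w - 1L) <- STOP_MOTIF
  }
  seq
}
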