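#!/usr/bin/env Rscript
## Conservation of the retained lncRNAs: homology search against the 13
## species panels and between the A/B/D sub-genomes (E < 1e-5, >= 60%
## identity over >= 30% of the shorter sequence), then a neighbour-
## joining tree with bootstrap for the most widely conserved lncRNA.
library(pollenlnc)

seqs <- read_fasta("results/corpus/transcripts.fa")
lnc <- read_gtf("results/lncrna.gtf")

lnc_seq <- seqs[lnc$transcript_id]
tx2g <- setNames(lnc$gene_id, lnc$transcript_id)

sp_files <- list.files("results/corpus/species", full.names = TRUE)
calls <- do.call(rbind, lapply(sp_files, function(f) {
  sp <- sub("\\.fa$", "", basename(f))
  subj <- read_fasta(f)
  hits <- homology_search(lnc_seq, subj)
  if (!nrow(hits)) return(NULL)
  cc <- call_conservation(hits, nchar(lnc_seq), nchar(subj))
  cc$species <- sp
  cc
}))
write.table(calls, "results/conservation_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
spec <- species_conservation(calls, tx2g)
cat(sprintf("%d of %d lncRNA loci conserved in at least one species; %d in >= 2, %d in >= 9\n",
            spec$n_conserved, length(unique(lnc$gene_id)),
            spec$n_two_or_more, spec$n_nine_or_more))
cat("Conserved loci per species:\n")
print(sort(spec$per_species, decreasing = TRUE))

lnc_loci <- unique(lnc[, c("gene_id", "chrom")])
one_seq <- lnc_seq[!duplicated(tx2g)]
names(one_seq) <- tx2g[!duplicated(tx2g)]
sub <- subgenome_conservation(lnc_loci, one_seq)
cat("Sub-genome overlap counts (AB / AD / BD / all three):\n")
print(sub$overlaps)

cons <- calls[calls$conserved, ]
by_q <- sort(table(cons$query_id), decreasing = TRUE)
focal <- names(by_q)[1]
hom <- cons[cons$query_id == focal, ]
hom <- hom[!duplicated(hom$species), ]
seqset <- c(setNames(seqs[focal], "Triticum_aestivum"),
            setNames(vapply(seq_len(nrow(hom)), function(i)
              read_fasta(file.path("results/corpus/species",
                                   paste0(hom$species[i], ".fa")))[[
                                     hom$subject_id[i]]], character(1)),
              hom$species))
res <- nj_tree(seqset, bootstrap = 1000, seed = 1)
write_newick(res$tree, "results/homolog_tree.nwk")
cat(sprintf("NJ tree for %s (%d species) written with bootstrap supports: %s\n",
            focal, nrow(hom),
            paste(stats::na.omit(res$support), collapse = " ")))
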