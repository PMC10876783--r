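#!/usr/bin/env Rscript
## cis and trans target inference for the DE lncRNAs: 10-gene windows,
## Pearson co-expression over each (cultivar, stage) cell's six samples,
## BH correction for the trans search, and the ndG <= -0.15
## hybridization filter on trans candidates.
library(pollenlnc)

ts <- read_gtf("results/corpus/annotation.gtf")
counts <- read_counts("results/corpus/counts.tsv")
design <- read_design("results/corpus/design.tsv")
seqs <- read_fasta("results/corpus/transcripts.fa")
lnc <- read_gtf("results/lncrna.gtf")
all_de <- read.delim("results/de_results.tsv")

tx2gene <- setNames(ts$gene_id, ts$transcript_id)
em <- cpm_filter(tmm_normalize(expression_matrix(
  aggregate_to_locus(counts, tx2gene), design)))
lnc_loci <- unique(lnc[, c("gene_id", "chrom", "start", "end")])
coding <- ts[ts$class_code == "=", ]
gene_loci <- unique(coding[, c("gene_id", "chrom", "start", "end")])
locus_seq <- seqs
names(locus_seq) <- tx2gene[names(locus_seq)]
locus_seq <- locus_seq[!duplicated(names(locus_seq))]

cells <- unique(all_de[, c("cultivar", "stage")])
edges <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
  rl <- all_de[all_de$cultivar == cells$cultivar[i] &
                 all_de$stage == cells$stage[i] &
                 all_de$biotype == "lncRNA", ]
  if (!any(rl$direction != "ns")) return(NULL)
  build_cis_trans(rl, lnc_loci, gene_loci, em, seqs = locus_seq)
}))
write.table(edges, "results/edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

s <- edge_summary(edges)
cat(sprintf("%d cis edges (%d lncRNAs -> %d neighbours), %d trans edges (%d lncRNAs -> %d genes)\n",
            sum(edges$mode == "cis"),
            length(unique(edges$lncrna_id[edges$mode == "cis"])),
            length(unique(edges$gene_id[edges$mode == "cis"])),
            sum(edges$mode == "trans"),
            length(unique(edges$lncrna_id[edges$mode == "trans"])),
            length(unique(edges$gene_id[edges$mode == "trans"]))))
cat(sprintf("cis distance density mode: %.0f bp\n", s$cis_distance_mode_bp))
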