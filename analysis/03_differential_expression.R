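#!/usr/bin/env Rscript
## Locus-level quantification and heat-vs-control differential
## expression per cultivar and stage: TMM normalization, CPM < 1 filter,
## the nonparametric (M, D) noise-distribution test with BH FDR, and the
## study-style summary tabulations.
library(pollenlnc)

ts <- read_gtf("results/corpus/annotation.gtf")
counts <- read_counts("results/corpus/counts.tsv")
design <- read_design("results/corpus/design.tsv")
lnc <- read_gtf("results/lncrna.gtf")

tx2gene <- setNames(ts$gene_id, ts$transcript_id)
em <- cpm_filter(tmm_normalize(expression_matrix(
  aggregate_to_locus(counts, tx2gene), design)))
biotype <- setNames(ifelse(rownames(em$counts) %in% unique(lnc$gene_id),
                           "lncRNA", "coding"), rownames(em$counts))

cells <- unique(design[, c("cultivar", "stage")])
results <- lapply(seq_len(nrow(cells)), function(i) {
  r <- noiseq_de(em, cells$cultivar[i], cells$stage[i], biotype = biotype)
  r$direction[r$biotype == "coding" & abs(r$log2fc) <= 1 &
                r$direction != "ns"] <- "ns"
  r
})
all_de <- do.call(rbind, results)
write.table(all_de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- summarize_de(results, em)
write.table(summ$updown_counts, "results/de_updown.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$top_variance, "results/top_variance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

de <- all_de[all_de$direction != "ns", ]
cat(sprintf("%d loci tested; %d DE lncRNAs, %d DE coding genes\n",
            nrow(em$counts),
            length(unique(de$gene_id[de$biotype == "lncRNA"])),
            length(unique(de$gene_id[de$biotype == "coding"]))))
cat("Up/down counts per cultivar and stage:\n")
print(summ$updown_counts[summ$updown_counts$count > 0, ])
cat(sprintf("lncRNAs DE with the same direction in both stages: %d\n",
            summ$stage_overlap_concordant))
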