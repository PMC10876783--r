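#!/usr/bin/env Rscript
## Classic Fisher GO enrichment of the lncRNA target genes (cis + trans
## edges and miRNA-module mRNAs) against the expressed-gene universe,
## with true-path annotation propagation and depth-2 parent rollup.
library(pollenlnc)

ts <- read_gtf("results/corpus/annotation.gtf")
counts <- read_counts("results/corpus/counts.tsv")
design <- read_design("results/corpus/design.tsv")
dag <- read_obo("results/corpus/ontology.obo")
gene2go <- read_gene2go("results/corpus/gene2go.tsv")
edges <- read.delim("results/edges.tsv")
modules <- read.delim("results/modules.tsv")

tx2gene <- setNames(ts$gene_id, ts$transcript_id)
em <- cpm_filter(tmm_normalize(expression_matrix(
  aggregate_to_locus(counts, tx2gene), design)))
closure <- propagate_annotations(gene2go, dag)
population <- intersect(rownames(em$counts), names(gene2go))
study <- intersect(unique(c(edges$gene_id, modules$mrna_id)), population)

rows <- fisher_enrich(study, population, closure)
rows <- rollup_terms(rows, dag, max_depth = 2)
write.table(rows, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d target genes against a universe of %d; %d terms tested, %d significant (p < 0.05)\n",
            length(study), length(population), nrow(rows),
            sum(rows$significant)))
cat("Significant terms and their rollup parents:\n")
print(rows[rows$significant,
           c("term_id", "study_count", "population_count", "p_fisher",
             "parent_term")])
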