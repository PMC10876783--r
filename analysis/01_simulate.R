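#!/usr/bin/env Rscript
## Build the synthetic study corpus: an annotated toy wheat genome with
## coding and lncRNA loci on A/B/D chromosomes, a 4-cultivar x 2-stage x
## 2-condition x 3-replicate count matrix, miRNAs, 13 species of lncRNA
## homolog sets, and GO annotations -- all with planted ground truth.
library(pollenlnc)

cfg <- simulation_config(seed = 1)
sim <- simulate_study(cfg, outdir = "results/corpus")

cat("Corpus written to results/corpus\n")
cat(sprintf("  %d transcripts (%d coding loci, %d lncRNA loci) on %d chromosomes\n",
            nrow(sim$transcripts), nrow(sim$gene_loci), nrow(sim$lnc_loci),
            length(unique(sim$transcripts$chrom))))
cat(sprintf("  %d samples; %d planted DE calls over %d loci\n",
            nrow(sim$design), nrow(sim$ground_truth$de_table),
            length(unique(sim$ground_truth$de_table$gene_id))))
cat(sprintf("  planted: %d sponge and %d precursor triples (%d and %d triple-contrast rows), %d cis pairs, %d trans pairs\n",
            length(unique(sim$ground_truth$sponge_triples$lncrna_id)),
            length(unique(sim$ground_truth$precursor_triples$lncrna_id)),
            nrow(sim$ground_truth$sponge_triples),
            nrow(sim$ground_truth$precursor_triples),
            nrow(sim$ground_truth$cis_pairs),
            nrow(sim$ground_truth$trans_pairs)))
cat(sprintf("  mean lncRNA length %.0f nt vs coding %.0f nt\n",
            mean(nchar(sim$seqs[paste0(sim$lnc_loci$gene_id, ".1")])),
            mean(nchar(sim$seqs[paste0(sim$gene_loci$gene_id, ".1")]))))
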