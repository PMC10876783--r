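#!/usr/bin/env Rscript
## lncRNA-miRNA-mRNA regulatory modules: plant-rule target scanning of
## the DE lncRNAs and DE mRNAs against the miRNA panel, then sponge
## (concordant trends) vs precursor (perfect complement, opposite
## trends) classification.
library(pollenlnc)

ts <- read_gtf("results/corpus/annotation.gtf")
seqs <- read_fasta("results/corpus/transcripts.fa")
mirnas <- read_fasta("results/corpus/mirnas.fa")
lnc <- read_gtf("results/lncrna.gtf")
all_de <- read.delim("results/de_results.tsv")

tx2gene <- setNames(ts$gene_id, ts$transcript_id)
locus_seq <- seqs
names(locus_seq) <- tx2gene[names(locus_seq)]
locus_seq <- locus_seq[!duplicated(names(locus_seq))]
de_ids <- unique(all_de$gene_id[all_de$direction != "ns"])
lnc_ids <- intersect(de_ids, unique(lnc$gene_id))
mrna_ids <- intersect(de_ids,
                      unique(ts$gene_id[ts$class_code == "="]))

lnc_hits <- scan_mirna_targets(mirnas, locus_seq[lnc_ids])
mrna_hits <- scan_mirna_targets(mirnas, locus_seq[mrna_ids],
                                rna_class = "mRNA")
modules <- classify_modules(lnc_hits, mrna_hits, all_de)
write.table(modules, "results/modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

s <- module_summary(modules)
cat("Per-role counts (lncRNA / miRNA / mRNA / modules):\n")
print(s$counts)
if (nrow(s$shared)) {
  cat("Modules shared by two or more cultivars:\n")
  print(s$shared)
}
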