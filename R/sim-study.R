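#' Simulate the complete study corpus
#'
#' Runs the three generator stages in order — genome/annotation, miRNA +
#' homolog + GO extras, then counts — and optionally writes every file
#' the analysis consumes (GTF, FASTA, counts and design TSVs, miRNA and
#' per-species FASTA, gene-to-GO TSV, OBO, protein FASTA) plus the
#' ground-truth tables. With a fixed config the corpus is fully
#' reproducible.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; created if missing.
#' @param write_genome also assemble and write the genome FASTA (the
#'   chromosome sequences are only needed when a consumer wants them).
#' @return list of class `study_corpus`: the `genome_sim` fields plus
#'   `counts`, `design`, `mu` and, when written, `paths`.
#' @export
simulate_study <- function(config, outdir = NULL, write_genome = FALSE) {
  sim <- simulate_genome(config)
  sim <- simulate_mirnas_and_homologs(config, sim)
  cc <- simulate_counts(config, sim)
  sim$counts <- cc$counts
  sim$design <- cc$design
  sim$mu <- cc$mu
  class(sim) <- c("study_corpus", class(sim))
  if (!is.null(outdir)) {
    sim$paths <- write_study(sim, outdir, write_genome)
  }
  sim
}

write_study <- function(sim, outdir, write_genome = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$gtf <- write_gtf(sim$transcripts, file.path(outdir, "annotation.gtf"))
  p$transcripts <- write_fasta(sim$seqs,
                               file.path(outdir, "transcripts.fa"))
  p$counts <- write_counts(sim$counts, file.path(outdir, "counts.tsv"),
                           id_col = "transcript_id")
  p$design <- write_design(sim$design, file.path(outdir, "design.tsv"))
  p$mirnas <- write_fasta(sim$mirnas, file.path(outdir, "mirnas.fa"))
  p$proteins <- write_fasta(sim$protein_db,
                            file.path(outdir, "proteins.fa"))
  sp_dir <- file.path(outdir, "species")
  dir.create(sp_dir, showWarnings = FALSE)
  p$species <- vapply(names(sim$species_sets), function(sp) {
    write_fasta(sim$species_sets[[sp]], file.path(sp_dir,
                                                  paste0(sp, ".fa")))
  }, character(1))
  p$gene2go <- write_gene2go(sim$go$gene2go,
                             file.path(outdir, "gene2go.tsv"))
  p$obo <- write_obo(sim$go$dag, file.path(outdir, "ontology.obo"))
  gt_dir <- file.path(outdir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (nm in c("de_table", "cis_pairs", "trans_pairs", "sponge_triples",
               "precursor_triples", "subgenome_pairs", "homolog_map",
               "mirnas")) {
    x <- sim$ground_truth[[nm]]
    if (!is.null(x))
      write.table(x, file.path(gt_dir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  if (write_genome) {
    p$genome <- write_fasta(build_genome_seqs(sim),
                            file.path(outdir, "genome.fa"))
  }
  p
}

#' Assemble chromosome sequences from the layout plan
#'
#' Concatenates intergenic background, exon sequence (the current spliced
#' transcript sequence, so planted site edits are reflected) and introns
#' per chromosome. The annotated strand is a label; genomic exon content
#' equals the spliced sequence read on the forward strand.
#'
#' @param sim a `study_corpus` / `genome_sim`.
#' @return named character vector chromosome -> sequence.
#' @export
build_genome_seqs <- function(sim) {
  with_seed(sim$config$seed + 3L, {
    out <- character(0)
    for (ch in names(sim$layout)) {
      pieces <- character(0)
      for (pl in sim$layout[[ch]]) {
        pieces <- c(pieces, random_seq(pl$gap))
        tid <- paste0(pl$gene, ".",
                      1L)
        s <- sim$seqs[[tid]]
        if (!is.na(pl$exon_split)) {
          pieces <- c(pieces, substr(s, 1L, pl$exon_split), pl$intron,
                      substr(s, pl$exon_split + 1L, nchar(s)))
        } else {
          pieces <- c(pieces, s)
        }
      }
      out[ch] <- paste0(pieces, collapse = "")
    }
    out
  })
}
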