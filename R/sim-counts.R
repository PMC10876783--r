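#' Simulate the per-sample count matrix and design
#'
#' Negative-binomial counts at the transcript level over the full design
#' (cultivar x stage x condition x replicate). Unplanted genes share one
#' dispersion; planted differentially expressed loci have their heat-cell
#' means multiplied by 2^(+/- log2FC); planted cis/trans pairs share a
#' per-sample latent factor inside their contrast cell, with low
#' dispersion, so the population correlation of the pair is >= 0.9;
#' lncRNA baseline means sit below coding means; a slice of lncRNAs is
#' planted below the CPM filter.
#'
#' @param config a [simulation_config()].
#' @param sim a `genome_sim`.
#' @return list with `counts` (transcripts x samples), `design`, `mu`
#'   (expected values actually used).
#' @export
simulate_counts <- function(config, sim) {
  with_seed(config$seed + 1L, simulate_counts_impl(config, sim))
}

simulate_counts_impl <- function(cfg, sim) {
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        condition = cfg$conditions,
                        stage = cfg$stages,
                        cultivar = cfg$cultivars,
                        stringsAsFactors = FALSE)
  design <- design[, c("cultivar", "stage", "condition", "replicate")]
  design$sample <- with(design, paste(cultivar, substr(stage, 1, 3),
                                      substr(condition, 1, 3), replicate,
                                      sep = "_"))
  n_s <- nrow(design)
  tx <- sim$transcripts$transcript_id
  gt <- sim$ground_truth
  locus <- sim$tx2gene[tx]
  is_lnc <- sim$biotype[locus] == "lncRNA"

  ## baseline means: lncRNAs lower than coding
  base <- ifelse(is_lnc,
                 rlnorm(length(tx), meanlog = log(40), sdlog = 0.6),
                 rlnorm(length(tx), meanlog = log(150), sdlog = 0.5))
  names(base) <- tx
  ## planted differentially expressed loci get solid baselines so their
  ## (M, D) signal clears the pooled noise at three replicates;
  ## down-regulated loci start higher, since their |D| is bounded by the
  ## control mean
  de_dir <- tapply(gt$de_table$direction, gt$de_table$gene_id,
                   function(x) x[1L])
  up_loci <- names(de_dir)[de_dir == "up"]
  down_loci <- names(de_dir)[de_dir == "down"]
  base[locus %in% up_loci] <-
    rlnorm(sum(locus %in% up_loci), meanlog = log(400), sdlog = 0.25)
  base[locus %in% down_loci] <-
    rlnorm(sum(locus %in% down_loci), meanlog = log(2500), sdlog = 0.2)
  ## loci planted below the CPM filter sit well below one count per
  ## sample, as the sub-CPM tail does on real libraries
  low_tx <- tx[locus %in% gt$low_expressed]
  base[low_tx] <- runif(length(low_tx), 0.005, 0.08)
  base <- pmax(base, 5)
  base[low_tx] <- pmin(base[low_tx], 0.08)
  ## mean-dispersion trend: biological dispersion shrinks with
  ## expression, as in real RNA-seq; cfg$nb_dispersion sets the scale at
  ## the lncRNA reference mean of 40
  disp <- setNames(0.005 + cfg$nb_dispersion * 20 / base, tx)
  disp <- pmin(disp, 0.3)

  mu <- matrix(base, nrow = length(tx), ncol = n_s,
               dimnames = list(tx, design$sample))
  cell_of <- paste(design$cultivar, design$stage)
  heat <- design$condition == "heat"

  ## planted differential expression
  for (i in seq_len(nrow(gt$de_table))) {
    r <- gt$de_table[i, ]
    cols <- cell_of == paste(r$cultivar, r$stage) & heat
    rows <- which(locus == r$gene_id)
    fold <- 2^(if (r$direction == "up") r$true_log2fc else -r$true_log2fc)
    mu[rows, cols] <- mu[rows, cols] * fold
  }

  ## planted co-expression pairs: the pair's population correlation over
  ## its cell's six samples comes mostly from the shared heat response
  ## (both members are planted DE in the same cells with one direction),
  ## topped up by a small shared latent factor and tight dispersion so
  ## the within-condition residuals co-vary too; the resulting r ~ 0.99
  ## samples |r| > 0.81 at n = 6 essentially always, without injecting
  ## large within-condition noise into the DE test's noise pool
  plant_pair <- function(lnc, gene, cultivar, stage, sd_log2, d) {
    cols <- which(cell_of == paste(cultivar, stage))
    z <- rnorm(length(cols), sd = sd_log2)
    rows <- which(locus %in% c(lnc, gene))
    scale <- pmax(base[rows], 1200) / base[rows]
    mu[rows, ] <<- mu[rows, ] * scale
    mu[rows, cols] <<- mu[rows, cols] *
      matrix(2^z, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    disp[tx[rows]] <<- d
  }
  if (!is.null(gt$cis_pairs)) {
    for (i in seq_len(nrow(gt$cis_pairs))) {
      p <- gt$cis_pairs[i, ]
      plant_pair(p$lncrna_id, p$gene_id, p$cultivar, p$stage,
                 sd_log2 = 0.15, d = 0.003)
    }
  }
  if (!is.null(gt$trans_pairs)) {
    for (i in seq_len(nrow(gt$trans_pairs))) {
      p <- gt$trans_pairs[i, ]
      plant_pair(p$lncrna_id, p$gene_id, p$cultivar, p$stage,
                 sd_log2 = 0.15, d = 0.003)
    }
  }

  depth <- runif(n_s, 0.8, 1.25)
  mu_eff <- t(t(mu) * depth)
  counts <- matrix(rnbinom(length(mu_eff), mu = mu_eff,
                           size = 1 / disp[rep(seq_along(tx), n_s)]),
                   nrow = length(tx), dimnames = dimnames(mu))
  list(counts = counts, design = design, mu = mu)
}
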