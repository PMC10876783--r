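#' Nonparametric noise-distribution differential expression test
#'
#' For a heat-vs-control contrast within one (cultivar, stage) cell, the
#' per-gene signal is M = log2(mean_heat / mean_control) and
#' D = |mean_heat - mean_control| on TMM-normalized CPM with a 0.5
#' count-scale pseudocount. The noise distribution pools (M, D) from every
#' within-condition replicate pair of the two contrast groups across all
#' genes. A gene's probability of differential expression is the fraction
#' of noise points it dominates (|M_noise| < |M_gene| and
#' D_noise < D_gene); the empirical p-value is the add-one complement
#' (1 + #non-dominated) / (1 + #noise points), and FDR is Benjamini-
#' Hochberg across genes.
#'
#' Direction calls follow the lncRNA rule by default: `up` requires
#' log2FC > `lfc_threshold` and FDR <= `fdr_threshold` (`down`
#' symmetric). Coding genes conventionally use `lfc_threshold = 1`.
#'
#' @param em a filtered, TMM-normalized `expr_matrix`.
#' @param cultivar,stage the contrast cell.
#' @param lfc_threshold |log2FC| needed for an up/down call.
#' @param fdr_threshold FDR needed for an up/down call.
#' @param biotype optional named vector gene -> {"lncRNA", "coding"};
#'   recorded in the result.
#' @return data.frame of class `de_result`: `gene_id`, `cultivar`,
#'   `stage`, `log2fc`, `d_stat`, `de_probability`, `p_value`, `fdr`,
#'   `direction`, `biotype`.
#' @export
noiseq_de <- function(em, cultivar, stage, lfc_threshold = 0.5,
                      fdr_threshold = 0.05, biotype = NULL) {
  grp <- contrast_samples(em, cultivar, stage)
  if (length(grp$heat) < 2L || length(grp$control) < 2L)
    stopf("contrast %s:%s needs >= 2 replicates per condition",
          cultivar, stage)
  ## 0.5 pseudocount on the count scale before normalization, so the
  ## log-ratio of near-zero genes is damped on every library size
  eff <- em$lib_sizes * em$tmm
  cpm <- t(t(em$counts + 0.5) / eff) * 1e6
  x_heat <- cpm[, grp$heat, drop = FALSE]
  x_ctrl <- cpm[, grp$control, drop = FALSE]
  mu_h <- rowMeans(x_heat)
  mu_c <- rowMeans(x_ctrl)
  m_sig <- log2(mu_h / mu_c)
  d_sig <- abs(mu_h - mu_c)
  ## noise: all within-condition replicate pairs, all genes
  noise_m <- numeric(0); noise_d <- numeric(0)
  for (x in list(x_heat, x_ctrl)) {
    pairs <- combn(ncol(x), 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- x[, pairs[1L, k]]; b <- x[, pairs[2L, k]]
      noise_m <- c(noise_m, log2(a / b))
      noise_d <- c(noise_d, abs(a - b))
    }
  }
  prob <- dominance_probability(abs(m_sig), d_sig, abs(noise_m), noise_d)
  n_noise <- length(noise_m)
  p <- (1 + round((1 - prob) * n_noise)) / (1 + n_noise)
  fdr <- p.adjust(p, method = "BH")
  direction <- rep("ns", length(m_sig))
  direction[m_sig > lfc_threshold & fdr <= fdr_threshold] <- "up"
  direction[m_sig < -lfc_threshold & fdr <= fdr_threshold] <- "down"
  bt <- if (is.null(biotype)) NA_character_ else
    unname(biotype[rownames(cpm)])
  out <- data.frame(gene_id = rownames(cpm), cultivar = cultivar,
                    stage = stage, log2fc = m_sig, d_stat = d_sig,
                    de_probability = prob, p_value = p, fdr = fdr,
                    direction = direction, biotype = bt,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

## fraction of noise points strictly dominated by each signal point,
## computed by sorting + binary search instead of an outer product
dominance_probability <- function(abs_m, d, noise_abs_m, noise_d) {
  n <- length(noise_abs_m)
  if (n == 0L) stopf("empty noise distribution")
  ord <- order(noise_abs_m)
  nm <- noise_abs_m[ord]
  nd <- noise_d[ord]
  ## for each signal point, among noise with |M| < |M_sig| count D < D_sig;
  ## do it with a loop over signal points on cumulative structures
  res <- numeric(length(abs_m))
  ## process signal points in order of |M|; maintain a sorted container of
  ## noise D values whose |M| is below the current signal |M|
  sig_ord <- order(abs_m)
  inserted <- 0L
  pool <- numeric(n)
  for (i in sig_ord) {
    while (inserted < n && nm[inserted + 1L] < abs_m[i]) {
      inserted <- inserted + 1L
      pool[inserted] <- nd[inserted]
    }
    if (inserted == 0L) {
      res[i] <- 0
    } else {
      res[i] <- sum(pool[seq_len(inserted)] < d[i]) / n
    }
  }
  res
}
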