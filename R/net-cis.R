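#' Protein-coding genes in the cis window of a lncRNA locus
#'
#' Returns up to `k` protein-coding genes upstream and `k` downstream of
#' the lncRNA locus on the same chromosome, by genomic order and ignoring
#' strand (fewer near chromosome ends). `distance_bp` is the signed gap
#' between closest edges: negative for genes upstream of the locus, 0 when
#' overlapping.
#'
#' @param lnc_locus one-row data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param genes data.frame of protein-coding loci with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param k window half-width in genes.
#' @return data.frame `gene_id`, `side` ("upstream"/"downstream"),
#'   `distance_bp`; empty when the chromosome has no coding genes.
#' @export
cis_window <- function(lnc_locus, genes, k = 10L) {
  g <- genes[genes$chrom == lnc_locus$chrom, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), side = character(0),
                      distance_bp = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(g)) return(empty)
  g <- g[order(g$start, g$end), , drop = FALSE]
  before <- which(g$end <= lnc_locus$start)
  after <- which(g$start >= lnc_locus$end)
  overlap <- setdiff(seq_len(nrow(g)), c(before, after))
  up <- utils::tail(before, k)
  down <- head(after, k)
  idx <- c(up, overlap, down)
  if (!length(idx)) return(empty)
  side <- c(rep("upstream", length(up)), rep("overlap", length(overlap)),
            rep("downstream", length(down)))
  dist <- numeric(length(idx))
  dist[side == "upstream"] <- g$end[up] - lnc_locus$start    # negative gap
  dist[side == "overlap"] <- 0
  dist[side == "downstream"] <- g$start[down] - lnc_locus$end
  data.frame(gene_id = g$gene_id[idx], side = side, distance_bp = dist,
             stringsAsFactors = FALSE)
}

#' Build cis and trans regulatory edges from co-expression
#'
#' For each contrast cell (cultivar, stage), correlates every
#' differentially expressed lncRNA with protein-coding genes over that
#' cell's samples (condition x replicate, n = 6 under the default design).
#' Cis edges (gene inside the 10-gene window) are kept at p < 0.05; trans
#' edges (outside the window) are Benjamini-Hochberg corrected across all
#' trans tests of the cell and kept at q < 0.05, then filtered by
#' hybridization energy ndG <= `ndg_cutoff`.
#'
#' @param de_lnc `de_result` rows for lncRNAs (one contrast cell).
#' @param lnc_loci data.frame of lncRNA loci (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param gene_loci data.frame of protein-coding loci.
#' @param em TMM-normalized `expr_matrix` containing both biotypes.
#' @param seqs named character vector of sequences (lncRNA and gene ids)
#'   for the ndG filter; pass `NULL` to skip the filter.
#' @param k cis window half-width in genes.
#' @param alpha significance level for p (cis) and q (trans).
#' @param ndg_cutoff retain trans edges with ndG <= this value.
#' @return data.frame of class `edge_table`: `lncrna_id`, `gene_id`,
#'   `mode`, `cultivar`, `stage`, `r`, `p`, `q`, `distance_bp`, `ndg`.
#' @export
build_cis_trans <- function(de_lnc, lnc_loci, gene_loci, em, seqs = NULL,
                            k = 10L, alpha = 0.05, ndg_cutoff = -0.15) {
  stopifnot(nrow(de_lnc) > 0)
  cultivar <- de_lnc$cultivar[1L]
  stage <- de_lnc$stage[1L]
  grp <- contrast_samples(em, cultivar, stage)
  cols <- c(grp$heat, grp$control)
  expr <- log2(cpm_matrix(em)[, cols, drop = FALSE] + 1)
  lnc_ids <- intersect(unique(de_lnc$gene_id[de_lnc$direction != "ns"]),
                       rownames(expr))
  gene_ids <- intersect(gene_loci$gene_id, rownames(expr))
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), cultivar = character(0),
                      stage = character(0), r = numeric(0), p = numeric(0),
                      q = numeric(0), distance_bp = numeric(0),
                      ndg = numeric(0), stringsAsFactors = FALSE)
  if (!length(lnc_ids) || !length(gene_ids)) {
    class(empty) <- c("edge_table", "data.frame")
    return(empty)
  }
  xl <- t(expr[lnc_ids, , drop = FALSE])
  xg <- t(expr[gene_ids, , drop = FALSE])
  ok_l <- apply(xl, 2L, sd) > 0
  ok_g <- apply(xg, 2L, sd) > 0
  xl <- xl[, ok_l, drop = FALSE]; xg <- xg[, ok_g, drop = FALSE]
  if (!ncol(xl) || !ncol(xg)) {
    class(empty) <- c("edge_table", "data.frame")
    return(empty)
  }
  n <- nrow(xl)
  rmat <- cor(xl, xg)
  rmat <- pmin(pmax(rmat, -1), 1)
  tmat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- 2 * pt(-abs(tmat), df = n - 2)
  pmat[rmat^2 >= 1] <- 0
  ## neighbourhood membership and signed distances
  in_win <- matrix(FALSE, nrow = ncol(xl), ncol = ncol(xg),
                   dimnames = dimnames(rmat))
  dist_bp <- matrix(NA_real_, nrow = ncol(xl), ncol = ncol(xg),
                    dimnames = dimnames(rmat))
  for (lid in rownames(in_win)) {
    locus <- lnc_loci[lnc_loci$gene_id == lid, , drop = FALSE]
    if (!nrow(locus)) next
    win <- cis_window(locus[1L, ], gene_loci, k)
    hit <- intersect(win$gene_id, colnames(in_win))
    in_win[lid, hit] <- TRUE
    dist_bp[lid, hit] <- win$distance_bp[match(hit, win$gene_id)]
  }
  pairs <- which(!is.na(rmat), arr.ind = TRUE)
  df <- data.frame(lncrna_id = rownames(rmat)[pairs[, 1L]],
                   gene_id = colnames(rmat)[pairs[, 2L]],
                   r = rmat[pairs], p = pmat[pairs],
                   cis = in_win[pairs], distance_bp = dist_bp[pairs],
                   stringsAsFactors = FALSE)
  cis <- df[df$cis & df$p < alpha, , drop = FALSE]
  cis_out <- if (nrow(cis)) data.frame(
    lncrna_id = cis$lncrna_id, gene_id = cis$gene_id, mode = "cis",
    cultivar = cultivar, stage = stage, r = cis$r, p = cis$p, q = NA_real_,
    distance_bp = cis$distance_bp, ndg = NA_real_,
    stringsAsFactors = FALSE) else empty
  tr <- df[!df$cis, , drop = FALSE]
  tr_out <- empty
  if (nrow(tr)) {
    tr$q <- bh_adjust(tr$p)
    tr <- tr[tr$q < alpha, , drop = FALSE]
    if (nrow(tr)) {
      ndg <- rep(NA_real_, nrow(tr))
      keep <- rep(TRUE, nrow(tr))
      if (!is.null(seqs)) {
        for (i in seq_len(nrow(tr))) {
          ndg[i] <- ndg_score(seqs[[tr$lncrna_id[i]]],
                              seqs[[tr$gene_id[i]]])
          keep[i] <- ndg[i] <= ndg_cutoff
        }
      }
      tr <- tr[keep, , drop = FALSE]; ndg <- ndg[keep]
      if (nrow(tr)) {
        tr_out <- data.frame(
          lncrna_id = tr$lncrna_id, gene_id = tr$gene_id, mode = "trans",
          cultivar = cultivar, stage = stage, r = tr$r, p = tr$p,
          q = tr$q, distance_bp = NA_real_, ndg = ndg,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(cis_out, tr_out)
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Summaries of a cis/trans edge table
#'
#' Per-cultivar lncRNA and target counts, a targets-per-lncRNA histogram
#' and the cis distance distribution with its density mode.
#'
#' @param edges an `edge_table` (possibly several contrasts bound
#'   together).
#' @return list with `per_cultivar`, `targets_per_lncrna`,
#'   `cis_distance_mode_bp`.
#' @export
edge_summary <- function(edges) {
  per_cultivar <- do.call(rbind, lapply(
    split(edges, list(edges$cultivar, edges$mode), drop = TRUE),
    function(e) data.frame(cultivar = e$cultivar[1L], mode = e$mode[1L],
                           n_lncrna = length(unique(e$lncrna_id)),
                           n_targets = length(unique(e$gene_id)),
                           n_edges = nrow(e), stringsAsFactors = FALSE)))
  tgt <- table(table(paste(edges$lncrna_id, edges$cultivar)))
  cis_d <- abs(edges$distance_bp[edges$mode == "cis"])
  mode_bp <- if (length(cis_d) >= 2L) {
    d <- stats::density(cis_d)
    d$x[which.max(d$y)]
  } else NA_real_
  list(per_cultivar = per_cultivar,
       targets_per_lncrna = tgt,
       cis_distance_mode_bp = mode_bp)
}
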