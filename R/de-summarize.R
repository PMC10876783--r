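#' Summary tabulations of differential-expression results
#'
#' Produces the study's reporting tables from a set of per-contrast DE
#' results: per-cultivar/stage up- and down-regulated counts, cultivar
#' overlap sets per stage (sensitive pair, tolerant pair, all four),
#' stage-overlap counts with concordant direction, and the top-K genes by
#' variance of normalized log2 expression for heatmapping.
#'
#' @param results list of `de_result` data.frames (one per contrast).
#' @param em the `expr_matrix` the results came from (for the variance
#'   ranking).
#' @param sensitive cultivars of the heat-sensitive pair.
#' @param tolerant cultivars of the heat-tolerant pair.
#' @param top_k number of most-variable genes to report.
#' @return list with `updown_counts`, `cultivar_overlap`,
#'   `stage_overlap_concordant`, `top_variance`.
#' @export
summarize_de <- function(results, em, sensitive = c("cr", "wk"),
                         tolerant = c("ha", "yo"), top_k = 1000L) {
  all <- do.call(rbind, results)
  de <- all[all$direction != "ns", , drop = FALSE]
  updown <- as.data.frame(table(cultivar = de$cultivar, stage = de$stage,
                                direction = de$direction))
  names(updown)[4] <- "count"

  de_sets <- function(stage) {
    lapply(split(de$gene_id[de$stage == stage], de$cultivar[de$stage == stage]),
           unique)
  }
  overlap_row <- function(stage) {
    s <- de_sets(stage)
    get <- function(cv) if (cv %in% names(s)) s[[cv]] else character(0)
    inter <- function(cvs) length(Reduce(intersect, lapply(cvs, get)))
    data.frame(stage = stage,
               sensitive_pair = if (length(sensitive) == 2L)
                 inter(sensitive) else NA_integer_,
               tolerant_pair = if (length(tolerant) == 2L)
                 inter(tolerant) else NA_integer_,
               all_cultivars = inter(unique(de$cultivar)),
               stringsAsFactors = FALSE)
  }
  stages <- unique(de$stage)
  cultivar_overlap <- do.call(rbind, lapply(stages, overlap_row))

  ## genes DE in both stages of the same cultivar with the same direction
  key <- paste(de$gene_id, de$cultivar, de$direction)
  conc <- 0L
  if (length(stages) >= 2L) {
    k1 <- unique(key[de$stage == stages[1L]])
    k2 <- unique(key[de$stage == stages[2L]])
    conc <- length(intersect(k1, k2))
  }

  expr <- log2(cpm_matrix(em) + 1)
  v <- apply(expr, 1L, var)
  top <- head(order(v, decreasing = TRUE), top_k)
  top_variance <- data.frame(gene_id = rownames(expr)[top],
                             variance = v[top], stringsAsFactors = FALSE,
                             row.names = NULL)
  list(updown_counts = updown,
       cultivar_overlap = cultivar_overlap,
       stage_overlap_concordant = conc,
       top_variance = top_variance)
}
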