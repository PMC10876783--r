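#' Expression matrix with sample design
#'
#' Genes-by-samples counts plus the sample design (cultivar, stage,
#' condition, replicate). TMM normalization factors are attached by
#' [tmm_normalize()].
#'
#' @param counts non-negative numeric matrix, rows = genes, columns =
#'   samples.
#' @param design data.frame with columns `sample`, `cultivar`, `stage`,
#'   `condition`, `replicate`; `sample` must match `colnames(counts)`.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(counts, design) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (is.null(colnames(counts))) stopf("counts need sample column names")
  if (!setequal(colnames(counts), design$sample))
    stopf("design samples do not match count columns")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  structure(list(counts = counts,
                 design = design,
                 lib_sizes = colSums(counts),
                 tmm = rep(1, ncol(counts))),
            class = "expr_matrix")
}

#' Aggregate transcript counts to locus (gene) level
#'
#' Gene count = sum of member-transcript counts per sample.
#'
#' @param counts transcripts-by-samples matrix.
#' @param tx2gene named character vector transcript_id -> gene_id covering
#'   every row of `counts`.
#' @return genes-by-samples matrix.
#' @export
aggregate_to_locus <- function(counts, tx2gene) {
  unmapped <- setdiff(rownames(counts), names(tx2gene))
  if (length(unmapped))
    stopf("unmapped transcript(s): %s",
          paste(head(unmapped, 5L), collapse = ", "))
  g <- tx2gene[rownames(counts)]
  out <- rowsum(counts, group = g, reorder = TRUE)
  out
}

## samples belonging to one (cultivar, stage) cell, split by condition
contrast_samples <- function(em, cultivar, stage,
                             conditions = c("heat", "control")) {
  d <- em$design
  sel <- d$cultivar == cultivar & d$stage == stage
  if (!any(sel)) stopf("no samples for contrast %s:%s", cultivar, stage)
  lapply(setNames(conditions, conditions),
         function(cc) d$sample[sel & d$condition == cc])
}
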