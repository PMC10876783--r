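#' Read a counts TSV (rows = genes, columns = samples)
#' @param path path to a TSV whose first column is the gene/transcript id.
#' @return numeric matrix with ids as rownames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stopf("negative counts in %s", path)
  m
}

#' Write a counts matrix as TSV
#' @param counts numeric matrix with rownames.
#' @param path output path.
#' @param id_col name of the id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design TSV
#'
#' Columns: `sample`, `cultivar`, `stage`, `condition`, `replicate`.
#'
#' @param path path to the design TSV.
#' @return data.frame.
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "cultivar", "stage", "condition", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("design missing column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' Write a sample design TSV
#' @param design data.frame as returned by [read_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation TSV
#' @param path TSV with columns `gene_id`, `term_id`.
#' @return named list gene -> character vector of term ids.
#' @export
read_gene2go <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stopf("annotation TSV needs columns gene_id, term_id")
  split(df$term_id, df$gene_id)
}

#' Write a gene-to-GO annotation TSV
#' @param gene2go named list gene -> term ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene2go <- function(gene2go, path) {
  df <- data.frame(gene_id = rep(names(gene2go), lengths(gene2go)),
                   term_id = unlist(gene2go, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in newick format
#'
#' Thin wrapper over [ape::write.tree()] so every module writes trees the
#' same way; bootstrap supports stored as node labels are preserved.
#'
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
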