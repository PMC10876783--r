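#' Neighbour-joining tree of a homolog set with bootstrap support
#'
#' Builds a reference-anchored pseudo-alignment: every sequence is
#' globally aligned to the first (the wheat lncRNA), and the character at
#' each reference position is recorded, giving a sequences x positions
#' matrix. Pairwise distances are mismatch proportions over columns where
#' both rows are ungapped (1 - identity); the tree is Saitou-Nei
#' neighbour joining and supports come from resampling alignment columns
#' with replacement.
#'
#' @param seqs named character vector, first element is the anchor.
#' @param bootstrap number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return list of class `nj_result`: `tree` (an `ape::phylo` with
#'   bootstrap percentages as node labels), `support`, `distances`,
#'   `alignment` (the character matrix).
#' @export
nj_tree <- function(seqs, bootstrap = 1000L, seed = 1L) {
  if (length(seqs) < 3L) stopf("NJ needs >= 3 sequences")
  aln <- anchor_alignment(seqs)
  d <- alignment_distances(aln)
  tree <- ape::nj(as.dist(d))
  boot <- with_seed(seed, ape::boot.phylo(
    tree, aln, function(x) ape::nj(as.dist(alignment_distances(x))),
    B = bootstrap, rooted = FALSE, quiet = TRUE))
  support <- round(100 * boot / bootstrap)
  tree$node.label <- as.character(support)
  structure(list(tree = tree, support = support, distances = d,
                 alignment = aln),
            class = "nj_result")
}

## rows = sequences, columns = anchor positions; "-" where a sequence has
## no base aligned to that anchor position
anchor_alignment <- function(seqs) {
  anchor <- seqs[[1L]]
  n <- nchar(anchor)
  mat <- matrix("-", nrow = length(seqs), ncol = n,
                dimnames = list(names(seqs), NULL))
  mat[1L, ] <- seq_chars(anchor)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  for (i in 2:length(seqs)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = anchor, subject = seqs[[i]], type = "global",
      substitutionMatrix = sub_mat, gapOpening = 4, gapExtension = 1)
    p_ch <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    s_ch <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    keep <- p_ch != "-"
    mat[i, ] <- s_ch[keep]
  }
  mat
}

## mismatch proportion over columns where both rows have a base
alignment_distances <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok))
        mean(aln[i, ok] != aln[j, ok]) else 1
    }
  }
  d
}

#' Neighbour joining from a precomputed distance matrix
#'
#' Convenience wrapper over [ape::nj()] used for distance-level checks
#' (e.g. additive four-taxon matrices).
#'
#' @param d symmetric distance matrix with labelled rows.
#' @return an `ape::phylo`.
#' @export
nj_from_dist <- function(d) {
  ape::nj(as.dist(d))
}
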