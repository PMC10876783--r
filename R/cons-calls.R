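#' Conservation calls from homology hits
#'
#' A hit is conserved when E-value < `max_evalue` (strict), identity >=
#' `min_ident` percent and coverage of the shorter sequence >= `min_cov`
#' (both inclusive, reading "minimum of 60%" and "at least 30%"
#' literally). Coverage is alignment length over the shorter of the two
#' sequence lengths, on the best single HSP.
#'
#' @param hits data.frame of hits ([homology_search()] or
#'   [read_blast6()]).
#' @param query_lens,subject_lens named numeric vectors of sequence
#'   lengths.
#' @param max_evalue,min_ident,min_cov thresholds.
#' @return `hits` with `coverage_of_shorter` and `conserved` columns.
#' @export
call_conservation <- function(hits, query_lens, subject_lens,
                              max_evalue = 1e-5, min_ident = 60,
                              min_cov = 0.30) {
  if (!nrow(hits)) {
    hits$coverage_of_shorter <- numeric(0)
    hits$conserved <- logical(0)
    return(hits)
  }
  unknown_q <- setdiff(hits$query_id, names(query_lens))
  unknown_s <- setdiff(hits$subject_id, names(subject_lens))
  if (length(unknown_q) || length(unknown_s))
    stopf("hit references unknown sequence(s): %s",
          paste(head(c(unknown_q, unknown_s), 5L), collapse = ", "))
  shorter <- pmin(query_lens[hits$query_id],
                  subject_lens[hits$subject_id])
  hits$coverage_of_shorter <- hits$alignment_length / shorter
  hits$conserved <- hits$evalue < max_evalue &
    hits$percent_identity >= min_ident &
    hits$coverage_of_shorter >= min_cov
  hits
}

#' Per-species conservation counts for lncRNA loci
#'
#' A locus is conserved in a species when any of its transcripts has a
#' conserved hit against that species' lncRNA set.
#'
#' @param calls output of [call_conservation()] with a `species` column.
#' @param tx2gene named character vector transcript -> locus.
#' @return list with `per_species` (conserved-locus counts),
#'   `conserved_loci` (ids conserved in >= 1 species),
#'   `n_two_or_more`, `n_nine_or_more` (loci conserved in >= 2 / >= 9
#'   species).
#' @export
species_conservation <- function(calls, tx2gene) {
  cons <- calls[calls$conserved, , drop = FALSE]
  locus <- unname(tx2gene[cons$query_id])
  per_species <- vapply(split(locus, cons$species),
                        function(x) length(unique(x)), integer(1))
  by_locus <- lapply(split(cons$species, locus), unique)
  list(per_species = per_species,
       conserved_loci = names(by_locus),
       n_conserved = length(by_locus),
       n_two_or_more = sum(lengths(by_locus) >= 2L),
       n_nine_or_more = sum(lengths(by_locus) >= 9L))
}

#' Sub-genome conservation of wheat lncRNA loci
#'
#' Assigns each locus to sub-genome A, B or D by the suffix letter of its
#' chromosome ("U" and anything else excluded), runs the homology engine
#' between sub-genome sets with the same conservation thresholds, and
#' tabulates the three-set overlap.
#'
#' @param loci data.frame with `gene_id`, `chrom`.
#' @param seqs named character vector, one representative sequence per
#'   locus id.
#' @param ... thresholds passed to [call_conservation()].
#' @return list with `per_subgenome` (locus counts), `overlaps` (named
#'   counts AB, AD, BD, ABD of loci conserved across those sub-genome
#'   pairs/triple), `n_any` (loci conserved in at least one other
#'   sub-genome), `excluded` (locus ids not on A/B/D chromosomes) and
#'   `membership` (per-locus list of sub-genomes it is conserved in).
#' @export
subgenome_conservation <- function(loci, seqs, ...) {
  sg <- sub("^.*([A-Z])$", "\\1", loci$chrom)
  ok <- sg %in% c("A", "B", "D")
  excluded <- loci$gene_id[!ok]
  loci <- loci[ok, , drop = FALSE]
  sg <- sg[ok]
  sets <- split(loci$gene_id, sg)
  lens <- setNames(nchar(seqs), names(seqs))
  membership <- setNames(vector("list", nrow(loci)), loci$gene_id)
  pairs <- list(c("A", "B"), c("A", "D"), c("B", "D"))
  for (pr in pairs) {
    a <- intersect(sets[[pr[1]]], names(seqs))
    b <- intersect(sets[[pr[2]]], names(seqs))
    if (!length(a) || !length(b)) next
    hits <- homology_search(seqs[a], seqs[b])
    calls <- call_conservation(hits, lens, lens, ...)
    cons <- calls[calls$conserved, , drop = FALSE]
    for (q in unique(cons$query_id))
      membership[[q]] <- union(membership[[q]], pr[2])
    for (s in unique(cons$subject_id))
      membership[[s]] <- union(membership[[s]], pr[1])
  }
  own <- setNames(sg, loci$gene_id)
  in_pair <- function(x, y) {
    sum(vapply(names(membership), function(id) {
      m <- union(membership[[id]], own[[id]])
      all(c(x, y) %in% m)
    }, logical(1)))
  }
  abd <- sum(vapply(names(membership), function(id) {
    m <- union(membership[[id]], own[[id]])
    all(c("A", "B", "D") %in% m)
  }, logical(1)))
  list(per_subgenome = vapply(sets, length, integer(1)),
       overlaps = c(AB = in_pair("A", "B"), AD = in_pair("A", "D"),
                    BD = in_pair("B", "D"), ABD = abd),
       n_any = sum(lengths(membership) > 0L),
       excluded = excluded,
       membership = membership)
}
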