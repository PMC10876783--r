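#' Classify lncRNA-miRNA-mRNA regulatory modules
#'
#' A module forms when a lncRNA and an mRNA are both targets of the same
#' miRNA and both are differentially expressed in the same
#' (cultivar, stage) contrast. Concordant trends (up/up or down/down) make
#' the lncRNA a candidate miRNA sponge (ceRNA); opposite trends make it a
#' candidate miRNA precursor, but only when the lncRNA carries a perfect
#' complement of the miRNA. Opposite trends without perfect
#' complementarity yield no module.
#'
#' @param lnc_hits miRNA hits on lncRNAs ([scan_mirna_targets()] output).
#' @param mrna_hits miRNA hits on mRNAs.
#' @param de_results combined `de_result` rows for lncRNAs and genes
#'   (all contrasts).
#' @return data.frame of class `module_table`: `lncrna_id`, `mirna_id`,
#'   `mrna_id`, `role`, `cultivar`, `stage`, `lnc_direction`,
#'   `mrna_direction`, `score_lnc`, `score_mrna`, `lnc_perfect`.
#' @export
classify_modules <- function(lnc_hits, mrna_hits, de_results) {
  de <- de_results[de_results$direction != "ns", , drop = FALSE]
  rows <- list()
  for (m in intersect(unique(lnc_hits$mirna_id), unique(mrna_hits$mirna_id))) {
    lh <- lnc_hits[lnc_hits$mirna_id == m, , drop = FALSE]
    mh <- mrna_hits[mrna_hits$mirna_id == m, , drop = FALSE]
    for (il in seq_len(nrow(lh))) {
      lnc <- lh$rna_id[il]
      de_l <- de[de$gene_id == lnc, , drop = FALSE]
      if (!nrow(de_l)) next
      for (im in seq_len(nrow(mh))) {
        mrna <- mh$rna_id[im]
        de_m <- de[de$gene_id == mrna, , drop = FALSE]
        if (!nrow(de_m)) next
        shared <- merge(de_l, de_m, by = c("cultivar", "stage"),
                        suffixes = c("_lnc", "_mrna"))
        for (is in seq_len(nrow(shared))) {
          dl <- shared$direction_lnc[is]
          dm <- shared$direction_mrna[is]
          role <- if (dl == dm) "sponge" else if (lh$perfect[il])
            "precursor" else NA_character_
          if (is.na(role)) next
          rows[[length(rows) + 1L]] <- data.frame(
            lncrna_id = lnc, mirna_id = m, mrna_id = mrna, role = role,
            cultivar = shared$cultivar[is], stage = shared$stage[is],
            lnc_direction = dl, mrna_direction = dm,
            score_lnc = lh$score[il], score_mrna = mh$score[im],
            lnc_perfect = lh$perfect[il], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), mirna_id = character(0),
               mrna_id = character(0), role = character(0),
               cultivar = character(0), stage = character(0),
               lnc_direction = character(0), mrna_direction = character(0),
               score_lnc = numeric(0), score_mrna = numeric(0),
               lnc_perfect = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("module_table", "data.frame")
  out
}

#' Counts and cultivar sharing of regulatory modules
#'
#' @param modules a `module_table`.
#' @return list with `counts` (per-role lncRNA/miRNA/mRNA counts),
#'   `per_cultivar` (modules per cultivar and role) and `shared` (modules
#'   present in >= 2 cultivars, with their cultivar sets).
#' @export
module_summary <- function(modules) {
  count_role <- function(role) {
    m <- modules[modules$role == role, , drop = FALSE]
    c(n_lncrna = length(unique(m$lncrna_id)),
      n_mirna = length(unique(m$mirna_id)),
      n_mrna = length(unique(m$mrna_id)),
      n_modules = length(unique(paste(m$lncrna_id, m$mirna_id, m$mrna_id))))
  }
  counts <- rbind(sponge = count_role("sponge"),
                  precursor = count_role("precursor"))
  per_cultivar <- if (nrow(modules)) {
    pc <- as.data.frame(table(cultivar = modules$cultivar,
                              role = modules$role))
    names(pc)[3] <- "n"
    pc
  } else {
    data.frame(cultivar = character(0), role = character(0),
               n = integer(0))
  }
  key <- paste(modules$lncrna_id, modules$mirna_id, modules$mrna_id,
               modules$role, sep = "/")
  cvs <- lapply(split(modules$cultivar, key), unique)
  shared_keys <- names(cvs)[lengths(cvs) >= 2L]
  shared <- data.frame(module = shared_keys,
                       cultivars = vapply(cvs[shared_keys], paste,
                                          character(1), collapse = ","),
                       n_cultivars = lengths(cvs[shared_keys]),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(counts = counts, per_cultivar = per_cultivar, shared = shared)
}
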