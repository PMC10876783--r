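LNCRNA_CLASS_CODES <- c("i", "o", "u", "x")

#' Select lncRNA candidates by gffcompare class code
#'
#' Keeps transcripts tagged "i" (intronic), "o" (generic exonic overlap),
#' "u" (intergenic) or "x" (antisense).
#'
#' @param ts a [transcript_set()].
#' @return a `transcript_set` restricted to candidate class codes.
#' @export
select_candidates <- function(ts) {
  out <- ts[ts$class_code %in% LNCRNA_CLASS_CODES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove transcripts shorter than a minimum spliced length
#'
#' The published rule is strict ("shorter than 200 nucleotides were
#' removed"), so a transcript of exactly `min_len` is kept.
#'
#' @param ts a `transcript_set`.
#' @param min_len minimum spliced length in nt.
#' @return filtered `transcript_set`.
#' @export
length_filter <- function(ts, min_len = 200L) {
  out <- ts[ts$spliced_length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-scorer coding-potential consensus
#'
#' Each candidate is scored by three coding-potential callers and retained
#' as non-coding only when all three agree:
#' \itemize{
#'   \item logistic scorer: non-coding iff the fitted coding probability is
#'     below the model cutoff (the role of CPAT);
#'   \item ORF-rule scorer: non-coding iff longest ORF < 300 nt and ORF
#'     coverage < 0.5 (the role of CPC);
#'   \item hexamer-sign scorer: non-coding iff the hexamer usage-bias score
#'     is < 0 (the role of CNCI).
#' }
#' The seven-region Venn of the three non-coding call sets is recorded so
#' the intersection bookkeeping can be reported.
#'
#' @param candidates a `transcript_set` of candidates.
#' @param seqs named character vector of candidate sequences.
#' @param model a `coding_model`.
#' @param hexamer_tables tables used to score candidates (must be the ones
#'   the model was trained with).
#' @return list of class `discovery_result`: `retained` (transcript ids),
#'   `report` (per-candidate [CodingPotentialReport] data.frame),
#'   `venn` (named counts of the 7 regions), `drop_counts`.
#' @export
consensus_filter <- function(candidates, seqs, model, hexamer_tables) {
  seqs <- seqs[candidates$transcript_id]
  if (anyNA(names(seqs))) stopf("missing sequence for some candidates")
  feat <- coding_features(seqs, hexamer_tables)
  prob <- coding_probability(model, feat)
  nc_logit <- prob < model$cutoff
  nc_orf <- feat$orf_length < 300 & feat$orf_coverage < 0.5
  nc_hex <- feat$hexamer < 0
  consensus <- nc_logit & nc_orf & nc_hex
  report <- data.frame(
    transcript_id = feat$transcript_id,
    orf_length = feat$orf_length,
    orf_coverage = feat$orf_coverage,
    fickett_score = feat$fickett,
    hexamer_score = feat$hexamer,
    logistic_probability = prob,
    call_logistic = ifelse(nc_logit, "noncoding", "coding"),
    call_orf_rule = ifelse(nc_orf, "noncoding", "coding"),
    call_hexamer = ifelse(nc_hex, "noncoding", "coding"),
    consensus = ifelse(consensus, "noncoding", "coding"),
    stringsAsFactors = FALSE)
  venn <- c(
    logit_only = sum(nc_logit & !nc_orf & !nc_hex),
    orf_only = sum(!nc_logit & nc_orf & !nc_hex),
    hex_only = sum(!nc_logit & !nc_orf & nc_hex),
    logit_orf = sum(nc_logit & nc_orf & !nc_hex),
    logit_hex = sum(nc_logit & !nc_orf & nc_hex),
    orf_hex = sum(!nc_logit & nc_orf & nc_hex),
    all_three = sum(nc_logit & nc_orf & nc_hex))
  structure(list(
    retained = feat$transcript_id[consensus],
    report = report,
    venn = venn,
    drop_counts = c(consensus = sum(!consensus))),
    class = "discovery_result")
}

#' Protein-domain veto on retained candidates
#'
#' Translates each retained transcript's longest ORF and removes the
#' transcript when the peptide matches any database protein: an exact
#' ungapped 8-residue seed that extends (ungapped, identity-counted) to an
#' alignment of at least `min_len` residues with at least `min_ident`
#' identity. This plays the role of a Pfam/HMMER scan; an external
#' hmmsearch-style hit table can replace it via `external_hits`.
#'
#' @param retained character vector of retained transcript ids.
#' @param seqs named character vector of transcript sequences.
#' @param protein_db named character vector of protein sequences.
#' @param min_ident minimum identity fraction of the extended alignment.
#' @param min_len minimum alignment length (aa).
#' @param external_hits optional character vector of transcript ids flagged
#'   as protein-coding by an external domain search; overrides the internal
#'   matcher.
#' @return list: `kept` ids, `removed` ids.
#' @export
domain_veto <- function(retained, seqs, protein_db, min_ident = 0.4,
                        min_len = 30L, external_hits = NULL) {
  if (!is.null(external_hits)) {
    removed <- intersect(retained, external_hits)
    return(list(kept = setdiff(retained, removed), removed = removed))
  }
  if (!length(protein_db)) stopf("empty protein database")
  db_pep <- lapply(protein_db, seq_chars)
  db_seeds <- lapply(protein_db, seq_kmers, k = 8L)
  removed <- character(0)
  for (id in retained) {
    orf <- orf_sequence(seqs[[id]])
    if (nchar(orf) < 27L) next   # nothing to match
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substring(orf, 1L, nchar(orf) - 3L)),
      if.fuzzy.codon = "solve"))
    if (nchar(pep) < 8L) next
    pep_ch <- seq_chars(pep)
    pep_seeds <- seq_kmers(pep, 8L)
    hit <- FALSE
    for (d in seq_along(db_seeds)) {
      m <- match(pep_seeds, db_seeds[[d]])
      seeds <- which(!is.na(m))
      for (s in seeds) {
        if (extend_protein_seed(pep_ch, db_pep[[d]], s, m[s],
                                min_ident, min_len)) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) removed <- c(removed, id)
  }
  list(kept = setdiff(retained, removed), removed = removed)
}

## greedy ungapped extension of an exact 8-aa seed; returns TRUE when the
## best same-diagonal alignment reaches the identity/length thresholds
extend_protein_seed <- function(q, s, qpos, spos, min_ident, min_len) {
  diag_off <- spos - qpos
  lo <- max(1L, 1L - diag_off)
  hi <- min(length(q), length(s) - diag_off)
  if (hi - lo + 1L < min_len) return(FALSE)
  qa <- q[lo:hi]
  sa <- s[(lo + diag_off):(hi + diag_off)]
  eq <- qa == sa
  n <- length(eq)
  ## best identity over any diagonal window of length >= min_len
  cs <- c(0, cumsum(eq))
  best <- 0
  for (a in seq_len(n - min_len + 1L)) {
    b <- seq.int(a + min_len - 1L, n)
    ident <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
    best <- max(best, max(ident))
    if (best >= min_ident) break
  }
  best >= min_ident
}

#' Run the full lncRNA discovery cascade
#'
#' class-code selection -> length filter -> three-scorer consensus ->
#' protein-domain veto, with per-stage drop counts.
#'
#' @param ts a `transcript_set` (all assembled transcripts).
#' @param seqs named character vector of transcript sequences.
#' @param training list with `coding` and `noncoding` character vectors of
#'   training sequences for the hexamer tables and logistic model.
#' @param protein_db named character vector of protein sequences for the
#'   veto.
#' @param min_len minimum spliced length (nt).
#' @param fixed_cutoff optional fixed coding-probability cutoff (e.g.
#'   0.365); `NULL` derives it from the two-graph ROC.
#' @return list of class `discovery_run`: `lncrna` (retained
#'   `transcript_set`), `report`, `venn`, `stage_counts`, `model`,
#'   `hexamer_tables`, `removed_by_veto`.
#' @export
discover_lncrnas <- function(ts, seqs, training, protein_db,
                             min_len = 200L, fixed_cutoff = NULL) {
  n0 <- nrow(ts)
  cand <- select_candidates(ts)
  n1 <- nrow(cand)
  cand <- length_filter(cand, min_len)
  n2 <- nrow(cand)
  tables <- train_hexamer_tables(training$coding, training$noncoding)
  tr_seqs <- c(training$coding, training$noncoding)
  names(tr_seqs) <- paste0("train_", seq_along(tr_seqs))
  feat <- coding_features(tr_seqs, tables)
  labels <- rep(c(1L, 0L), c(length(training$coding),
                             length(training$noncoding)))
  model <- fit_coding_model(feat, labels, fixed_cutoff)
  cons <- consensus_filter(cand, seqs, model, tables)
  n3 <- length(cons$retained)
  veto <- domain_veto(cons$retained, seqs, protein_db)
  lnc <- cand[cand$transcript_id %in% veto$kept, , drop = FALSE]
  rownames(lnc) <- NULL
  structure(list(
    lncrna = lnc,
    report = cons$report,
    venn = cons$venn,
    stage_counts = c(input = n0, class_code = n1, length = n2,
                     consensus = n3, domain_veto = length(veto$kept)),
    model = model,
    hexamer_tables = tables,
    removed_by_veto = veto$removed),
    class = "discovery_run")
}
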