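#' Transcript set container
#'
#' A light tabular model of assembled transcripts. Coordinates are held
#' 0-based half-open internally; GTF input/output converts to and from the
#' 1-based inclusive convention at the file boundary, so a single convention
#' rules all window arithmetic.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `class_code`, and list-columns
#'   `exon_starts`, `exon_ends` (0-based half-open, sorted, non-overlapping).
#' @return object of class `transcript_set` (a data.frame).
#' @export
transcript_set <- function(transcripts) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
           "class_code", "exon_starts", "exon_ends")
  miss <- setdiff(req, names(transcripts))
  if (length(miss)) stopf("transcript_set: missing column(s) %s",
                          paste(miss, collapse = ", "))
  for (i in seq_len(nrow(transcripts))) {
    es <- transcripts$exon_starts[[i]]
    ee <- transcripts$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee)) {
      stopf("transcript %s: invalid exon intervals",
            transcripts$transcript_id[i])
    }
    if (is.unsorted(es, strictly = TRUE) && length(es) > 1L)
      stopf("transcript %s: exons not sorted", transcripts$transcript_id[i])
    if (length(es) > 1L && any(es[-1L] < ee[-length(ee)]))
      stopf("transcript %s: overlapping exons", transcripts$transcript_id[i])
  }
  transcripts$spliced_length <- vapply(
    seq_len(nrow(transcripts)),
    function(i) sum(transcripts$exon_ends[[i]] - transcripts$exon_starts[[i]]),
    numeric(1)
  )
  class(transcripts) <- c("transcript_set", "data.frame")
  transcripts
}

#' Spliced lengths of a transcript set
#' @param ts a `transcript_set`.
#' @return named numeric vector of summed exon lengths.
#' @export
spliced_length <- function(ts) {
  setNames(ts$spliced_length, ts$transcript_id)
}

#' Read a GTF annotation into a transcript set
#'
#' Parses a 9-column GTF, validating each non-comment line, and assembles
#' exon features into transcript models. The gffcompare `class_code`
#' attribute is honoured when present; transcripts without one are treated
#' as reference matches (code `"="`). Coordinates are converted from GTF's
#' 1-based inclusive to the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return a [transcript_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF not found: %s", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad)) stopf("malformed GTF line %d in %s (expected 9 columns)",
                         bad[1L], path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stopf("no exon features in %s", path)
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gid <- as.character(md$gene_id)
  cc <- if ("class_code" %in% names(md)) as.character(md$class_code) else
    rep(NA_character_, length(gr))
  ord <- order(tid, GenomicRanges::start(gr))
  gr <- gr[ord]; tid <- tid[ord]; gid <- gid[ord]; cc <- cc[ord]
  idx <- split(seq_along(gr), tid)
  rows <- lapply(idx, function(ii) {
    st <- GenomicRanges::start(gr)[ii] - 1L   # to 0-based half-open
    en <- GenomicRanges::end(gr)[ii]
    code <- cc[ii][!is.na(cc[ii])]
    data.frame(
      transcript_id = tid[ii][1L],
      gene_id = gid[ii][1L],
      chrom = as.character(GenomicRanges::seqnames(gr))[ii][1L],
      start = min(st), end = max(en),
      strand = as.character(GenomicRanges::strand(gr))[ii][1L],
      class_code = if (length(code)) code[1L] else "=",
      exon_starts = I(list(st)), exon_ends = I(list(en)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$strand[out$strand == "*"] <- "."
  transcript_set(out)
}

#' Write a transcript set as GTF
#'
#' Emits one `transcript` and per-exon `exon` rows per transcript with
#' `gene_id`, `transcript_id` and `class_code` attributes, converting back
#' to 1-based inclusive coordinates.
#'
#' @param ts a [transcript_set()].
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path, source = "pollenlnc") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ts))) {
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s"; class_code "%s";',
                     ts$gene_id[i], ts$transcript_id[i], ts$class_code[i])
    strand <- ts$strand[i]
    writeLines(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       ts$chrom[i], source, ts$start[i] + 1L, ts$end[i],
                       strand, attr9), con)
    es <- ts$exon_starts[[i]]; ee <- ts$exon_ends[[i]]
    for (j in seq_along(es)) {
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                         ts$chrom[i], source, es[j] + 1L, ee[j], strand,
                         attr9), con)
    }
  }
  invisible(path)
}
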