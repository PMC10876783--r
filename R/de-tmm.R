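#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample scaling factors. The reference
#' sample is the one whose upper-quartile of library-scaled counts is
#' closest to the mean upper-quartile. For each sample, M (log2 ratio) and
#' A (average log abundance) are computed on genes positive in both sample
#' and reference, trimmed by 30% on M and 5% on A, and the factor is
#' 2^(inverse-variance-weighted mean of the remaining M values). Factors
#' are rescaled to geometric mean 1.
#'
#' @param counts genes-by-samples count matrix.
#' @param ref_sample optional column index of the reference sample.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  ns <- ncol(counts)
  if (ns < 2L) stopf("TMM needs >= 2 samples")
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("zero library size")
  if (is.null(ref_sample)) {
    f75 <- vapply(seq_len(ns),
                  function(j) quantile(counts[, j] / lib[j], 0.75,
                                       names = FALSE),
                  numeric(1))
    ref_sample <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ns), function(j) {
    tmm_one(counts[, j], counts[, ref_sample], lib[j], lib[ref_sample])
  }, numeric(1))
  f / exp(mean(log(f)))
}

## single-sample TMM against a reference (logratioTrim = .3, sumTrim = .05,
## inverse-variance weighting)
tmm_one <- function(obs, ref, lib_obs, lib_ref) {
  n_obs <- obs / lib_obs
  n_ref <- ref / lib_ref
  log_r <- log2(n_obs / n_ref)
  abs_e <- (log2(n_obs) + log2(n_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(log_r) & is.finite(abs_e)
  if (!any(fin)) stopf("no genes expressed in both sample and reference")
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * 0.3) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * 0.05) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  if (!any(keep)) return(1)
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Attach TMM factors to an expression matrix
#' @param em an `expr_matrix`.
#' @return the `expr_matrix` with `tmm` factors set.
#' @export
tmm_normalize <- function(em) {
  em$tmm <- tmm_factors(em$counts)
  em
}

#' TMM-normalized counts per million
#' @param em an `expr_matrix` (after [tmm_normalize()]).
#' @return genes-by-samples CPM matrix.
#' @export
cpm_matrix <- function(em) {
  eff <- em$lib_sizes * em$tmm
  t(t(em$counts) / eff) * 1e6
}

#' Filter low-count genes by CPM
#'
#' A gene is kept when its TMM-normalized CPM is at least `min_cpm` in
#' every sample of at least one (cultivar, stage, condition) group — the
#' gene must be consistently expressed somewhere in the design. The
#' published threshold is strict on the removal side ("CPM smaller than
#' one"), so CPM exactly 1 passes.
#'
#' @param em an `expr_matrix`.
#' @param min_cpm CPM threshold.
#' @return filtered `expr_matrix` (library sizes and factors recomputed).
#' @export
cpm_filter <- function(em, min_cpm = 1) {
  cpm <- cpm_matrix(em)
  grp <- interaction(em$design$cultivar, em$design$stage,
                     em$design$condition, drop = TRUE)
  keep <- rep(FALSE, nrow(cpm))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    keep <- keep | apply(cpm[, cols, drop = FALSE] >= min_cpm, 1L, all)
  }
  out <- expression_matrix(em$counts[keep, , drop = FALSE], em$design)
  tmm_normalize(out)
}
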