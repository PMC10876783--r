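#' Pearson correlation with two-sided t-test
#'
#' Product-moment r with p from t = r * sqrt(n-2) / sqrt(1-r^2) on n-2
#' degrees of freedom. At n = 6 the two-sided p < 0.05 boundary sits at
#' |r| = 0.811, the published correspondence between the correlation and
#' significance cutoffs.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and `p`, or `NULL` when either vector has zero
#'   variance (the edge is skipped).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("pearson_test: unequal lengths")
  if (n < 3L) stopf("pearson_test: need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) return(NULL)
  r <- cor(x, y)
  r2 <- min(r^2, 1)
  if (r2 >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

#' Critical |r| for two-sided significance
#'
#' The smallest |r| whose two-sided p-value is below `alpha` at sample
#' size `n`.
#'
#' @param n sample size.
#' @param alpha significance level.
#' @return numeric critical correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}
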