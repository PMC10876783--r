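#' @importFrom stats cor density dhyper pnbinom pnorm pt qt quantile rbinom
#'   rgamma rlnorm rnbinom rnorm runif sd setNames var p.adjust phyper glm
#'   binomial predict as.dist qnorm
#' @importFrom utils head tail read.delim write.table combn
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
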