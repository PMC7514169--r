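#' @useDynLib efemin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median runif rnorm dnorm dbinom pbinom pnorm quantile ecdf
#' @importFrom utils read.csv write.csv read.delim write.table combn head
#' @keywords internal
"_PACKAGE"
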