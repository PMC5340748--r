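`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib lvssa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom RNifti pixdim<- qform<- sform<-
#' @importFrom stats quantile rnorm runif sd cor uniroot prcomp median
#' @importFrom utils read.csv write.csv combn head tail
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_num_matrix <- function(x, ncol, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol) stopf("%s must have %d columns", what, ncol)
  if (anyNA(x) || any(!is.finite(x))) stopf("%s contains non-finite values", what)
  x
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("zero-length vector cannot be normalized")
  v / n
}
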