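#' @useDynLib dockrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov median predict quantile sd var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dockrf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dockrf_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_dockrf("'%s' must be a single finite number", name,
                class = "dockrf_validation_error")
  invisible(x)
}
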