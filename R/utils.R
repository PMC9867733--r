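#' @useDynLib ssrinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor plogis pnorm qlogis qnorm quantile rbinom rnorm
#'   runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' Derive a stage seed from a master seed
#'
#' Every random operation in the package draws its seed deterministically from
#' a master seed plus a short stage tag, so that an entire pipeline run is a
#' pure function of (inputs, master seed) while stages remain decoupled.
#'
#' @param master integer master seed.
#' @param tag character stage tag, e.g. `"week6"` or `"boot17"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(as.double(utf8ToInt(tag)) * seq_along(utf8ToInt(tag)) * 2654435.0)
  as.integer((abs(master) + h) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
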