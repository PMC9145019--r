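#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median rnorm runif setNames sd na.omit
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib clopbpk, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Trapezoidal integral of y over x
#'
#' Linear trapezoid throughout (no log-linear down-slope correction); this is
#' the convention used for all AUC_last computations in the package.
#'
#' @param x numeric vector, strictly increasing
#' @param y numeric vector of the same length
#' @return the integral as a single number
#' @export
trapz <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

read_json_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

write_json_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

clopbpk_extdata <- function(file) {
  p <- system.file("extdata", file, package = "clopbpk")
  if (!nzchar(p)) stop("missing packaged config file: ", file, call. = FALSE)
  p
}
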