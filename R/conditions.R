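#' @title Classed error conditions
#' @description All errors raised by the package carry an S3 condition class
#'   naming the failure mode, so callers (and the CLI) can branch on the
#'   class rather than matching message text. The classes are:
#'   `DuplicateIdError`, `ParseError`, `SchemaError`, `UnknownIdError`,
#'   `UnknownCategoryError`, `UnknownGroupError`, `ParameterError`,
#'   `DimensionError`, `IdMismatchError`, `InsufficientDataError`,
#'   `EmptyClusterError`, `ZeroDivisionPolicyError`, `MissingContextError`,
#'   `EmptyChartError`, `IncompleteColorError`, `IoError`.
#'   Every condition also carries the umbrella class `scRadialError`.
#' @name scRadial-errors
NULL

scStop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "scRadialError"), call = call))
}

# Parameter sanity helper: single non-NA string
assertString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    scStop("ParameterError", sprintf("'%s' must be a single string", what))
  }
  invisible(x)
}

assertCount <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    scStop("ParameterError",
           sprintf("'%s' must be a single integer >= %d", what, min))
  }
  invisible(as.integer(x))
}
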