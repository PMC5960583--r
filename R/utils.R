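## Internal helpers shared across modules.

#' @useDynLib trammelcatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Gear type, fate and vitality vocabularies used throughout.
WALL_TYPES <- c("PMF", "MMF", "MMF_GRECA")
FATES <- c("MARKETABLE", "DISCARD")
VITALITY_LEVELS <- c("DEAD", "POOR", "GOOD", "EXCELLENT")
NET_LEVEL <- "NET_LEVEL"

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stopf("file '%s': missing column(s) %s", file,
          paste(sQuote(missing), collapse = ", "))
  invisible(df)
}

## Empirical central interval, lower/upper as a length-2 vector.
central_interval <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  unname(stats::quantile(x, c(alpha, 1 - alpha), names = FALSE))
}
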