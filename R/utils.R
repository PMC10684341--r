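#' Derive a deterministic sub-stream seed
#'
#' Stochastic pipeline stages each draw from their own seed derived from a
#' single master seed, so a stage can be rerun in isolation and reproduce the
#' full-run result exactly.
#'
#' @param seed master seed (integer).
#' @param stage stage index (small positive integer) or stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
sub_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  # affine map modulo a Mersenne prime keeps distinct stages on distinct streams
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %% (2^31 - 1))
}

#' Count decimal places of a coordinate
#'
#' Counts digits after the decimal point in the textual rendering of a
#' coordinate. Trailing zeros count when the text is given explicitly ("40.10"
#' has two decimals); for bare numerics the shortest round-trip rendering is
#' used, where trailing zeros are invisible.
#'
#' @param x character or numeric vector of coordinates.
#' @return integer vector of decimal counts.
#' @keywords internal
n_decimals <- function(x) {
  if (is.numeric(x)) x <- vapply(x, function(v) format(v, digits = 15), "")
  x <- trimws(x)
  has_dot <- grepl(".", x, fixed = TRUE)
  dec <- sub("^[^.]*\\.", "", x)
  dec <- gsub("[^0-9]", "", dec)
  ifelse(has_dot, nchar(dec), 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
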