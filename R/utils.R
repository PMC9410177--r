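#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate cor p.adjust phyper rnorm runif sd setNames
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Round-half-up to the nearest integer
#'
#' Reporting helper matching the convention used for printed census and
#' percentage summaries (round() in R rounds half to even, which would turn
#' 44.5 into 44).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Deterministic sub-seed derivation: keeps derived seeds positive and < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
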