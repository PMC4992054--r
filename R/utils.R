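#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (ACGTN alphabet, case
#'   insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Base R rounds half to even (IEEE 754); published tables in this field
#' conventionally round half up. A tiny epsilon absorbs binary
#' representation error for quotients of integers.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
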