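# shared helpers: sequence utilities, Phred conversion, seed derivation

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred+33 encoding helpers
#'
#' `phred_to_int` decodes a quality string into integer Phred scores;
#' `int_to_phred` is its inverse.
#'
#' @param qual a single quality string (Phred+33).
#' @param q integer vector of Phred scores.
#' @return integer vector / single character string.
#' @export
phred_to_int <- function(qual) {
  if (nchar(qual) == 0) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' @rdname phred_to_int
#' @export
int_to_phred <- function(q) {
  intToUtf8(pmin(pmax(as.integer(round(q)), 0L), 93L) + 33L)
}

# stable per-stage seed derived from a master seed and a stage name, so that
# one pipeline seed governs all stochastic stages without collisions
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# vectorized per-base quality counting without splitting strings: counts
# characters in the Phred+33 range [0, thresh-1] via a single regex
count_below_phred <- function(quals, thresh) {
  if (thresh <= 0) return(integer(length(quals)))
  re <- sprintf("[\\x21-\\x%02x]", 33L + thresh - 1L)
  nchar(quals) - nchar(gsub(re, "", quals, perl = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

# random DNA of given lengths (vectorized)
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  }, character(1))
}
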