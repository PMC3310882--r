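# Internal helpers shared across modules.

# Probes are concrete oligos: uppercase ACGT only.
is_valid_probe <- function(x, probe_length = 25L) {
  nchar(x) == probe_length & grepl("^[ACGT]+$", x)
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors of A/C/G/T
#' sequences.
#'
#' @param x Character vector of DNA sequences (ACGT).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp_dna("AACGT")
revcomp_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s) of given length; relies on the caller's RNG state.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1L, paste0, collapse = "")
}

# n random DNA strings of length len, all distinct and disjoint from `avoid`.
random_distinct_dna <- function(n, len, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- unique(random_dna(n - length(out) + 8L, len))
    cand <- setdiff(cand, c(avoid, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
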