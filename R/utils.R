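## Internal helpers shared across modules. All genomic coordinates in this
## package are 0-based half-open (BED convention); 1-based coordinates appear
## only in human-readable report text.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors. `N` is preserved.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## DNA string -> integer vector (A=1, C=2, G=3, T=4, N/other = NA)
seq_to_int <- function(x) {
  stopifnot(length(x) == 1L)
  idx <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  idx
}

int_to_seq <- function(i) paste(DNA_BASES[i], collapse = "")

## stop() without the call, with sprintf-style formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

## deterministic seed derivation for sub-streams, kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}
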