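#' Rotate a sequence string
#'
#' Returns the rotation of `seq` starting at position `k + 1`, i.e. the
#' string `seq[(k+1)..n] + seq[1..k]`. Rotating by 0 or by the sequence
#' length is the identity.
#'
#' @param seq A single character string.
#' @param k Rotation offset in bases (`0 <= k <= nchar(seq)`).
#' @return The rotated string.
#' @export
#' @examples
#' rotate_seq("ACGTT", 2)  # "GTTAC"
rotate_seq <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  k <- as.integer(k %% max(n, 1L))
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

#' Reverse complement of a DNA string
#'
#' @param seq A single character string over \{A,C,G,T,N\}.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Random DNA of length n (uses the current RNG stream).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Positions (1-based) of each k-mer in a sequence string, as a list keyed by
## k-mer, restricted to k-mers occurring at least `min_occ` times.
kmer_positions <- function(seq, k, min_occ = 2L) {
  n <- nchar(seq)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- kmers %in% names(which(table(kmers) >= min_occ))
  split(starts[keep], kmers[keep])
}

## Derive a child seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

## Internal coordinate convention: 0-based half-open [start, end).
interval_width <- function(start, end) end - start

## Overlap width between two half-open intervals.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
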