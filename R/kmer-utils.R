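## Low-level k-mer string helpers shared by the index, the pseudoaligner and
## the test oracles. All sequences are plain uppercase character strings over
## {A,C,G,T,N}; k-mers containing N are never indexed.

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character strings. `N` maps to
#' `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement; storing k-mers canonically makes the index
#' strand-agnostic. With odd k a k-mer can never equal its own reverse
#' complement, so the forward/reverse decision is always well defined.
#'
#' @param x character vector of k-mers.
#' @return list with `canonical` (character) and `is_forward` (logical,
#'   `TRUE` where the input already was the canonical form).
#' @export
canonicalize <- function(x) {
  rc <- revcomp(x)
  fwd <- x <= rc
  canonical <- x
  canonical[!fwd] <- rc[!fwd]
  list(canonical = canonical, is_forward = fwd)
}

#' Enumerate the k-mers of a sequence
#'
#' @param seq single sequence string.
#' @param k k-mer length.
#' @return character vector of `nchar(seq) - k + 1` k-mers (empty when the
#'   sequence is shorter than k).
#' @export
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## Error unless every sequence is a (possibly empty) string over ACGTN.
assert_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

## uppercase and U->T, the normalisation applied to all sequence input
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
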