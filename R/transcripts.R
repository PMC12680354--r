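#' Ordered reference transcript set
#'
#' Container for a reference transcriptome: transcript identifiers paired
#' with nucleotide sequences, in input order. The 0-based position of a
#' transcript in this order is its *ordinal*; transcript compatibility
#' classes are sets of ordinals, and deterministic tie-breaking during read
#' classification prefers the smallest ordinal (the first transcript in the
#' reference).
#'
#' @param seqs character vector of nucleotide sequences (uppercased,
#'   `U` converted to `T`).
#' @param ids character vector of unique transcript identifiers; defaults to
#'   the names of `seqs`.
#' @return an object of class `transcript_set`: a list with `id`, `seq` and
#'   `length` (bp), all parallel vectors in reference order.
#' @export
transcript_set <- function(seqs, ids = names(seqs)) {
  if (length(seqs) == 0) stop("transcript set is empty", call. = FALSE)
  if (is.null(ids)) ids <- paste0("tx", seq_along(seqs) - 1L)
  ids <- as.character(ids)
  seqs <- normalize_seq(as.character(seqs))
  if (anyDuplicated(ids)) stop("duplicated transcript ids", call. = FALSE)
  if (length(ids) != length(seqs)) stop("ids and sequences differ in length", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty transcript sequence", call. = FALSE)
  assert_nucleotides(seqs, "transcript")
  structure(list(id = ids, seq = unname(seqs), length = nchar(seqs)),
            class = "transcript_set")
}

#' @export
length.transcript_set <- function(x) length(x$id)

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set with %d transcripts (%d bp total)\n",
              length(x$id), sum(x$length)))
  invisible(x)
}
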