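## Sequence file IO. FASTA goes through Biostrings (plain or gzipped,
## auto-detected); sequences are uppercased and U converted to T so
## direct-RNA-style input indexes correctly. FASTQ uses a strict 4-line
## record reader so that malformed records (in particular quality strings
## whose length does not match the sequence) are reported with their record
## index instead of being silently padded.

#' Read a reference FASTA into a transcript set
#'
#' @param path FASTA path, plain or gzipped.
#' @return a [transcript_set]; ids are the first whitespace-delimited token
#'   of each header, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  transcript_set(as.character(x), ids = ids)
}

#' Read FASTQ records
#'
#' Strict 4-line-per-record FASTQ (plain or gzipped, auto-detected).
#' Sequences are uppercased with `U -> T`.
#'
#' @param path FASTQ path.
#' @return list with `id`, `seq`, `qual`, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")  # gzfile reads plain text transparently
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) %/% 4
  hd <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  bad_hd <- !startsWith(hd, "@")
  if (any(bad_hd)) {
    stop("malformed FASTQ record ", which(bad_hd)[1], " in ", path,
         ": header does not start with '@' (line ",
         (which(bad_hd)[1] - 1L) * 4L + 1L, ")", call. = FALSE)
  }
  bad_pl <- !startsWith(pl, "+")
  if (any(bad_pl)) {
    stop("malformed FASTQ record ", which(bad_pl)[1], " in ", path,
         ": separator line does not start with '+'", call. = FALSE)
  }
  bad_q <- nchar(ql) != nchar(sq)
  if (any(bad_q)) {
    stop("malformed FASTQ record ", which(bad_q)[1], " in ", path,
         ": quality length differs from sequence length", call. = FALSE)
  }
  list(id = sub("\\s.*$", "", substring(hd, 2L)),
       seq = normalize_seq(sq),
       qual = ql)
}

#' Write sequences as FASTA / FASTQ
#'
#' @param ids,seqs parallel character vectors.
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @param qual optional quality strings for FASTQ; defaults to `"I"` repeated
#'   (Phred 40) per base.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", seqs), con)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(ids, seqs, path, qual = NULL) {
  if (is.null(qual)) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  }
  stopifnot(all(nchar(qual) == nchar(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
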