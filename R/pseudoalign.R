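## Error-tolerant read classification against the T-DBG index.
##
## A read's transcript compatibility class is decided by a cascade over the
## multiset of TCCs of its k-mers:
##   (1) any k-mer on the d-list        -> veto, unmapped
##   (2) no k-mer hits                  -> unmapped
##   (3) non-empty intersection of all hit TCCs -> that intersection
##   (4) >=1 uniquely mapping k-mer     -> most frequent singleton TCC
##   (5) otherwise                      -> most frequent TCC overall (mode)
## The intersection is the transcript set the read is compatible with along
## its whole mappable extent; errors or variants can empty it, in which case
## the mode recovers the "longest chain" of compatibility.

#' Classify one read into a transcript compatibility class
#'
#' Walks the read left to right. Each hashed k-mer that hits the index
#' anchors the read on a unitig; the anchored stretch is then extended by
#' direct base comparison between read and unitig, so every k-mer position
#' inside the stretch is known to carry that unitig's TCC without further
#' hashing. This contig-skipping makes the number of hash lookups
#' proportional to the number of stretches plus mismatching positions, while
#' the collected TCC multiset is exactly the one an exhaustive per-k-mer scan
#' would produce.
#'
#' Ties in branch (4) (equal counts of uniquely mapping k-mers for distinct
#' transcripts) go to the smallest transcript ordinal, i.e. the transcript
#' occurring first in the reference. Ties in branch (5) go to the TCC with
#' the smallest minimum ordinal, then lexicographically on the sorted ordinal
#' vector, giving a total deterministic order.
#'
#' @param index a [tdbg_index][build_index].
#' @param read nucleotide string over `{A,C,G,T,N}`; k-mers containing `N`
#'   are skipped. Reads shorter than k are unmapped, not errors.
#' @param read_id identifier carried into the result.
#' @return a list of class `read_classification` with `read_id`, `tcc`
#'   (sorted 0-based ordinals, or `NULL`), `tcc_key`, `branch` (one of
#'   `"intersection"`, `"unique_mode"`, `"mode"`, `"unmapped"`,
#'   `"dlist_veto"`), `n_kmers_examined` (hash lookups performed) and
#'   `read_length`.
#' @export
classify_read <- function(index, read, read_id = "read") {
  stopifnot(inherits(index, "tdbg_index"))
  read <- normalize_seq(read)
  assert_nucleotides(read, "read")
  k <- index$k
  L <- nchar(read)
  res <- function(branch, tcc_id = NA_integer_, examined = 0L) {
    tcc <- if (is.na(tcc_id)) NULL else index$tccs[[tcc_id]]
    structure(list(read_id = read_id, tcc = tcc,
                   tcc_key = if (is.na(tcc_id)) NA_character_
                             else index$tcc_keys[tcc_id],
                   branch = branch, n_kmers_examined = examined,
                   read_length = L),
              class = "read_classification")
  }
  if (L < k) return(res("unmapped"))

  npos <- L - k + 1L
  km <- substring(read, 1:npos, k:L)
  if (grepl("N", read, fixed = TRUE)) {
    valid <- !grepl("N", km, fixed = TRUE)
  } else {
    valid <- rep(TRUE, npos)
  }
  has_dlist <- length(index$dlist) > 0

  ## the hash holds both orientations of every indexed k-mer, so each
  ## examined position is a single lookup of the raw read k-mer; the sign of
  ## the stored id encodes whether the query matched the canonical form
  node_of <- index$node_of
  node_uid <- index$node_uid; node_off <- index$node_off
  node_fwd <- index$node_fwd; node_tcc <- index$node_tcc
  unitig_seq <- index$unitig_seq
  dlist <- index$dlist

  tally <- numeric(length(index$tccs))   # k-mer multiplicity per TCC id
  seen <- integer(0)                     # distinct TCC ids encountered
  examined <- 0L
  p <- 1L
  while (p <= npos) {
    if (!valid[p]) { p <- p + 1L; next }
    examined <- examined + 1L
    i0 <- node_of[[km[p]]]
    if (is.null(i0)) {
      if (has_dlist && !is.null(dlist[[km[p]]])) {
        return(res("dlist_veto", examined = examined))
      }
      p <- p + 1L
      next
    }
    i <- abs(i0)
    uid <- node_uid[i]
    off <- node_off[i]                    # 0-based
    useq <- unitig_seq[uid]
    q_fwd <- (i0 > 0L) == node_fwd[i]
    ## verified extension: longest run of read positions whose k-mers match
    ## the unitig consecutively, found by direct base comparison
    if (q_fwd) {
      max_e <- min(L - (p + k - 1L), nchar(useq) - (off + k))
      if (max_e > 0L) {
        a <- utf8ToInt(substr(read, p + k, p + k - 1L + max_e))
        b <- utf8ToInt(substr(useq, off + k + 1L, off + k + max_e))
        mism <- which(a != b)
        e <- if (length(mism)) mism[1] - 1L else max_e
      } else e <- 0L
    } else {
      max_e <- min(L - (p + k - 1L), off)
      if (max_e > 0L) {
        a <- utf8ToInt(substr(read, p + k, p + k - 1L + max_e))
        b <- rev(utf8ToInt(chartr("ACGT", "TGCA",
                                  substr(useq, off - max_e + 1L, off))))
        mism <- which(a != b)
        e <- if (length(mism)) mism[1] - 1L else max_e
      } else e <- 0L
    }
    m <- 1L + e
    tid <- index$unitig_tcc[uid]
    if (tally[tid] == 0) seen <- c(seen, tid)
    tally[tid] <- tally[tid] + m
    p <- p + m
  }

  if (length(seen) == 0L) return(res("unmapped", examined = examined))

  ## (3) intersection over the distinct TCCs encountered
  inter <- Reduce(intersect, index$tccs[seen])
  if (length(inter) > 0L) {
    key <- paste(sort.int(inter), collapse = ",")
    tid <- match(key, index$tcc_keys)
    if (is.na(tid)) {
      ## the intersection need not itself be an indexed TCC
      return(structure(list(read_id = read_id, tcc = sort.int(inter),
                            tcc_key = key, branch = "intersection",
                            n_kmers_examined = examined, read_length = L),
                       class = "read_classification"))
    }
    out <- res("intersection", tid, examined)
    return(out)
  }

  ## (4) mode over uniquely mapping k-mers (singleton TCCs)
  singleton <- seen[lengths(index$tccs[seen]) == 1L]
  if (length(singleton) > 0L) {
    cnt <- tally[singleton]
    best <- singleton[cnt == max(cnt)]
    if (length(best) > 1L) {
      ords <- vapply(index$tccs[best], `[`, 1L, 1L)
      best <- best[which.min(ords)]
    }
    return(res("unique_mode", best, examined))
  }

  ## (5) global mode, threshold one occurrence
  cnt <- tally[seen]
  best <- seen[cnt == max(cnt)]
  if (length(best) > 1L) {
    mins <- vapply(index$tccs[best], min, 1L)
    best <- best[mins == min(mins)]
    if (length(best) > 1L) {
      ## lexicographic order on the sorted ordinal vectors
      vecs <- index$tccs[best]
      sel <- 1L
      for (j in seq_along(vecs)[-1]) {
        if (lex_less(vecs[[j]], vecs[[sel]])) sel <- j
      }
      best <- best[sel]
    }
  }
  res("mode", best, examined)
}

## TRUE iff integer vector a precedes b lexicographically (prefix first)
lex_less <- function(a, b) {
  m <- min(length(a), length(b))
  for (i in seq_len(m)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Pseudoalign a batch of reads
#'
#' Applies [classify_read] to each read in input order and aggregates
#' transcript-compatibility-class counts.
#'
#' @param index a [tdbg_index][build_index].
#' @param reads character vector of read sequences, or a path handled by
#'   [read_fastq]/[read_fasta], or a `DNAStringSet`.
#' @param read_ids identifiers; default `names(reads)` or `read1..readN`.
#' @return list with:
#'   \describe{
#'     \item{counts}{`tcc_counts`: `counts` named by TCC key (sorted comma
#'       separated 0-based ordinals), `class_members` (list of ordinal
#'       vectors, parallel to `counts`), `n_reads_total`, `n_reads_mapped`.}
#'     \item{classifications}{data.frame with one row per read in input
#'       order: `read_id`, `branch`, `tcc_key`, `n_kmers_examined`,
#'       `read_length`.}
#'     \item{mapping_rate}{mapped fraction; 0 when there are no reads.}
#'   }
#' @export
pseudoalign_batch <- function(index, reads, read_ids = NULL) {
  stopifnot(inherits(index, "tdbg_index"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    rec <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) read_fastq(reads)
           else read_fasta(reads)
    read_ids <- rec$id
    reads <- rec$seq
  }
  reads <- as.character(reads)
  if (is.null(read_ids)) {
    read_ids <- if (!is.null(names(reads))) names(reads)
                else paste0("read", seq_along(reads))
  }
  n <- length(reads)
  cls <- vector("list", n)
  for (i in seq_len(n)) {
    cls[[i]] <- classify_read(index, reads[i], read_ids[i])
  }
  keys <- vapply(cls, function(x) x$tcc_key, "")
  branch <- vapply(cls, function(x) x$branch, "")
  mapped <- !is.na(keys)
  tab <- table(keys[mapped])
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  members <- if (length(tab) > 0) {
    lapply(strsplit(names(tab), ",", fixed = TRUE), as.integer)
  } else list()
  classifications <- data.frame(
    read_id = vapply(cls, function(x) x$read_id, ""),
    branch = branch,
    tcc_key = keys,
    n_kmers_examined = vapply(cls, function(x) x$n_kmers_examined, 1L),
    read_length = vapply(cls, function(x) x$read_length, 1L),
    stringsAsFactors = FALSE)
  list(
    counts = structure(list(counts = counts, class_members = members,
                            n_reads_total = n,
                            n_reads_mapped = sum(mapped)),
                       class = "tcc_counts"),
    classifications = classifications,
    mapping_rate = if (n == 0) 0 else sum(mapped) / n
  )
}
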