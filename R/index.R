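## Compacted transcriptome de Bruijn graph (T-DBG) index.
##
## Nodes of the raw graph are canonical k-mers; each k-mer carries a
## transcript compatibility class (TCC): the set of transcript ordinals whose
## sequence contains it. Maximal non-branching runs of k-mers with identical
## TCC are compacted into unitigs, and the k-mer map records, for every
## canonical k-mer, its unitig, offset and strand. Read classification only
## ever touches this map plus the per-unitig TCCs.

IDX_FORMAT <- "lrquant_tdbg_index"
IDX_VERSION <- 1L
BASES <- c("A", "C", "G", "T")

#' Build a compacted transcriptome de Bruijn graph index
#'
#' Enumerates the canonical k-mers of all transcripts, labels each with its
#' transcript compatibility class (the set of 0-based transcript ordinals
#' containing it), and compacts maximal non-branching runs of identically
#' labelled k-mers into unitigs. The default k of 63 targets long reads:
#' longer k-mers reduce graph complexity and make any single k-mer hit far
#' more specific, at the cost of requiring a 63 bp error-free stretch to
#' produce a hit.
#'
#' k-mers containing `N` are skipped entirely (not indexed, never counted as
#' mapped). Transcripts shorter than k contribute no k-mers but are retained
#' in the transcript table so they appear (with zero counts) in downstream
#' abundance output.
#'
#' @param transcripts a [transcript_set], or a named character vector /
#'   `DNAStringSet` coercible to one.
#' @param k odd integer k-mer length, `>= 15`. Default 63.
#' @return an object of class `tdbg_index`.
#' @export
build_index <- function(transcripts, k = 63L) {
  if (!inherits(transcripts, "transcript_set")) {
    transcripts <- transcript_set(as.character(transcripts),
                                  ids = names(transcripts))
  }
  k <- as.integer(k)
  if (is.na(k) || k < 15L) stop("k must be an integer >= 15", call. = FALSE)
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  if (!any(transcripts$length >= k)) {
    stop("no transcript is at least k bases long", call. = FALSE)
  }

  ## --- canonical k-mer -> transcript-set table -------------------------
  n_tx <- length(transcripts$id)
  per_tx <- lapply(seq_len(n_tx), function(i) {
    km <- kmers_of(transcripts$seq[i], k)
    km[!grepl("N", km, fixed = TRUE)]
  })
  canon_all <- canonicalize(unlist(per_tx, use.names = FALSE))$canonical
  tx_all <- rep(seq_len(n_tx) - 1L, lengths(per_tx))  # 0-based ordinals

  keep <- !duplicated(paste0(canon_all, "\t", tx_all))
  canon_u <- canon_all[keep]
  tx_u <- tx_all[keep]

  K <- sort(unique(canon_u), method = "radix")
  n <- length(K)
  ## the k-mer hash stores both orientations: K[i] -> i, revcomp(K[i]) -> -i,
  ## so a read k-mer resolves in one lookup with its orientation in the sign
  node_of <- new.env(parent = emptyenv(), size = max(4L * n, 29L))
  list2env(setNames(as.list(seq_len(n)), K), envir = node_of)
  list2env(setNames(as.list(-seq_len(n)), revcomp(K)), envir = node_of)

  node_idx <- match(canon_u, K)
  tx_by_node <- split(tx_u, node_idx)   # keys ascend numerically
  tx_by_node <- lapply(tx_by_node, function(v) sort.int(unique(v)))
  stopifnot(length(tx_by_node) == n)

  tcc_key_by_node <- vapply(tx_by_node, paste, "", collapse = ",")
  first <- !duplicated(tcc_key_by_node)
  tcc_keys <- unname(tcc_key_by_node[first])
  tccs <- tx_by_node[first]
  names(tccs) <- NULL
  node_tcc <- match(tcc_key_by_node, tcc_keys)

  ## --- raw-graph neighborhoods, orientation-aware ----------------------
  ## outJ/outF: forward successors of K[i] (one column per appended base);
  ## inJ/inF: forward predecessors. Successors of the reverse orientation
  ## are the reverse complements of the forward predecessors, so these four
  ## matrices describe the whole bidirected neighborhood.
  suf <- substring(K, 2L)
  pre <- substring(K, 1L, k - 1L)
  rc_suf <- revcomp(suf)   # revcomp(suf + b) == comp(b) + rc_suf
  rc_pre <- revcomp(pre)   # revcomp(b + pre) == rc_pre + comp(b)
  comp_base <- c(A = "T", C = "G", G = "C", T = "A")
  outJ <- matrix(NA_integer_, n, 4L); outF <- matrix(NA, n, 4L)
  inJ <- matrix(NA_integer_, n, 4L); inF <- matrix(NA, n, 4L)
  for (b in 1:4) {
    cand <- paste0(suf, BASES[b])
    rcc <- paste0(comp_base[[BASES[b]]], rc_suf)
    fwd <- cand <= rcc
    cand[!fwd] <- rcc[!fwd]
    outJ[, b] <- match(cand, K)
    outF[, b] <- fwd
    cand2 <- paste0(BASES[b], pre)
    rcc2 <- paste0(rc_pre, comp_base[[BASES[b]]])
    fwd2 <- cand2 <= rcc2
    cand2[!fwd2] <- rcc2[!fwd2]
    inJ[, b] <- match(cand2, K)
    inF[, b] <- fwd2
  }
  out_hit <- !is.na(outJ); in_hit <- !is.na(inJ)
  outdegF <- as.integer(rowSums(out_hit))
  indegF <- as.integer(rowSums(in_hit))

  ## unique neighbor (meaningful only where the corresponding degree is 1)
  ocol <- max.col(out_hit, ties.method = "first")
  icol <- max.col(in_hit, ties.method = "first")
  osel <- cbind(seq_len(n), ocol); isel <- cbind(seq_len(n), icol)
  uout_j <- outJ[osel]; uout_fwd <- outF[osel]
  uout_j[outdegF != 1L] <- NA_integer_; uout_fwd[outdegF != 1L] <- NA
  uin_j <- inJ[isel]; uin_fwd <- inF[isel]
  uin_j[indegF != 1L] <- NA_integer_; uin_fwd[indegF != 1L] <- NA

  ## --- unitig starts ----------------------------------------------------
  ## (i, o) starts a unitig unless its oriented predecessor p exists
  ## uniquely, has out-degree 1, and carries the same TCC.
  pred_outdeg_F <- ifelse(uin_fwd, outdegF[uin_j], indegF[uin_j])
  startF <- indegF != 1L | pred_outdeg_F != 1L | node_tcc[uin_j] != node_tcc
  startF[is.na(startF)] <- TRUE
  pred_outdeg_R <- ifelse(!uout_fwd, outdegF[uout_j], indegF[uout_j])
  startR <- outdegF != 1L | pred_outdeg_R != 1L | node_tcc[uout_j] != node_tcc
  startR[is.na(startR)] <- TRUE

  ## succ of (i, TRUE) = (uout_j[i], uout_fwd[i]) when outdegF[i] == 1;
  ## succ of (i, FALSE) = (uin_j[i], !uin_fwd[i]) when indegF[i] == 1.
  visited <- logical(n)
  wnode <- integer(n); wfwd <- logical(n); wpos <- 0L  # walk order
  u_start <- integer(n); u_len <- integer(n); n_unitigs <- 0L

  do_walk <- function(i, o) {
    start_pos <- wpos
    repeat {
      wpos <<- wpos + 1L
      wnode[wpos] <<- i; wfwd[wpos] <<- o
      visited[i] <<- TRUE
      if (o) {
        if (outdegF[i] != 1L) break
        j <- uout_j[i]; oj <- uout_fwd[i]
      } else {
        if (indegF[i] != 1L) break
        j <- uin_j[i]; oj <- !uin_fwd[i]
      }
      indeg_j <- if (oj) indegF[j] else outdegF[j]
      if (indeg_j != 1L || node_tcc[j] != node_tcc[i] || visited[j]) break
      i <- j; o <- oj
    }
    n_unitigs <<- n_unitigs + 1L
    u_start[n_unitigs] <<- start_pos + 1L
    u_len[n_unitigs] <<- wpos - start_pos
  }

  for (i in seq_len(n)) {
    if (!visited[i] && startF[i]) do_walk(i, TRUE)
    if (!visited[i] && startR[i]) do_walk(i, FALSE)
  }
  for (i in seq_len(n)) if (!visited[i]) do_walk(i, TRUE)  # isolated cycles

  u_start <- u_start[seq_len(n_unitigs)]
  u_len <- u_len[seq_len(n_unitigs)]
  node_uid <- integer(n); node_off <- integer(n); node_fwd <- logical(n)
  uid_by_pos <- rep.int(seq_len(n_unitigs), u_len)
  off_by_pos <- sequence(u_len) - 1L
  node_uid[wnode] <- uid_by_pos
  node_off[wnode] <- off_by_pos
  node_fwd[wnode] <- wfwd

  ## --- unitig sequences (vectorized over the walk order) ----------------
  ext_chr <- substring(K[wnode], k, k)
  rsel <- !wfwd
  ext_chr[rsel] <- chartr("ACGT", "TGCA", substring(K[wnode[rsel]], 1L, 1L))
  first_km <- K[wnode[u_start]]
  rsel1 <- !wfwd[u_start]
  first_km[rsel1] <- revcomp(first_km[rsel1])
  tails <- character(n_unitigs)
  long_u <- which(u_len > 1L)
  if (length(long_u) > 0) {
    tails[long_u] <- vapply(long_u, function(u) {
      paste(ext_chr[(u_start[u] + 1L):(u_start[u] + u_len[u] - 1L)],
            collapse = "")
    }, "")
  }
  unitig_seq <- paste0(first_km, tails)
  unitig_tcc <- node_tcc[wnode[u_start]]
  unitig_nkmers <- u_len

  ## --- unitig-level edges ((k-1)-overlap adjacency, undirected) ---------
  ## Every raw-graph adjacency incident to node i shows up in its forward
  ## successor or forward predecessor scan; adjacencies between consecutive
  ## k-mers of the same unitig are internal and excluded (offset difference
  ## of 1 within one unitig is taken as internal).
  epairs <- vector("list", 8L)
  for (b in 1:4) {
    src <- which(out_hit[, b]); dst <- outJ[src, b]
    keep_e <- node_uid[src] != node_uid[dst] |
      abs(node_off[src] - node_off[dst]) != 1L
    epairs[[b]] <- cbind(pmin(node_uid[src], node_uid[dst])[keep_e],
                         pmax(node_uid[src], node_uid[dst])[keep_e])
    src2 <- which(in_hit[, b]); dst2 <- inJ[src2, b]
    keep_e2 <- node_uid[src2] != node_uid[dst2] |
      abs(node_off[src2] - node_off[dst2]) != 1L
    epairs[[4L + b]] <- cbind(pmin(node_uid[src2], node_uid[dst2])[keep_e2],
                              pmax(node_uid[src2], node_uid[dst2])[keep_e2])
  }
  edges <- do.call(rbind, epairs)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- edges[!duplicated(edges[, 1] * (n_unitigs + 1) + edges[, 2]), ,
                   drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"

  structure(list(
    format = IDX_FORMAT, version = IDX_VERSION,
    k = k,
    transcript_id = transcripts$id,
    transcript_lengths = transcripts$length,
    kmers = K,
    node_of = node_of,
    node_uid = node_uid, node_off = node_off, node_fwd = node_fwd,
    node_tcc = node_tcc,
    unitig_seq = unitig_seq, unitig_tcc = unitig_tcc,
    unitig_nkmers = unitig_nkmers,
    tccs = tccs, tcc_keys = tcc_keys,
    edges = edges,
    dlist = new.env(parent = emptyenv())
  ), class = "tdbg_index")
}

#' @export
print.tdbg_index <- function(x, ...) {
  cat(sprintf(paste0("tdbg_index: k=%d, %d transcripts, %d k-mers, ",
                     "%d unitigs, %d TCCs, %d d-list k-mers\n"),
              x$k, length(x$transcript_id), length(x$kmers),
              length(x$unitig_seq), length(x$tccs),
              length(ls(x$dlist))))
  invisible(x)
}

#' Look up a single k-mer in the index
#'
#' The query is canonicalized before lookup, so a k-mer and its reverse
#' complement return the same hit with flipped orientation.
#'
#' @param index a `tdbg_index`.
#' @param kmer a single string of length `index$k`.
#' @return `NULL` when the k-mer is absent; otherwise a list with
#'   `unitig_id` (1-based), `offset` (0-based position of the k-mer within
#'   the unitig), `orientation` (`"+"` when the query matches the unitig's
#'   forward k-mer, `"-"` otherwise), `tcc` (sorted 0-based transcript
#'   ordinals) and `tcc_id`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "tdbg_index"))
  kmer <- normalize_seq(kmer)
  if (length(kmer) != 1L || nchar(kmer) != index$k) {
    stop("query must be a single k-mer of length k = ", index$k, call. = FALSE)
  }
  assert_nucleotides(kmer, "k-mer")
  if (grepl("N", kmer, fixed = TRUE)) return(NULL)
  i0 <- index$node_of[[kmer]]
  if (is.null(i0)) return(NULL)
  i <- abs(i0)
  qry_fwd_on_unitig <- (i0 > 0L) == index$node_fwd[i]
  list(unitig_id = index$node_uid[i],
       offset = index$node_off[i],
       orientation = if (qry_fwd_on_unitig) "+" else "-",
       tcc = index$tccs[[index$node_tcc[i]]],
       tcc_id = index$node_tcc[i])
}

#' Attach distinguishing (d-list) k-mers to an index
#'
#' d-list k-mers are "certificates" of non-transcriptomic origin: canonical
#' k-mers present in the supplied sequences (e.g. intronic or genomic flanks)
#' but absent from the transcriptome. During classification, a read touching
#' any d-list k-mer is vetoed as unmapped, preventing erroneous assignment of
#' e.g. intronic reads to exonic transcripts.
#'
#' @param index a `tdbg_index`.
#' @param dlist_sequences character vector (or `transcript_set` /
#'   `DNAStringSet`) of d-list sequences; may be empty.
#' @return the index with its d-list replaced.
#' @export
build_dlist <- function(index, dlist_sequences) {
  stopifnot(inherits(index, "tdbg_index"))
  seqs <- if (inherits(dlist_sequences, "transcript_set")) {
    dlist_sequences$seq
  } else normalize_seq(as.character(dlist_sequences))
  env <- new.env(parent = emptyenv())
  if (length(seqs) > 0) {
    assert_nucleotides(seqs, "d-list sequence")
    km <- unlist(lapply(seqs, kmers_of, k = index$k), use.names = FALSE)
    if (length(km) > 0) {
      km <- km[!grepl("N", km, fixed = TRUE)]
      canon <- unique(canonicalize(km)$canonical)
      novel <- canon[is.na(match(canon, index$kmers))]
      if (length(novel) > 0) {
        ## both orientations, same one-lookup convention as the k-mer map
        list2env(setNames(as.list(rep(TRUE, 2L * length(novel))),
                          c(novel, revcomp(novel))), envir = env)
      }
    }
  }
  index$dlist <- env
  index
}

#' d-list k-mers of an index
#'
#' @param index a `tdbg_index`.
#' @return sorted character vector of canonical d-list k-mers.
#' @export
dlist_kmers <- function(index) {
  keys <- ls(index$dlist)
  keys <- keys[keys <= revcomp(keys)]   # canonical orientation only
  sort(keys, method = "radix")
}

#' Summary statistics of the compacted graph
#'
#' Nodes are unitigs; edges are deduplicated undirected (k-1)-overlap links
#' between unitigs (self-loops counted once). The bp fraction of the largest
#' connected component measures how entangled the transcriptome graph is: at
#' longer k, repeats shorter than k no longer join transcripts, so both the
#' node count and this fraction drop.
#'
#' @param index a `tdbg_index`.
#' @return list with `k`, `n_nodes`, `n_edges`,
#'   `largest_component_bp_fraction` and `total_bp` (summed unitig lengths).
#' @export
graph_stats <- function(index) {
  stopifnot(inherits(index, "tdbg_index"))
  n_nodes <- length(index$unitig_seq)
  bp <- nchar(index$unitig_seq)
  total_bp <- sum(bp)
  g <- igraph::graph_from_data_frame(
    data.frame(from = index$edges[, 1], to = index$edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  comp <- igraph::components(g)
  comp_bp <- tapply(bp, comp$membership, sum)
  list(k = index$k,
       n_nodes = n_nodes,
       n_edges = nrow(index$edges),
       largest_component_bp_fraction = unname(max(comp_bp) / total_bp),
       total_bp = total_bp)
}

#' Serialize / restore an index
#'
#' The on-disk form carries a format and version stamp; loading a file with a
#' different stamp, or a truncated/corrupt file, is an error.
#'
#' @param index a `tdbg_index`.
#' @param path file path.
#' @return `load_index` returns the restored `tdbg_index`; `save_index`
#'   returns `path` invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "tdbg_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(x) || !identical(x$format, IDX_FORMAT)) {
    stop("'", path, "' is not a serialized tdbg_index", call. = FALSE)
  }
  if (!identical(x$version, IDX_VERSION)) {
    stop("index version ", x$version, " does not match supported version ",
         IDX_VERSION, call. = FALSE)
  }
  class(x) <- "tdbg_index"
  x
}

#' Export unitigs as GFA1 for visualization
#'
#' Writes segment (`S`) lines for unitigs and link (`L`) lines for the
#' (k-1)-overlap edges. Link orientations are not tracked in the index and
#' are emitted as `+`; the export targets visual inspection of graph
#' structure (e.g. in Bandage), not sequence reconstruction.
#'
#' @param index a `tdbg_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(index, path) {
  stopifnot(inherits(index, "tdbg_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%d\t%s", seq_along(index$unitig_seq),
                     index$unitig_seq), con)
  if (nrow(index$edges) > 0) {
    writeLines(sprintf("L\t%d\t+\t%d\t+\t%dM",
                       index$edges[, 1], index$edges[, 2], index$k - 1L), con)
  }
  invisible(path)
}
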