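# Brute-force oracles, written along independent routes from the package
# internals: reverse complements come from Biostrings, k-mer TCCs from a
# naive per-transcript scan, graph adjacency from exhaustive prefix/suffix
# matching over oriented k-mers, and read classification from an exhaustive
# per-position scan with the cascade rules applied literally.

o_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

o_canon <- function(x) {
  rc <- o_revcomp(x)
  pmin(x, rc)
}

o_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L), "")
}

# canonical k-mer -> sorted 0-based transcript ordinals, as a named list
o_tcc_map <- function(tx, k) {
  map <- list()
  for (i in seq_along(tx$seq)) {
    km <- o_kmers(tx$seq[i], k)
    km <- km[!grepl("N", km)]
    for (ck in unique(o_canon(km))) {
      map[[ck]] <- union(map[[ck]], i - 1L)
    }
  }
  lapply(map, sort)
}

# exhaustive classification: cascade rules evaluated over every k-mer
o_classify <- function(read, tcc_map, k, dlist = character(0)) {
  km <- o_kmers(read, k)
  if (length(km) == 0) return(list(branch = "unmapped", tcc = NULL))
  km <- km[!grepl("N", km)]
  if (length(km) == 0) return(list(branch = "unmapped", tcc = NULL))
  ck <- o_canon(km)
  if (length(dlist) > 0 && any(ck %in% dlist)) {
    return(list(branch = "dlist_veto", tcc = NULL))
  }
  tccs <- lapply(ck, function(x) tcc_map[[x]])
  hit <- !vapply(tccs, is.null, NA)
  if (!any(hit)) return(list(branch = "unmapped", tcc = NULL))
  tccs <- tccs[hit]
  inter <- Reduce(intersect, tccs)
  if (length(inter) > 0) {
    return(list(branch = "intersection", tcc = sort(inter)))
  }
  keys <- vapply(tccs, paste, "", collapse = ",")
  single <- lengths(tccs) == 1L
  if (any(single)) {
    counts <- table(keys[single])
    top <- names(counts)[counts == max(counts)]
    ords <- as.integer(top)
    return(list(branch = "unique_mode", tcc = min(ords)))
  }
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  vecs <- lapply(strsplit(top, ","), as.integer)
  # order by (min ordinal, then vector lexicographic via zero-padded string)
  pad <- vapply(vecs, function(v) paste(sprintf("%09d", v), collapse = ","), "")
  sel <- order(vapply(vecs, min, 1L), pad)[1]
  list(branch = "mode", tcc = vecs[[sel]])
}

# exhaustive compaction: oriented k-mer adjacency by (k-1) prefix/suffix
# matching, joinable pairs (out-degree 1, in-degree 1, same TCC) merged, and
# the resulting partition of canonical k-mers returned as components.
o_compaction <- function(tx, k) {
  map <- o_tcc_map(tx, k)
  K <- sort(names(map), method = "radix")
  tcc_key <- vapply(map[K], paste, "", collapse = ",")
  oriented <- c(K, o_revcomp(K))                 # 2n oriented strings
  node <- rep(seq_along(K), 2L)
  prefs <- substr(oriented, 1L, k - 1L)
  sufs <- substr(oriented, 2L, k)
  # adjacency a -> b iff suffix(a) == prefix(b)
  adj <- which(outer(sufs, prefs, "=="), arr.ind = TRUE)
  a <- adj[, 1]; b <- adj[, 2]
  outdeg <- tabulate(a, nbins = 2L * length(K))
  indeg <- tabulate(b, nbins = 2L * length(K))
  joinable <- outdeg[a] == 1L & indeg[b] == 1L &
    tcc_key[node[a]] == tcc_key[node[b]]
  g <- igraph::graph_from_data_frame(
    data.frame(from = node[a[joinable]], to = node[b[joinable]]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(K)))
  comp <- igraph::components(g)$membership
  unitig_sets <- split(K, comp)                  # canonical k-mers per unitig
  # unitig-level edges: adjacency pairs that are not joinable
  ua <- comp[node[a[!joinable]]]; ub <- comp[node[b[!joinable]]]
  n_edges <- if (length(ua) == 0) 0L else {
    length(unique(paste0(pmin(ua, ub), "_", pmax(ua, ub))))
  }
  list(kmer_sets = unname(lapply(unitig_sets, sort)),
       n_nodes = length(unitig_sets),
       n_edges = n_edges,
       tcc_key = tcc_key)
}

# implementation-side partition of canonical k-mers into unitigs
impl_kmer_sets <- function(index) {
  unname(lapply(split(index$kmers, index$node_uid), sort))
}

# canonical set-of-sets comparison
expect_same_partition <- function(a, b) {
  norm <- function(x) sort(vapply(x, paste, "", collapse = "|"))
  expect_identical(norm(a), norm(b))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
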