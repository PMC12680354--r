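test_that("single non-repetitive transcript compacts to one unitig", {
  tx <- transcript_set(random_seq(100, seed = 1), "t1")
  idx <- build_index(tx, k = 31)
  expect_length(idx$kmers, 70)            # 100 - 31 + 1
  expect_length(idx$unitig_seq, 1)
  expect_identical(idx$tccs, list(0L))
  st <- graph_stats(idx)
  expect_identical(st$n_nodes, 1L)
  expect_identical(st$n_edges, 0L)
  expect_equal(st$largest_component_bp_fraction, 1.0)
  expect_identical(st$total_bp, 100L)
})

test_that("input validation rejects bad transcript sets and k", {
  expect_error(transcript_set(character(0)), "empty")
  expect_error(transcript_set(c("ACGT", "ACGT"), c("a", "a")), "duplicated")
  expect_error(transcript_set("ACGXT", "a"), "outside")
  tx <- transcript_set(random_seq(100, seed = 2), "t1")
  expect_error(build_index(tx, k = 14), "odd|>= 15")
  expect_error(build_index(tx, k = 32), "odd")
  expect_error(build_index(tx, k = 13), ">= 15")
  short <- transcript_set("ACGTACGT", "s1")
  expect_error(build_index(short, k = 15), "at least k")
})

test_that("k-mer lookup is canonical with orientation, errors on bad input", {
  tx <- transcript_set(random_seq(120, seed = 3), "t1")
  idx <- build_index(tx, k = 31)
  km <- substr(tx$seq, 20, 50)
  h <- lookup_kmer(idx, km)
  hrc <- lookup_kmer(idx, revcomp(km))
  expect_false(is.null(h))
  expect_identical(h$tcc, 0L)
  expect_identical(h$unitig_id, hrc$unitig_id)
  expect_identical(h$offset, hrc$offset)
  expect_false(h$orientation == hrc$orientation)
  expect_null(lookup_kmer(idx, strrep("A", 31)))
  expect_error(lookup_kmer(idx, "ACGT"), "length")
})

test_that("unitig decomposition matches the exhaustive compaction oracle", {
  # two transcripts sharing an internal 25-mer
  set.seed(11)
  block <- random_seq(25)
  t1 <- paste0(random_seq(20), block, random_seq(18))
  t2 <- paste0(random_seq(15), block, random_seq(22))
  tx <- transcript_set(c(t1, t2), c("t1", "t2"))
  idx <- build_index(tx, k = 15)
  oc <- o_compaction(tx, 15)
  expect_same_partition(impl_kmer_sets(idx), oc$kmer_sets)
  st <- graph_stats(idx)
  expect_identical(st$n_nodes, oc$n_nodes)
  expect_identical(st$n_edges, oc$n_edges)

  # branching fixture: three transcripts sharing one exon
  set.seed(12)
  exon <- random_seq(30)
  txs <- vapply(1:3, function(i) {
    paste0(random_seq(20 + 5 * i), exon, random_seq(25 - 3 * i))
  }, "")
  tx3 <- transcript_set(txs, paste0("t", 1:3))
  idx3 <- build_index(tx3, k = 15)
  oc3 <- o_compaction(tx3, 15)
  expect_same_partition(impl_kmer_sets(idx3), oc3$kmer_sets)
  st3 <- graph_stats(idx3)
  expect_identical(st3$n_nodes, oc3$n_nodes)
  expect_identical(st3$n_edges, oc3$n_edges)
})

test_that("compaction matches the oracle on random shared-block fixtures", {
  for (s in 1:6) {
    n_tx <- 3 + (s %% 4)
    blocks <- if (s %% 2 == 0) {
      list(list(transcripts = c(1, 2), width = 24),
           list(transcripts = c(2, 3), width = 20))
    } else NULL
    tx <- generate_transcriptome(n_tx, c(60, 120), shared_blocks = blocks,
                                 seed = 100 + s)
    idx <- build_index(tx, k = 15)
    oc <- o_compaction(tx, 15)
    expect_same_partition(impl_kmer_sets(idx), oc$kmer_sets)
    expect_identical(graph_stats(idx)$n_edges, oc$n_edges)
  }
})

test_that("every TCC is the exact transcript set of its unitig k-mers", {
  tx <- generate_transcriptome(
    5, c(80, 150),
    shared_blocks = list(list(transcripts = c(1, 3), width = 30)),
    seed = 42)
  idx <- build_index(tx, k = 15)
  omap <- o_tcc_map(tx, 15)
  for (u in seq_along(idx$unitig_seq)) {
    ukm <- idx$kmers[idx$node_uid == u]
    expected <- Reduce(intersect, omap[ukm])
    # the TCC must equal the transcripts containing ALL the unitig's k-mers,
    # and by compaction every k-mer in the unitig carries the same set
    for (ck in ukm) expect_identical(omap[[ck]], idx$tccs[[idx$unitig_tcc[u]]])
    expect_identical(sort(expected), idx$tccs[[idx$unitig_tcc[u]]])
  }
})

test_that("all transcript k-mers are indexed and contain their transcript", {
  tx <- generate_transcriptome(
    4, c(100, 200),
    shared_blocks = list(list(transcripts = c(1, 2), width = 40)),
    seed = 7)
  k <- 21
  idx <- build_index(tx, k = k)
  for (i in seq_along(tx$seq)) {
    for (p in seq_len(tx$length[i] - k + 1)) {
      h <- lookup_kmer(idx, substr(tx$seq[i], p, p + k - 1))
      expect_false(is.null(h))
      expect_true((i - 1L) %in% h$tcc)
    }
  }
})

test_that("graph complexity is monotone non-increasing in k", {
  # repeats of 40 bp: shared at k=31 (branch points), invisible at k=63
  tx <- generate_transcriptome(
    8, c(200, 400),
    shared_blocks = list(list(transcripts = c(1, 2), width = 40),
                         list(transcripts = c(3, 4, 5), width = 40)),
    seed = 19)
  st31 <- graph_stats(build_index(tx, k = 31))
  st63 <- graph_stats(build_index(tx, k = 63))
  expect_lte(st63$n_nodes, st31$n_nodes)
  expect_lte(st63$n_edges, st31$n_edges)
  expect_lte(st63$largest_component_bp_fraction,
             st31$largest_component_bp_fraction)
})

test_that("two disjoint equal-length transcripts split bp evenly", {
  tx <- transcript_set(c(random_seq(150, seed = 8), random_seq(150, seed = 9)),
                       c("a", "b"))
  idx <- build_index(tx, k = 31)
  st <- graph_stats(idx)
  expect_identical(st$n_nodes, 2L)
  expect_equal(st$largest_component_bp_fraction, 0.5)
})

test_that("d-list keeps only k-mers absent from the transcriptome", {
  tx <- generate_transcriptome(3, c(100, 150), seed = 31)
  k <- 15
  idx <- build_index(tx, k = k)

  # d-list identical to the transcriptome: nothing is distinguishing
  idx1 <- build_dlist(idx, tx$seq)
  expect_length(dlist_kmers(idx1), 0)

  # one novel 2k-length sequence: k+1 sliding-window k-mers
  novel <- random_seq(2 * k, seed = 77)
  idx2 <- build_dlist(idx, novel)
  expect_length(dlist_kmers(idx2), k + 1)

  # sequence overlapping an exon boundary: equals the set-difference oracle
  mixed <- paste0(substr(tx$seq[1], 1, 30), random_seq(40, seed = 78))
  idx3 <- build_dlist(idx, mixed)
  all_km <- o_canon(o_kmers(mixed, k))
  tx_km <- names(o_tcc_map(tx, k))
  expect_setequal(dlist_kmers(idx3), setdiff(all_km, tx_km))
})

test_that("index serialization round-trips and validates", {
  tx <- generate_transcriptome(3, c(80, 120), seed = 5)
  idx <- build_dlist(build_index(tx, k = 15), random_seq(40, seed = 6))
  f <- tempfile(fileext = ".lrk")
  save_index(idx, f)
  idx2 <- load_index(f)
  expect_identical(idx$kmers, idx2$kmers)
  expect_identical(idx$unitig_seq, idx2$unitig_seq)
  expect_identical(idx$tccs, idx2$tccs)
  expect_identical(idx$edges, idx2$edges)
  expect_identical(idx$k, idx2$k)
  expect_identical(dlist_kmers(idx), dlist_kmers(idx2))
  expect_identical(as.list(idx$node_of, sorted = TRUE),
                   as.list(idx2$node_of, sorted = TRUE))
  expect_identical(graph_stats(idx), graph_stats(idx2))

  empty <- tempfile()
  file.create(empty)
  expect_error(load_index(empty), "cannot read")
  notidx <- tempfile()
  saveRDS(list(a = 1), notidx)
  expect_error(load_index(notidx), "not a serialized")
  stale <- unclass(idx)
  stale$version <- 99L
  saveRDS(stale, notidx)
  expect_error(load_index(notidx), "version")
})

test_that("GFA export lists every unitig and edge", {
  tx <- generate_transcriptome(
    3, c(80, 120),
    shared_blocks = list(list(transcripts = c(1, 2), width = 30)), seed = 15)
  idx <- build_index(tx, k = 15)
  f <- tempfile(fileext = ".gfa")
  write_gfa(idx, f)
  lines <- readLines(f)
  expect_identical(sum(startsWith(lines, "S")), length(idx$unitig_seq))
  expect_identical(sum(startsWith(lines, "L")), nrow(idx$edges))
})
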