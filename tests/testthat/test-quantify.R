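fake_classifications <- function(tcc_keys, read_lengths) {
  data.frame(read_id = paste0("r", seq_along(tcc_keys)),
             branch = ifelse(is.na(tcc_keys), "unmapped", "intersection"),
             tcc_key = tcc_keys,
             n_kmers_examined = 1L,
             read_length = as.integer(read_lengths),
             stringsAsFactors = FALSE)
}

test_that("effective lengths follow the mean-read-length-minus-k rule", {
  tx <- transcript_set(c(random_seq(500, seed = 1), random_seq(500, seed = 2)),
                       c("t0", "t1"))
  idx <- build_index(tx, k = 63)
  cls <- fake_classifications(c("0", "0"), c(100, 200))
  el <- estimate_effective_lengths(cls, idx)
  expect_equal(unname(el$l_e[1]), 300 / 2 - 63)   # = 87
  # untouched transcript falls back to annotated length minus k
  expect_equal(unname(el$l_e[2]), 500 - 63)
  expect_identical(el$fallback_used, c(FALSE, TRUE))

  # clamping: mean read length below k still yields l_e >= 1
  el2 <- estimate_effective_lengths(fake_classifications("0", 64), idx)
  expect_gte(min(el2$l_e), 1)
})

test_that("the read cap truncates the stream exactly", {
  tx <- transcript_set(random_seq(500, seed = 3), "t0")
  idx <- build_index(tx, k = 63)
  lens <- c(100, 150, 200, 250, 300)
  cls <- fake_classifications(rep("0", 5), lens)
  el <- estimate_effective_lengths(cls, idx, cap = 2)
  expect_equal(unname(el$l_e[1]), mean(lens[1:2]) - 63)
  expect_identical(el$n_reads_used, 2L)
  # unmapped reads do not count against the cap
  cls2 <- fake_classifications(c(NA, "0", NA, "0", "0"), lens)
  el2 <- estimate_effective_lengths(cls2, idx, cap = 2)
  expect_equal(unname(el2$l_e[1]), mean(lens[c(2, 4)]) - 63)
  expect_error(estimate_effective_lengths(cls, idx, cap = 0), "positive")
})

test_that("length_norm = FALSE forces unit effective lengths", {
  tx <- transcript_set(random_seq(500, seed = 4), "t0")
  idx <- build_index(tx, k = 63)
  cls <- fake_classifications("0", 300)
  el <- estimate_effective_lengths(cls, idx, length_norm = FALSE)
  expect_true(all(el$l_e == 1))
})

test_that("EM resolves worked class configurations to their fixed points", {
  le <- c(100, 100)
  sym <- list(counts = c("0" = 10, "1" = 10, "0,1" = 10),
              class_members = list(0L, 1L, c(0L, 1L)))
  for (m in c("default", "longread")) {
    em <- run_em(sym, le, mode = m)
    expect_equal(unname(em$est_counts), c(15, 15), tolerance = 1e-6)
  }
  asym <- list(counts = c("0" = 30, "0,1" = 10),
               class_members = list(0L, c(0L, 1L)))
  em_d <- run_em(asym, le, mode = "default")
  em_l <- run_em(asym, le, mode = "longread")
  expect_equal(unname(em_d$est_counts), c(40, 0), tolerance = 1e-6)
  expect_equal(unname(em_l$est_counts), c(35, 5), tolerance = 1e-6)
})

test_that("EM conserves counts and its log-likelihood never decreases", {
  set.seed(71)
  for (rep in 1:5) {
    n_tx <- 6
    n_cls <- 10
    members <- lapply(seq_len(n_cls), function(i) {
      sort(sample(0:(n_tx - 1), sample(1:3, 1)))
    })
    counts <- as.numeric(sample(1:50, n_cls, replace = TRUE))
    names(counts) <- vapply(members, paste, "", collapse = ",")
    le <- runif(n_tx, 50, 500)
    for (m in c("default", "longread")) {
      em <- run_em(list(counts = counts, class_members = members), le,
                   mode = m)
      expect_equal(sum(em$est_counts), sum(counts), tolerance = 1e-9)
      if (length(em$loglik) > 1) {
        expect_true(all(diff(em$loglik) > -1e-9))
      }
    }
  }
  expect_error(run_em(list(counts = c("0" = 1), class_members = list(0L)),
                      c(10), tol = 0), "positive")
})

test_that("EM handles degenerate inputs", {
  empty <- list(counts = numeric(0), class_members = list())
  em <- run_em(empty, c(10, 10))
  expect_equal(unname(em$est_counts), c(0, 0))
  expect_true(em$converged)
  # longread mode with only singleton classes skips EM entirely
  singletons <- list(counts = c("0" = 5, "1" = 7),
                     class_members = list(0L, 1L))
  em2 <- run_em(singletons, c(10, 10), mode = "longread")
  expect_equal(unname(em2$est_counts), c(5, 7))
  expect_identical(em2$n_iters, 0L)
})

test_that("TPM normalizes by effective length to one million", {
  one <- compute_tpm(c(5, 0), c(100, 100))
  expect_equal(one$tpm, c(1e6, 0))
  two <- compute_tpm(c(10, 10), c(200, 100))
  expect_equal(two$tpm[2] / two$tpm[1], 2)
  set.seed(5)
  any_tab <- compute_tpm(runif(20, 0, 100), runif(20, 50, 500))
  expect_equal(sum(any_tab$tpm), 1e6, tolerance = 1e-3)
  none <- compute_tpm(c(0, 0), c(100, 100))
  expect_equal(none$tpm, c(0, 0))
})

test_that("abundance tables round-trip through TSV deterministically", {
  tx <- generate_transcriptome(4, c(100, 200), seed = 6)
  idx <- build_index(tx, k = 31)
  tab <- compute_tpm(c(1.25, 0, 10/3, 7), c(80.5, 120, 99.9, 140), idx)
  f <- tempfile(fileext = ".tsv")
  write_abundance(tab, f)
  back <- read_abundance(f)
  expect_identical(back$target_id, tab$target_id)
  expect_equal(back$est_counts, tab$est_counts, tolerance = 1e-12)
  expect_equal(back$tpm, tab$tpm, tolerance = 1e-12)
  # byte determinism
  f2 <- tempfile()
  write_abundance(tab, f2)
  expect_identical(readLines(f), readLines(f2))
  # header-only output for an empty table
  f3 <- tempfile()
  write_abundance(tab[integer(0), ], f3)
  expect_identical(readLines(f3),
                   "target_id\tlength\teff_length\test_counts\ttpm")
})

test_that("without length normalization the pipeline is pure apportionment", {
  tx <- generate_transcriptome(
    6, c(150, 300),
    shared_blocks = list(list(transcripts = c(1, 2), width = 80)),
    seed = 9)
  idx <- build_index(tx, k = 31)
  sim <- simulate_reads(tx, 120, error_profile(0, "ont"), seed = 10)
  q <- quantify_reads(idx, sim$reads$seq, sim$reads$id, length_norm = FALSE)
  ba <- pseudoalign_batch(idx, sim$reads$seq, sim$reads$id)
  em <- run_em(ba$counts, rep(1, length(tx$id)), mode = "longread")
  expect_equal(q$abundance$est_counts, unname(em$est_counts))
  expect_true(all(q$abundance$eff_length == 1))
})
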