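## Synthetic data: transcriptomes with planted shared blocks, expression
## profiles, full-length/fragment read generation, and error injection from
## technology-style error profiles. Every function is a pure function of its
## inputs and seed.

#' Sequencing error profile
#'
#' A profile is a per-base error rate plus the split of error events into
#' deletions, substitutions and insertions, applied uniformly across read
#' positions. Two technology presets are provided:
#' \describe{
#'   \item{ont}{38.5\% deletions, 38.5\% substitutions, 23\% insertions.}
#'   \item{pacbio}{24.5\% deletions, 52.4\% substitutions, 23.1\%
#'     insertions.}
#' }
#'
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param preset `"ont"`, `"pacbio"`, or `"custom"`.
#' @param del_frac,sub_frac,ins_frac event-type fractions (must sum to 1);
#'   required for `preset = "custom"`, ignored otherwise.
#' @return list of class `error_profile` with `error_rate`, `del_frac`,
#'   `sub_frac`, `ins_frac`, `positional_model = "uniform"` and `preset`.
#' @export
error_profile <- function(error_rate, preset = c("custom", "ont", "pacbio"),
                          del_frac = NULL, sub_frac = NULL, ins_frac = NULL) {
  preset <- match.arg(preset)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  fr <- switch(preset,
    ont = c(0.385, 0.385, 0.23),
    pacbio = c(0.245, 0.524, 0.231),
    custom = c(del_frac, sub_frac, ins_frac))
  if (length(fr) != 3 || any(fr < 0)) {
    stop("del_frac, sub_frac, ins_frac must be three non-negative fractions",
         call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("error-type fractions must sum to 1", call. = FALSE)
  }
  structure(list(error_rate = error_rate, del_frac = fr[1], sub_frac = fr[2],
                 ins_frac = fr[3], positional_model = "uniform",
                 preset = preset),
            class = "error_profile")
}

#' Generate a random transcriptome with optional shared blocks
#'
#' Draws independent uniform-ACGT sequences and optionally plants identical
#' subsequence blocks across chosen transcripts, creating the multi-mapping
#' structure (shared exons) that exercises transcript compatibility classes.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range integer vector of length 2, min/max transcript length;
#'   lengths are drawn uniformly. Intended to be at least `2k` for the k the
#'   fixture will be indexed at.
#' @param shared_blocks optional list of blocks; each block is a list with
#'   `transcripts` (1-based indices, >= 2 of them) and `width` (block length
#'   in bp). The block sequence is drawn once and written into each listed
#'   transcript at a random feasible position.
#' @param seed integer seed; same seed, same output.
#' @return a [transcript_set] with ids `tx0..tx(n-1)`.
#' @export
generate_transcriptome <- function(n_transcripts, length_range = c(500L, 1500L),
                                   shared_blocks = NULL, seed = 1L) {
  if (n_transcripts < 1) stop("n_transcripts must be >= 1", call. = FALSE)
  stopifnot(length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  rng <- local_rng(seed)
  lens <- rng$integer(n_transcripts, length_range[1], length_range[2])
  seqs <- vapply(lens, function(L) {
    paste(BASES[rng$integer(L, 1L, 4L)], collapse = "")
  }, "")
  if (!is.null(shared_blocks)) {
    for (blk in shared_blocks) {
      txs <- blk$transcripts
      w <- blk$width
      if (length(txs) < 2 || any(txs < 1 | txs > n_transcripts)) {
        stop("shared block must name >= 2 valid transcripts", call. = FALSE)
      }
      if (any(lens[txs] < w)) {
        stop("shared block wider than a target transcript", call. = FALSE)
      }
      block <- paste(BASES[rng$integer(w, 1L, 4L)], collapse = "")
      for (t in txs) {
        pos <- rng$integer(1L, 1L, lens[t] - w + 1L)
        substr(seqs[t], pos, pos + w - 1L) <- block
      }
    }
  }
  transcript_set(seqs, ids = paste0("tx", seq_len(n_transcripts) - 1L))
}

#' Draw an expression profile and ground-truth counts
#'
#' @param transcripts a [transcript_set].
#' @param n_reads_total total number of reads to allot.
#' @param model `"uniform"` (counts as equal as integer division allows, the
#'   remainder going one read each to the lowest ordinals) or `"lognormal"`
#'   (multinomial draw with weights proportional to a lognormal sample).
#' @param meanlog,sdlog lognormal parameters (defaults 0 and 1).
#' @param seed integer seed.
#' @return list of class `sim_truth` with `target_id`, `true_counts`
#'   (integer, summing to `n_reads_total`), `true_tpm` (consistent with
#'   counts and annotated lengths), `model` and `seed`.
#' @export
sample_expression <- function(transcripts, n_reads_total,
                              model = c("uniform", "lognormal"),
                              meanlog = 0, sdlog = 1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(transcripts, "transcript_set"), n_reads_total >= 0)
  n <- length(transcripts$id)
  if (model == "uniform") {
    base <- n_reads_total %/% n
    counts <- rep(base, n)
    r <- n_reads_total %% n
    if (r > 0) counts[seq_len(r)] <- counts[seq_len(r)] + 1L
  } else {
    rng <- local_rng(seed)
    w <- rng$lognormal(n, meanlog, sdlog)
    counts <- rng$multinomial(n_reads_total, w / sum(w))
  }
  dens <- counts / transcripts$length
  tpm <- if (sum(dens) > 0) 1e6 * dens / sum(dens) else rep(0, n)
  structure(list(target_id = transcripts$id,
                 true_counts = as.integer(counts),
                 true_tpm = tpm, model = model, seed = seed),
            class = "sim_truth")
}

#' Generate error-free reads from a truth profile
#'
#' `full_length` mode emits each source transcript's entire sequence as the
#' read (the long-read idealization); `fragment` mode emits a uniform random
#' substring of length at least `min_len`. Each read's strand is flipped with
#' probability 0.5. Read ids encode the source transcript
#' (`<target_id>:<n>`), so oracle checks can recover provenance.
#'
#' @param transcripts a [transcript_set].
#' @param truth a `sim_truth` from [sample_expression] (same transcripts).
#' @param read_model `"full_length"` or `"fragment"`.
#' @param min_len minimum fragment length (fragment mode only).
#' @param seed integer seed.
#' @return list with `id`, `seq`, `source` (transcript id per read) and
#'   `n_skipped` (fragment mode: transcripts shorter than `min_len`, skipped
#'   with a warning).
#' @export
generate_reads <- function(transcripts, truth,
                           read_model = c("full_length", "fragment"),
                           min_len = 200L, seed = 1L) {
  read_model <- match.arg(read_model)
  stopifnot(inherits(transcripts, "transcript_set"),
            identical(truth$target_id, transcripts$id))
  rng <- local_rng(seed)
  counts <- truth$true_counts
  n_skipped <- 0L
  src <- rep(seq_along(counts), counts)
  if (read_model == "fragment") {
    short <- transcripts$length[src] < min_len
    if (any(short)) {
      n_skipped <- sum(short)
      warning(n_skipped, " reads skipped: source transcript shorter than min_len")
      src <- src[!short]
    }
  }
  n <- length(src)
  if (read_model == "full_length") {
    seqs <- transcripts$seq[src]
  } else {
    tl <- transcripts$length[src]
    len <- vapply(tl, function(L) rng$integer(1L, min_len, L), 1L)
    start <- vapply(seq_len(n), function(i) {
      rng$integer(1L, 1L, tl[i] - len[i] + 1L)
    }, 1L)
    seqs <- substr(transcripts$seq[src], start, start + len - 1L)
  }
  flip <- rng$uniform(n) < 0.5
  seqs[flip] <- revcomp(seqs[flip])
  ord_count <- integer(length(counts))
  idn <- integer(n)
  for (i in seq_len(n)) {
    ord_count[src[i]] <- ord_count[src[i]] + 1L
    idn[i] <- ord_count[src[i]]
  }
  list(id = paste0(transcripts$id[src], ":", idn),
       seq = seqs,
       source = transcripts$id[src],
       n_skipped = n_skipped)
}

#' Inject sequencing errors into reads
#'
#' For each read, the number of error events is drawn
#' `Binomial(read_length, error_rate)`; each event is independently typed
#' (deletion / substitution / insertion) by the profile fractions and placed
#' uniformly at random. Substitutions replace a base with a different base
#' chosen uniformly; insertions insert a uniform base at a uniform position
#' (including both ends); deletions remove a single base. Events are applied
#' sequentially, positions drawn against the current sequence.
#'
#' @param reads character vector of read sequences (or the list returned by
#'   [generate_reads], whose `seq` is used and other fields passed through).
#' @param profile an [error_profile].
#' @param seed integer seed.
#' @return list with `seq` (mutated reads), `tally` (matrix, one row per
#'   read, columns `del`, `sub`, `ins` of realized event counts), and any
#'   pass-through fields (`id`, `source`).
#' @export
inject_errors <- function(reads, profile, seed = 1L) {
  stopifnot(inherits(profile, "error_profile"))
  passthru <- NULL
  if (is.list(reads) && !is.null(reads$seq)) {
    passthru <- reads[setdiff(names(reads), "seq")]
    reads <- reads$seq
  }
  n <- length(reads)
  tally <- matrix(0L, nrow = n, ncol = 3,
                  dimnames = list(NULL, c("del", "sub", "ins")))
  out <- reads
  if (profile$error_rate > 0 && n > 0) {
    rng <- local_rng(seed)
    fr <- c(profile$del_frac, profile$sub_frac, profile$ins_frac)
    cum <- cumsum(fr)
    for (i in seq_len(n)) {
      L0 <- nchar(reads[i])
      n_ev <- rng$binomial(L0, profile$error_rate)
      if (n_ev == 0L) next
      s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (ev in seq_len(n_ev)) {
        type <- findInterval(rng$uniform(1L), cum) + 1L  # 1=del 2=sub 3=ins
        L <- length(s)
        if (type == 1L) {                       # deletion
          if (L == 0L) next
          pos <- rng$integer(1L, 1L, L)
          s <- s[-pos]
          tally[i, 1L] <- tally[i, 1L] + 1L
        } else if (type == 2L) {                # substitution
          if (L == 0L) next
          pos <- rng$integer(1L, 1L, L)
          alt <- setdiff(BASES, s[pos])
          s[pos] <- alt[rng$integer(1L, 1L, length(alt))]
          tally[i, 2L] <- tally[i, 2L] + 1L
        } else {                                # insertion
          pos <- rng$integer(1L, 0L, L)         # insert after position pos
          b <- BASES[rng$integer(1L, 1L, 4L)]
          s <- append(s, b, after = pos)
          tally[i, 3L] <- tally[i, 3L] + 1L
        }
      }
      out[i] <- paste(s, collapse = "")
    }
  }
  c(list(seq = out, tally = tally), passthru)
}

#' One-call read simulation
#'
#' Convenience wrapper: expression profile, error-free reads, then error
#' injection, with per-stage seeds derived deterministically from `seed`.
#'
#' @param transcripts a [transcript_set].
#' @param n_reads total reads.
#' @param profile an [error_profile]; `error_rate = 0` leaves reads
#'   untouched.
#' @param expr_model,read_model,min_len,meanlog,sdlog passed through.
#' @param seed integer master seed.
#' @return list with `reads` (the [inject_errors] result) and `truth` (the
#'   `sim_truth`).
#' @export
simulate_reads <- function(transcripts, n_reads, profile,
                           expr_model = "uniform",
                           read_model = "full_length", min_len = 200L,
                           meanlog = 0, sdlog = 1, seed = 1L) {
  seed <- as.integer(seed)
  truth <- sample_expression(transcripts, n_reads, model = expr_model,
                             meanlog = meanlog, sdlog = sdlog,
                             seed = seed)
  rd <- generate_reads(transcripts, truth, read_model = read_model,
                       min_len = min_len, seed = seed + 1000L)
  er <- inject_errors(rd, profile, seed = seed + 2000L)
  list(reads = er, truth = truth)
}

#' Write ground truth as TSV
#'
#' Columns `target_id`, `true_counts`, `true_tpm`.
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(target_id = truth$target_id,
                   true_counts = truth$true_counts,
                   true_tpm = formatC(truth$true_tpm, digits = 15,
                                      format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth TSV
#'
#' @param path a TSV with at least `target_id` and `true_counts`
#'   (and optionally `true_tpm`) columns.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## Seeded RNG scoped to one generator call: draws come from an isolated
## RNG stream so simulator calls neither disturb nor depend on the caller's
## RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    integer = function(n, lo, hi) with_state(function()
      as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))),
    uniform = function(n) with_state(function() stats::runif(n)),
    binomial = function(size, prob) with_state(function()
      stats::rbinom(1L, size, prob)),
    lognormal = function(n, meanlog, sdlog) with_state(function()
      stats::rlnorm(n, meanlog, sdlog)),
    multinomial = function(size, prob) with_state(function()
      as.integer(stats::rmultinom(1L, size, prob)[, 1]))
  )
}
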