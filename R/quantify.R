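## Abundance estimation: transcript-specific effective lengths, the EM
## algorithm in its default and long-read variants, and the abundance table.

#' Transcript-specific effective lengths from observed read lengths
#'
#' For long reads there is no fragment-length distribution to integrate over;
#' instead the effective length of transcript t is estimated from the data as
#' the mean length of reads compatible with t, minus k:
#'
#'   l_e(t) = sum(l_r over reads whose TCC contains t) / (number of such
#'            reads) - k
#'
#' Only the first `cap` mapped reads (in stream order) are used; the default
#' cap of one million is enough to cover every expressed transcript in
#' human/mouse scale data while bounding the pass over the stream.
#' Transcripts seen in no read fall back to `max(annotated_length - k, 1)`.
#' All values are clamped to >= 1.
#'
#' @param classifications the `classifications` data.frame from
#'   [pseudoalign_batch], in stream order.
#' @param index the [tdbg_index][build_index] used for alignment (supplies k
#'   and annotated lengths).
#' @param cap maximum number of mapped reads to use (default 1e6).
#' @param length_norm when `FALSE`, skip estimation entirely and return
#'   `l_e = 1` for every transcript, removing any length effect from the EM;
#'   recommended at high or non-uniform sequencing error rates, where
#'   length normalization hurts rather than helps.
#' @return list with `l_e` (named numeric, reference order), `n_reads_used`,
#'   and `fallback_used` (logical per transcript).
#' @export
estimate_effective_lengths <- function(classifications, index,
                                       cap = 1000000L, length_norm = TRUE) {
  stopifnot(inherits(index, "tdbg_index"))
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive", call. = FALSE)
  n_tx <- length(index$transcript_id)
  if (!length_norm) {
    return(list(l_e = setNames(rep(1, n_tx), index$transcript_id),
                n_reads_used = 0L,
                fallback_used = rep(FALSE, n_tx)))
  }
  mapped <- classifications[!is.na(classifications$tcc_key), , drop = FALSE]
  n_used <- min(nrow(mapped), as.integer(cap))
  mapped <- mapped[seq_len(n_used), , drop = FALSE]

  len_sum <- numeric(n_tx)
  n_reads <- numeric(n_tx)
  if (n_used > 0) {
    members <- strsplit(mapped$tcc_key, ",", fixed = TRUE)
    tx <- as.integer(unlist(members, use.names = FALSE)) + 1L  # 1-based
    rl <- rep(mapped$read_length, lengths(members))
    s <- rowsum(cbind(rl, 1), tx)
    idx <- as.integer(rownames(s))
    len_sum[idx] <- s[, 1]
    n_reads[idx] <- s[, 2]
  }
  fallback <- n_reads == 0
  l_e <- numeric(n_tx)
  l_e[!fallback] <- len_sum[!fallback] / n_reads[!fallback] - index$k
  l_e[fallback] <- index$transcript_lengths[fallback] - index$k
  l_e <- pmax(l_e, 1)
  list(l_e = setNames(l_e, index$transcript_id),
       n_reads_used = n_used,
       fallback_used = fallback)
}

#' EM estimation of transcript counts from TCC counts
#'
#' Apportions multi-mapping reads among transcripts by
#' expectation-maximization under the standard generative model: a read
#' arises from transcript t with probability proportional to
#' `alpha_t / l_e(t)`, and a class c is observed when the read's transcript
#' lies in c. The update is
#'
#'   alpha_t <- sum over classes c containing t of
#'              n_c * (alpha_t / l_e(t)) / sum_{u in c} (alpha_u / l_e(u))
#'
#' Two variants are offered:
#' \describe{
#'   \item{default}{EM over all classes; `alpha` initialized to each
#'     transcript's unique (singleton-class) count plus an equal share of
#'     every multi-mapping class it belongs to.}
#'   \item{longread}{EM over multi-mapping classes (size >= 2) only,
#'     initialized uniformly over the transcripts those classes touch;
#'     after convergence each singleton class's count is added to its
#'     transcript. Keeping unique counts out of the EM stops highly covered
#'     transcripts from absorbing ambiguous reads, which helps under uniform
#'     indel-heavy error profiles.}
#' }
#' Both variants conserve the total mapped count exactly.
#'
#' @param tcc_counts a `tcc_counts` object from [pseudoalign_batch], or a
#'   list with `counts` (numeric) and `class_members` (list of 0-based
#'   ordinal vectors).
#' @param eff_lengths result of [estimate_effective_lengths], or a numeric
#'   vector of effective lengths (reference order).
#' @param n_transcripts number of transcripts (required when `eff_lengths`
#'   is a bare vector of a different source; defaults to its length).
#' @param mode `"default"` or `"longread"`.
#' @param tol convergence threshold on the max relative change of `alpha`
#'   (only transcripts with `alpha > 1e-8` are monitored). Default 1e-8.
#' @param max_iters iteration cap, default 10000.
#' @return list with `est_counts` (numeric, reference order), `n_iters`,
#'   `converged`, and `loglik` (observed-data log-likelihood trace, one value
#'   per iteration).
#' @export
run_em <- function(tcc_counts, eff_lengths, n_transcripts = NULL,
                   mode = c("longread", "default"),
                   tol = 1e-8, max_iters = 10000L) {
  mode <- match.arg(mode)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)
  counts <- tcc_counts$counts
  members <- tcc_counts$class_members
  le <- if (is.list(eff_lengths)) eff_lengths$l_e else eff_lengths
  if (is.null(n_transcripts)) n_transcripts <- length(le)
  if (any(le <= 0)) stop("effective lengths must be positive", call. = FALSE)
  est <- numeric(n_transcripts)
  names(est) <- names(le)
  if (length(counts) == 0 || sum(counts) == 0) {
    return(list(est_counts = est, n_iters = 0L, converged = TRUE,
                loglik = numeric(0)))
  }
  sizes <- lengths(members)
  uniq_tx <- unlist(members[sizes == 1L], use.names = FALSE) + 1L
  uniq_counts <- numeric(n_transcripts)
  if (length(uniq_tx) > 0) {
    s <- rowsum(counts[sizes == 1L], uniq_tx)
    uniq_counts[as.integer(rownames(s))] <- s[, 1]
  }

  if (mode == "default") {
    em_members <- members; em_counts <- counts
    alpha <- uniq_counts
    if (any(sizes > 1L)) {
      sh <- rowsum(rep(counts[sizes > 1L] / sizes[sizes > 1L],
                       sizes[sizes > 1L]),
                   unlist(members[sizes > 1L], use.names = FALSE) + 1L)
      alpha[as.integer(rownames(sh))] <-
        alpha[as.integer(rownames(sh))] + sh[, 1]
    }
  } else {
    multi <- sizes > 1L
    em_members <- members[multi]; em_counts <- counts[multi]
    alpha <- numeric(n_transcripts)
    tx_in <- unique(unlist(em_members, use.names = FALSE)) + 1L
    if (length(tx_in) > 0) alpha[tx_in] <- sum(em_counts) / length(tx_in)
  }

  loglik <- numeric(0)
  n_iters <- 0L
  converged <- length(em_counts) == 0L
  if (!converged) {
    cls_idx <- rep(seq_along(em_members), lengths(em_members))
    tx_idx <- unlist(em_members, use.names = FALSE) + 1L
    N <- sum(em_counts)
    repeat {
      n_iters <- n_iters + 1L
      w <- alpha / le
      wm <- w[tx_idx]
      denom <- rowsum(wm, cls_idx)[, 1]
      zero <- denom <= 0
      if (any(zero)) {
        ## a class whose members all hit zero abundance: reseed uniformly
        for (ci in which(zero)) {
          mem <- em_members[[ci]] + 1L
          alpha[mem] <- alpha[mem] + em_counts[ci] / length(mem)
        }
        w <- alpha / le; wm <- w[tx_idx]
        denom <- rowsum(wm, cls_idx)[, 1]
      }
      ## observed-data log-likelihood of the class counts under theta = alpha/N:
      ## sum_c n_c log(sum_{t in c} theta_t / l_e(t)); sum(alpha) stays N
      loglik[n_iters] <- sum(em_counts * log(denom)) - N * log(sum(alpha))
      contrib <- em_counts[cls_idx] * wm / denom[cls_idx]
      alpha_new <- numeric(n_transcripts)
      s <- rowsum(contrib, tx_idx)
      alpha_new[as.integer(rownames(s))] <- s[, 1]
      active <- alpha_new > 1e-8
      delta <- if (any(active)) {
        max(abs(alpha_new[active] - alpha[active]) / alpha_new[active])
      } else 0
      alpha <- alpha_new
      if (delta < tol) { converged <- TRUE; break }
      if (n_iters >= max_iters) break
    }
  }

  est <- alpha
  if (mode == "longread") est <- est + uniq_counts
  ## exact conservation against accumulated floating error
  tot <- sum(est)
  target <- sum(counts)
  if (tot > 0) est <- est * (target / tot)
  names(est) <- names(le)
  list(est_counts = est, n_iters = n_iters, converged = converged,
       loglik = loglik)
}

#' TPM from estimated counts and effective lengths
#'
#' `tpm_t = 1e6 * (est_counts_t / l_e(t)) / sum_u (est_counts_u / l_e(u))`;
#' all zero when nothing is expressed.
#'
#' @param est_counts numeric vector of estimated counts (reference order).
#' @param eff_lengths result of [estimate_effective_lengths] or numeric
#'   vector of the same length.
#' @param index optional [tdbg_index][build_index] supplying ids and
#'   annotated lengths for the table.
#' @return data.frame of class `abundance_table` with columns `target_id`,
#'   `length`, `eff_length`, `est_counts`, `tpm`, in reference order.
#' @export
compute_tpm <- function(est_counts, eff_lengths, index = NULL) {
  le <- if (is.list(eff_lengths)) eff_lengths$l_e else eff_lengths
  stopifnot(length(est_counts) == length(le))
  dens <- est_counts / le
  tot <- sum(dens)
  tpm <- if (tot > 0) 1e6 * dens / tot else rep(0, length(dens))
  ids <- if (!is.null(index)) index$transcript_id
         else if (!is.null(names(est_counts))) names(est_counts)
         else paste0("tx", seq_along(est_counts) - 1L)
  lens <- if (!is.null(index)) index$transcript_lengths
          else rep(NA_integer_, length(est_counts))
  structure(data.frame(target_id = ids, length = lens, eff_length = unname(le),
                       est_counts = unname(est_counts), tpm = unname(tpm),
                       stringsAsFactors = FALSE),
            class = c("abundance_table", "data.frame"))
}

#' Write / read a kallisto-style abundance table
#'
#' Tab-separated with header `target_id length eff_length est_counts tpm`,
#' rows in reference order. Numeric columns are written with full precision
#' (15 significant digits), so write/read round-trips are stable and output
#' is byte-deterministic for fixed input.
#'
#' @param table an `abundance_table` (or compatible data.frame).
#' @param path output path.
#' @return `path` invisibly; `read_abundance` returns the data.frame.
#' @export
write_abundance <- function(table, path) {
  df <- as.data.frame(table)
  need <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  for (col in c("eff_length", "est_counts", "tpm")) {
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(need, collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("abundance_table", "data.frame"))
}

#' Full long-read quantification pipeline
#'
#' Pseudoaligns reads, estimates transcript-specific effective lengths from
#' the first `cap` mapped reads, runs the EM in the chosen variant, and
#' returns the abundance table plus run metadata.
#'
#' @param index a [tdbg_index][build_index].
#' @param reads sequences / path, as for [pseudoalign_batch].
#' @param read_ids optional identifiers.
#' @param em_mode `"longread"` (default) or `"default"`.
#' @param length_norm use transcript-specific effective lengths (`TRUE`) or
#'   uniform `l_e = 1` (`FALSE`, the default for long reads; see
#'   [estimate_effective_lengths]).
#' @param cap effective-length read cap (default 1e6).
#' @param tol,max_iters EM convergence controls.
#' @return list with `abundance` (an `abundance_table`), `eff_lengths`,
#'   `em` (the [run_em] result), `mapping_rate`, `branch_tally`, and
#'   `classifications`.
#' @export
quantify_reads <- function(index, reads, read_ids = NULL,
                           em_mode = c("longread", "default"),
                           length_norm = FALSE, cap = 1000000L,
                           tol = 1e-8, max_iters = 10000L) {
  em_mode <- match.arg(em_mode)
  ba <- pseudoalign_batch(index, reads, read_ids)
  el <- estimate_effective_lengths(ba$classifications, index,
                                   cap = cap, length_norm = length_norm)
  em <- run_em(ba$counts, el, mode = em_mode, tol = tol,
               max_iters = max_iters)
  ab <- compute_tpm(em$est_counts, el, index)
  list(abundance = ab,
       eff_lengths = el,
       em = em,
       mapping_rate = ba$mapping_rate,
       branch_tally = table(ba$classifications$branch),
       classifications = ba$classifications)
}
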