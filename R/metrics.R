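## Agreement metrics between estimated and ground-truth abundances.

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line y = x:
#' `2*cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with population
#' (1/n) moments as in Lin's original definition. Unlike Pearson correlation
#' it penalizes scale and location shifts. Two identical constant vectors
#' give 1 by convention; a constant vector against a non-constant one gives 0
#' (zero covariance).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return scalar in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)  # identical constant vectors
  2 * cxy / denom
}

#' Normalized root mean squared error
#'
#' `RMSE(truth, est) / sd(truth)` with population (1/n) moments. Zero for a
#' perfect estimate; 1 for an estimator no better than predicting the truth's
#' mean.
#'
#' @param truth,est numeric vectors of equal length; `truth` must not be
#'   constant.
#' @return non-negative scalar.
#' @export
nrmse <- function(truth, est) {
  if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
  n <- length(truth)
  sdt <- sqrt(sum((truth - mean(truth))^2) / n)
  if (sdt == 0) stop("truth is constant; NRMSE undefined", call. = FALSE)
  sqrt(mean((truth - est)^2)) / sdt
}

#' Median relative difference
#'
#' Median over transcripts of `|est - truth| / truth`. By default only truly
#' expressed transcripts (`truth > 0`) enter; with `expressed_only = FALSE`
#' the denominator is guarded as `max(truth, eps)` so zero-truth transcripts
#' contribute `est / eps`-scale penalties rather than dividing by zero.
#'
#' @param truth,est numeric vectors of equal length.
#' @param expressed_only restrict to `truth > 0` (default `TRUE`).
#' @param eps denominator guard used when `expressed_only = FALSE`
#'   (default 1e-8).
#' @return non-negative scalar.
#' @export
mrd <- function(truth, est, expressed_only = TRUE, eps = 1e-8) {
  if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
  if (expressed_only) {
    keep <- truth > 0
    if (!any(keep)) stop("no expressed transcripts", call. = FALSE)
    stats::median(abs(est[keep] - truth[keep]) / truth[keep])
  } else {
    stats::median(abs(est - truth) / pmax(truth, eps))
  }
}

#' Percent expressed transcripts detected
#'
#' `100 * |{t : truth > 0 and est > threshold}| / |{t : truth > 0}|` — the
#' share of truly expressed transcripts whose estimate exceeds the detection
#' threshold (default 0: any positive estimate counts as detected).
#'
#' @param truth,est numeric vectors of equal length.
#' @param detect_threshold detection cutoff on the estimate (default 0).
#' @return percentage in `[0, 100]`.
#' @export
pet <- function(truth, est, detect_threshold = 0) {
  if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
  expressed <- truth > 0
  if (!any(expressed)) stop("no expressed transcripts", call. = FALSE)
  100 * sum(expressed & est > detect_threshold) / sum(expressed)
}

#' Full metric report for an estimate against ground truth
#'
#' Joins the two tables on `target_id` (outer join, missing entries counted
#' as zero), applies the chosen transform to both vectors for the
#' correlation-type metrics (CCC, Pearson, Spearman, NRMSE), and computes MRD
#' and PET on the untransformed values. The default `log2p1` transform
#' (`log2(x + 1)`) matches how expression agreement is usually visualized
#' while keeping zeros finite; the transform applied is recorded in the
#' report so results remain comparable.
#'
#' @param truth data.frame with `target_id` plus `true_counts` / `true_tpm`
#'   (e.g. from [read_truth] or [sample_expression]).
#' @param est data.frame with `target_id` plus `est_counts` / `tpm`
#'   (an `abundance_table`).
#' @param transform `"log2p1"` or `"identity"`.
#' @param unit compare in `"tpm"` or `"counts"`.
#' @return list of class `metric_report` with `ccc`, `pearson`, `spearman`,
#'   `nrmse`, `mrd`, `pet`, `n_transcripts`, `transform`, `unit`.
#' @export
evaluate_abundances <- function(truth, est,
                                transform = c("log2p1", "identity"),
                                unit = c("tpm", "counts")) {
  transform <- match.arg(transform)
  unit <- match.arg(unit)
  truth <- as.data.frame(unclass(truth)[c("target_id",
    intersect(c("true_counts", "true_tpm"), names(truth)))],
    stringsAsFactors = FALSE)
  est <- as.data.frame(est)
  tcol <- if (unit == "tpm") "true_tpm" else "true_counts"
  ecol <- if (unit == "tpm") "tpm" else "est_counts"
  if (!tcol %in% names(truth)) stop("truth table lacks ", tcol, call. = FALSE)
  if (!ecol %in% names(est)) stop("estimate table lacks ", ecol, call. = FALSE)
  ids <- union(truth$target_id, est$target_id)
  if (length(intersect(truth$target_id, est$target_id)) == 0) {
    stop("truth and estimate share no transcript ids", call. = FALSE)
  }
  tv <- ev <- numeric(length(ids))
  tv[match(truth$target_id, ids)] <- as.numeric(truth[[tcol]])
  ev[match(est$target_id, ids)] <- as.numeric(est[[ecol]])
  f <- if (transform == "log2p1") function(x) log2(x + 1) else identity
  tt <- f(tv); ee <- f(ev)
  structure(list(
    ccc = ccc(tt, ee),
    pearson = stats::cor(tt, ee, method = "pearson"),
    spearman = stats::cor(tt, ee, method = "spearman"),
    nrmse = nrmse(tt, ee),
    mrd = mrd(tv, ev),
    pet = pet(tv, ev),
    n_transcripts = length(ids),
    transform = transform,
    unit = unit
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (%d transcripts, unit=%s, transform=%s)\n",
    x$n_transcripts, x$unit, x$transform))
  cat(sprintf("  CCC      %8.4f\n  Pearson  %8.4f\n  Spearman %8.4f\n",
              x$ccc, x$pearson, x$spearman))
  cat(sprintf("  NRMSE    %8.4f\n  MRD      %8.4f\n  PET      %7.2f%%\n",
              x$nrmse, x$mrd, x$pet))
  invisible(x)
}
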