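# DTW alignment, truncation and the four similarity metrics.

new_warp_alignment <- function(pairs, nq, nr, distance = NA_real_,
                               truncated = FALSE,
                               truncated_head_q = 0L, truncated_head_r = 0L,
                               truncated_tail_q = 0L, truncated_tail_r = 0L) {
  pairs <- as.matrix(pairs)
  colnames(pairs) <- c("query", "reference")
  structure(list(
    pairs = pairs, nq = as.integer(nq), nr = as.integer(nr),
    distance = distance, truncated = truncated,
    q_keep = range(pairs[, 1]), r_keep = range(pairs[, 2]),
    truncated_head_q = truncated_head_q, truncated_head_r = truncated_head_r,
    truncated_tail_q = truncated_tail_q, truncated_tail_r = truncated_tail_r,
    insufficient = nrow(pairs) < 3L
  ), class = "warp_alignment")
}

#' Align two time series by dynamic time warping
#'
#' Computes the globally optimal monotone warping path between the two value
#' sequences under the symmetric2 step pattern (diagonal steps weighted 2,
#' horizontal/vertical steps weighted 1) with absolute-difference local
#' cost. The path starts at the first pair of indices and ends at the last
#' pair of both series; no truncation is applied here (see
#' [truncate_alignment()]). Among cost-equal optima the backtrace prefers
#' the diagonal step, then the step advancing the query.
#'
#' @param query,reference [time_series()] objects with at least 3 points,
#'   typically scaled to `[0, 1]`.
#' @return A `warp_alignment`: the `pairs` matrix of 1-based
#'   (query index, reference index) steps, series lengths `nq`/`nr`, the
#'   accumulated DTW distance, and (after truncation) retained index ranges
#'   and per-end truncation counts.
#' @export
#' @examples
#' s <- time_series(0:4, c(0, .2, .5, .9, 1))
#' dtw_align(s, s)$pairs  # the diagonal
dtw_align <- function(query, reference) {
  stopifnot(inherits(query, "time_series"), inherits(reference, "time_series"))
  if (length(query$values) < 3 || length(reference$values) < 3)
    stop("series shorter than 3 points cannot be aligned")
  res <- dtw_core(query$values, reference$values)
  new_warp_alignment(res$path, nq = length(query$values),
                     nr = length(reference$values), distance = res$distance)
}

#' @export
print.warp_alignment <- function(x, ...) {
  cat(sprintf(
    "<warp_alignment> %d pairs (%s), query %d pts [%d..%d], reference %d pts [%d..%d]\n",
    nrow(x$pairs), if (x$truncated) "truncated" else "untruncated",
    x$nq, x$q_keep[1], x$q_keep[2], x$nr, x$r_keep[1], x$r_keep[2]))
  invisible(x)
}

#' Truncate spurious start and end matches of a DTW alignment
#'
#' DTW forces both endpoints to align, so when one series leads or outruns
#' the other the out-of-overlap points pile up on the first or last index of
#' the partner series. Two rules recover the comparable time frames.
#' Head rule: if the first `m` indices of one series all align to the first
#' index of the other, the first `m - 1` of those pairs are dropped (the
#' last is kept). Tail rule: at the first path step touching the last index
#' of either series, all subsequent pairs are dropped. Retained ranges are
#' always contiguous. If fewer than 3 aligned pairs survive the alignment is
#' flagged (`insufficient`), and downstream reports mark the pair non-STP
#' with reason `insufficient_overlap` rather than erroring.
#'
#' @param alignment an untruncated `warp_alignment` from [dtw_align()].
#' @return The truncated `warp_alignment` with updated `q_keep`, `r_keep`
#'   and truncation counts.
#' @export
truncate_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "warp_alignment"))
  if (alignment$truncated)
    return(alignment)
  p <- alignment$pairs
  nq <- alignment$nq
  nr <- alignment$nr
  head_q <- head_r <- 0L

  # Head: run of leading pairs stuck at reference index 1 (query duplicated
  # onto the reference start) or, symmetrically, at query index 1. Only one
  # run can exceed length 1 on a valid path.
  run_r1 <- match(FALSE, p[, 2] == 1L, nomatch = nrow(p) + 1L) - 1L
  run_q1 <- match(FALSE, p[, 1] == 1L, nomatch = nrow(p) + 1L) - 1L
  if (run_r1 >= 2L) {
    p <- p[-seq_len(run_r1 - 1L), , drop = FALSE]
    head_q <- run_r1 - 1L
  } else if (run_q1 >= 2L) {
    p <- p[-seq_len(run_q1 - 1L), , drop = FALSE]
    head_r <- run_q1 - 1L
  }

  # Tail: keep up to (and including) the first pair touching either last
  # index.
  k <- which(p[, 1] == nq | p[, 2] == nr)[1]
  tail_q <- nq - p[k, 1]
  tail_r <- nr - p[k, 2]
  p <- p[seq_len(k), , drop = FALSE]

  new_warp_alignment(p, nq = nq, nr = nr, distance = alignment$distance,
                     truncated = TRUE,
                     truncated_head_q = head_q, truncated_head_r = head_r,
                     truncated_tail_q = as.integer(tail_q),
                     truncated_tail_r = as.integer(tail_r))
}

#' Percentage of alignment for one series
#'
#' The retained aligned time interval divided by the series' total time
#' interval — a ratio of time spans, not of index counts, so it is
#' meaningful for non-uniform sampling.
#'
#' @param alignment truncated `warp_alignment`.
#' @param series the [time_series()] named by `which`.
#' @param which `"query"` or `"reference"`.
#' @return Fraction in `[0, 1]`.
#' @export
pct_alignment <- function(alignment, series, which = c("query", "reference")) {
  stopifnot(inherits(alignment, "warp_alignment"), inherits(series, "time_series"))
  which <- match.arg(which)
  if (!alignment$truncated)
    stop("truncate the alignment before computing percentage of alignment")
  keep <- if (which == "query") alignment$q_keep else alignment$r_keep
  t <- series$times
  (t[keep[2]] - t[keep[1]]) / (t[length(t)] - t[1])
}

#' Spearman correlation of aligned expression values
#'
#' Each retained path pair contributes one (query value, reference value)
#' observation. Returns `NA` when either aligned value vector has zero
#' variance (the pair is then reported non-STP with reason
#' `zero_variance`).
#'
#' @param alignment truncated `warp_alignment`.
#' @param query,reference the aligned [time_series()] pair.
#' @return Spearman's rho in `[-1, 1]`, or `NA`.
#' @export
aligned_rho <- function(alignment, query, reference) {
  stopifnot(inherits(alignment, "warp_alignment"))
  if (!alignment$truncated)
    stop("truncate the alignment before computing aligned correlation")
  p <- alignment$pairs
  if (nrow(p) < 3)
    return(NA_real_)
  x <- query$values[p[, 1]]
  y <- reference$values[p[, 2]]
  if (sd(x) == 0 || sd(y) == 0)
    return(NA_real_)
  cor(x, y, method = "spearman")
}

# Observed rho for a pair: align, truncate, correlate. NA when the
# truncated overlap is too small or degenerate.
rho_pipeline <- function(query, reference) {
  al <- truncate_alignment(dtw_align(query, reference))
  if (al$insufficient)
    return(NA_real_)
  aligned_rho(al, query, reference)
}

#' Shuffle-based p-value for an aligned correlation
#'
#' Permutes the expression values of query and reference independently
#' (sampling times stay fixed), re-runs the full align/truncate/correlate
#' pipeline for each shuffle, and fits a Gaussian to the null rhos. The
#' p-value is the upper-tail probability `P(N(mu, sigma^2) >= rho)`:
#' a genuinely similar pair should correlate higher than its shuffled
#' versions. Shuffles whose truncated overlap is degenerate are dropped
#' from the null fit.
#'
#' @param query,reference [time_series()] pair.
#' @param n_shuffles number of permutations (default 100).
#' @param seed integer seed; derive one per gene with [stream_seed()] so
#'   results do not depend on processing order.
#' @param rho_observed optionally the precomputed observed rho.
#' @return List with `p_value`, `mu_null`, `sigma_null`, `rho_observed`
#'   and `n_valid` (shuffles entering the fit).
#' @export
shuffle_pvalue <- function(query, reference, n_shuffles = 100, seed = 1L,
                           rho_observed = NULL) {
  stopifnot(inherits(query, "time_series"), inherits(reference, "time_series"))
  if (is.null(rho_observed))
    rho_observed <- rho_pipeline(query, reference)
  if (is.na(rho_observed))
    return(list(p_value = NA_real_, mu_null = NA_real_, sigma_null = NA_real_,
                rho_observed = NA_real_, n_valid = 0L))
  set.seed(seed)
  null_rho <- vapply(seq_len(n_shuffles), function(i) {
    qs <- time_series(query$times, sample(query$values), query$label)
    rs <- time_series(reference$times, sample(reference$values),
                      reference$label)
    rho_pipeline(qs, rs)
  }, numeric(1))
  null_rho <- null_rho[!is.na(null_rho)]
  if (length(null_rho) < 2)
    return(list(p_value = NA_real_, mu_null = NA_real_, sigma_null = NA_real_,
                rho_observed = rho_observed, n_valid = length(null_rho)))
  mu <- mean(null_rho)
  sigma <- sd(null_rho)
  if (sigma == 0) {
    warning("degenerate shuffle null (sigma = 0)")
    p <- if (rho_observed > mu) 0 else if (rho_observed < mu) 1 else 0.5
  } else {
    p <- pnorm(rho_observed, mean = mu, sd = sigma, lower.tail = FALSE)
  }
  list(p_value = p, mu_null = mu, sigma_null = sigma,
       rho_observed = rho_observed, n_valid = length(null_rho))
}

#' Thresholds defining a similar temporal pattern (STP) pair
#'
#' A pair is STP when (a) at least one series has percentage of alignment
#' above `pct_high`, (b) neither series falls below `pct_low`, (c) the
#' aligned Spearman rho exceeds `rho_min`, and (d) the shuffle p-value is
#' below `p_max`.
#'
#' @param pct_high upper percentage-of-alignment threshold (default 0.80).
#' @param pct_low lower percentage-of-alignment threshold (default 0.50).
#' @param rho_min minimum aligned Spearman correlation (default 0.90).
#' @param p_max maximum shuffle p-value (default 0.05).
#' @return A named list of class `stp_thresholds`.
#' @export
stp_thresholds <- function(pct_high = 0.80, pct_low = 0.50,
                           rho_min = 0.90, p_max = 0.05) {
  stopifnot(pct_low >= 0, pct_low <= pct_high, pct_high <= 1,
            rho_min >= -1, rho_min <= 1, p_max > 0, p_max <= 1)
  structure(list(pct_high = pct_high, pct_low = pct_low,
                 rho_min = rho_min, p_max = p_max),
            class = "stp_thresholds")
}

#' Classify a similarity report as STP or not
#'
#' @param report list (or `similarity_report`) with `pct_query`,
#'   `pct_reference`, `rho` and `p_value`; `NA` metrics yield their own
#'   reason codes.
#' @param thresholds an [stp_thresholds()] object.
#' @return List with `is_stp` (logical) and `reason_code` (`"ok"` for STP,
#'   otherwise a comma-separated list of failed rules or a degeneracy
#'   code).
#' @export
classify_stp <- function(report, thresholds = stp_thresholds()) {
  stopifnot(inherits(thresholds, "stp_thresholds"))
  if (isTRUE(report$insufficient))
    return(list(is_stp = FALSE, reason_code = "insufficient_overlap"))
  if (is.na(report$rho))
    return(list(is_stp = FALSE, reason_code = "zero_variance"))
  failed <- character()
  if (max(report$pct_query, report$pct_reference) <= thresholds$pct_high)
    failed <- c(failed, "pct_high")
  if (min(report$pct_query, report$pct_reference) < thresholds$pct_low)
    failed <- c(failed, "pct_low")
  if (report$rho <= thresholds$rho_min)
    failed <- c(failed, "rho")
  if (is.na(report$p_value) || report$p_value >= thresholds$p_max)
    failed <- c(failed, "p_value")
  if (length(failed) == 0)
    list(is_stp = TRUE, reason_code = "ok")
  else
    list(is_stp = FALSE, reason_code = paste(failed, collapse = ","))
}

#' Assess temporal similarity of a query/reference pair
#'
#' Runs the full similarity pipeline — DTW alignment, truncation, the four
#' metrics (percentage of alignment for query and reference, aligned
#' Spearman rho, shuffle p-value) — and classifies the pair.
#'
#' @inheritParams shuffle_pvalue
#' @param thresholds an [stp_thresholds()] object.
#' @return A `similarity_report`: the four metrics, the Gaussian null
#'   parameters, `is_stp`, `reason_code`, and the truncated `alignment`.
#' @export
#' @examples
#' ref <- time_series(0:20 * 5, plogis((0:20 * 5 - 50) / 10))
#' qry <- time_series(0:20 * 5, plogis((0:20 * 5 - 55) / 10))
#' assess_similarity(qry, ref, n_shuffles = 25, seed = 1)
assess_similarity <- function(query, reference,
                              thresholds = stp_thresholds(),
                              n_shuffles = 100, seed = 1L) {
  al <- truncate_alignment(dtw_align(query, reference))
  report <- list(
    label = query$label,
    pct_query = NA_real_, pct_reference = NA_real_,
    rho = NA_real_, p_value = NA_real_,
    mu_null = NA_real_, sigma_null = NA_real_,
    insufficient = al$insufficient, alignment = al
  )
  if (!al$insufficient) {
    report$pct_query <- pct_alignment(al, query, "query")
    report$pct_reference <- pct_alignment(al, reference, "reference")
    report$rho <- aligned_rho(al, query, reference)
    if (!is.na(report$rho)) {
      sh <- shuffle_pvalue(query, reference, n_shuffles = n_shuffles,
                           seed = seed, rho_observed = report$rho)
      report$p_value <- sh$p_value
      report$mu_null <- sh$mu_null
      report$sigma_null <- sh$sigma_null
    }
  }
  cls <- classify_stp(report, thresholds)
  report$is_stp <- cls$is_stp
  report$reason_code <- cls$reason_code
  structure(report, class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report>%s pct(q) = %.3f pct(r) = %.3f rho = %.3f p = %.3g -> %s (%s)\n",
    if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
    x$pct_query, x$pct_reference, x$rho, x$p_value,
    if (isTRUE(x$is_stp)) "STP" else "not STP", x$reason_code))
  invisible(x)
}
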