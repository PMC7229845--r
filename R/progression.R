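# Warp-function construction, piecewise regression and progression scores.

#' Build the query-time to mean-reference-time warp function
#'
#' For each query time point retained by the truncated alignment, the
#' aligned reference times are grouped and averaged, giving the empirical
#' warp between the two time axes.
#'
#' @param alignment truncated `warp_alignment` with at least 3 retained
#'   query times.
#' @param query,reference the aligned [time_series()] pair.
#' @return A `warp_function` with strictly increasing `q_times` and
#'   non-decreasing `r_mean_times`.
#' @export
build_warp_function <- function(alignment, query, reference) {
  stopifnot(inherits(alignment, "warp_alignment"))
  if (!alignment$truncated)
    stop("truncate the alignment before building the warp function")
  p <- alignment$pairs
  if (length(unique(p[, 1])) < 3)
    stop("need at least 3 retained query times")
  rt <- reference$times[p[, 2]]
  grouped <- tapply(rt, p[, 1], mean)
  idx <- as.integer(names(grouped))
  warp_function(query$times[idx], as.numeric(grouped))
}

#' Warp function container
#'
#' @param q_times strictly increasing retained query times.
#' @param r_mean_times per query time, the mean (or, for condition-level
#'   warps, median) aligned reference time; non-decreasing.
#' @return An object of class `warp_function`.
#' @export
warp_function <- function(q_times, r_mean_times) {
  q_times <- as.numeric(q_times)
  r_mean_times <- as.numeric(r_mean_times)
  if (length(q_times) != length(r_mean_times))
    stop("q_times and r_mean_times must have the same length")
  if (any(diff(q_times) <= 0))
    stop("q_times must be strictly increasing")
  if (any(diff(r_mean_times) < -1e-9))
    stop("r_mean_times must be non-decreasing (monotone warp)")
  structure(list(q_times = q_times, r_mean_times = r_mean_times),
            class = "warp_function")
}

# Least-squares line through points (x, y); closed form, RSS included.
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss, n = n)
}

# All-pairs segment RSS: rss[i, j] is the OLS residual sum of squares of a
# line through points i..j (j > i). Prefix-sum based, O(n^2).
segment_rss_matrix <- function(x, y) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  at <- function(c, i) if (i >= 1) c[i] else 0
  rss <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    len <- j - i + 1
    sx <- cx[j] - at(cx, i - 1)
    sy <- cy[j] - at(cy, i - 1)
    sxx <- cxx[j] - at(cxx, i - 1) - sx^2 / len
    sxy <- cxy[j] - at(cxy, i - 1) - sx * sy / len
    syy <- cyy[j] - at(cyy, i - 1) - sy^2 / len
    rss[i, j] <- pmax(syy - sxy^2 / sxx, 0)
  }
  rss
}

# Exact dynamic-programming segmentation: minimum total RSS over all
# partitions of the points into `n_blocks` contiguous blocks of >= 2
# points. Returns the block index ranges and the total RSS.
best_partition <- function(rss, n_blocks) {
  n <- ncol(rss)
  best <- matrix(Inf, n_blocks, n)
  argmin <- matrix(NA_integer_, n_blocks, n)
  best[1, 2:n] <- rss[1, 2:n]
  if (n_blocks > 1) {
    for (k in 2:n_blocks) {
      for (j in (2 * k):n) {
        starts <- (2 * (k - 1) + 1):(j - 1)          # block k start index
        tot <- best[k - 1, starts - 1] + rss[starts, j]
        w <- which.min(tot)
        best[k, j] <- tot[w]
        argmin[k, j] <- starts[w]
      }
    }
  }
  # backtrack
  blocks <- vector("list", n_blocks)
  j <- n
  for (k in n_blocks:1) {
    i <- if (k == 1) 1L else argmin[k, j]
    blocks[[k]] <- c(i, j)
    j <- i - 1L
  }
  list(blocks = blocks, rss = best[n_blocks, n])
}

segments_from_blocks <- function(x, y, blocks) {
  segs <- lapply(blocks, function(b) {
    fit <- ols_line(x[b[1]:b[2]], y[b[1]:b[2]])
    data.frame(slope = fit$slope, intercept = fit$intercept,
               q_start = x[b[1]], q_end = x[b[2]], n_points = fit$n,
               rss = fit$rss)
  })
  do.call(rbind, segs)
}

# Segment span boundaries used for prediction and area integration:
# contiguous cover of [min(x), max(x)] with interior boundaries at the
# midpoint between the last point of one block and the first of the next.
block_boundaries <- function(x, blocks) {
  n_blocks <- length(blocks)
  b <- numeric(n_blocks + 1)
  b[1] <- x[blocks[[1]][1]]
  b[n_blocks + 1] <- x[blocks[[n_blocks]][2]]
  if (n_blocks > 1) {
    for (k in seq_len(n_blocks - 1))
      b[k + 1] <- (x[blocks[[k]][2]] + x[blocks[[k + 1]][1]]) / 2
  }
  b
}

interior_boundaries <- function(b) {
  if (length(b) > 2) b[-c(1, length(b))] else numeric(0)
}

#' Fit a piecewise linear model to a warp function
#'
#' For each candidate number of breakpoints `K = 0..max_breaks` the
#' least-squares optimal placement is found exactly by dynamic programming
#' over the observed query times (each segment spans >= 2 points; segments
#' are independent regressions, not continuity-constrained). The model
#' minimising `BIC = n log(RSS / n) + p log(n)` with
#' `p = 2 (K + 1) + K` parameters is returned. The RSS entering the BIC is
#' floored at 1e-10 so that on noiseless (exactly collinear) input the
#' penalty term decides and the simplest adequate model wins.
#'
#' @param warp a [warp_function()].
#' @param max_breaks maximum number of interior breakpoints (default 10);
#'   capped so every segment keeps >= 2 points.
#' @return A `segmented_warp`: per-segment slopes/intercepts/spans,
#'   breakpoints, block index ranges, total RSS and the selected BIC.
#' @export
fit_segments <- function(warp, max_breaks = 10) {
  stopifnot(inherits(warp, "warp_function"))
  x <- warp$q_times
  y <- warp$r_mean_times
  n <- length(x)
  if (n < 4)
    max_breaks <- 0
  max_blocks <- max(1L, min(as.integer(max_breaks) + 1L, n %/% 2L))
  rss_mat <- segment_rss_matrix(x, y)
  rss_floor <- 1e-10
  fits <- vector("list", max_blocks)
  bic <- numeric(max_blocks)
  for (k in seq_len(max_blocks)) {
    fits[[k]] <- best_partition(rss_mat, k)
    n_par <- 2 * k + (k - 1)
    bic[k] <- n * log(max(fits[[k]]$rss, rss_floor) / n) + n_par * log(n)
  }
  k_best <- which.min(bic)
  blocks <- fits[[k_best]]$blocks
  segs <- segments_from_blocks(x, y, blocks)
  structure(list(
    x = x, y = y, blocks = blocks, segments = segs,
    boundaries = block_boundaries(x, blocks),
    breakpoints = interior_boundaries(block_boundaries(x, blocks)),
    rss = sum(segs$rss), bic = bic[k_best], bic_by_k = bic
  ), class = "segmented_warp")
}

#' @export
print.segmented_warp <- function(x, ...) {
  cat(sprintf("<segmented_warp> %d segment(s) over [%g, %g]\n",
              nrow(x$segments), x$boundaries[1],
              x$boundaries[length(x$boundaries)]))
  print(x$segments[, c("slope", "intercept", "q_start", "q_end", "n_points")],
        row.names = FALSE)
  invisible(x)
}

#' Merge adjacent segments with near-identical slopes
#'
#' Repeatedly merges the adjacent pair with the smallest absolute slope
#' difference while that difference is below `delta_slope`, refitting a
#' single regression on the combined points and recomputing the slope,
#' until no adjacent pair qualifies.
#'
#' @param fit a `segmented_warp` from [fit_segments()].
#' @param delta_slope slope-difference threshold below which neighbours are
#'   merged (default 0.1).
#' @return The merged `segmented_warp`.
#' @export
merge_segments <- function(fit, delta_slope = 0.1) {
  stopifnot(inherits(fit, "segmented_warp"))
  blocks <- fit$blocks
  segs <- fit$segments
  while (nrow(segs) > 1) {
    d <- abs(diff(segs$slope))
    m <- which.min(d)
    if (d[m] >= delta_slope)
      break
    blocks[[m]] <- c(blocks[[m]][1], blocks[[m + 1]][2])
    blocks[[m + 1]] <- NULL
    segs <- segments_from_blocks(fit$x, fit$y, blocks)
  }
  structure(list(
    x = fit$x, y = fit$y, blocks = blocks, segments = segs,
    boundaries = block_boundaries(fit$x, blocks),
    breakpoints = interior_boundaries(block_boundaries(fit$x, blocks)),
    rss = sum(segs$rss), bic = NA_real_, bic_by_k = fit$bic_by_k
  ), class = "segmented_warp")
}

#' Evaluate a fitted segmented warp at new query times
#'
#' @param object a `segmented_warp`.
#' @param q_new numeric query times (clamped to the fitted span).
#' @param ... unused.
#' @return Fitted mean reference times.
#' @export
predict.segmented_warp <- function(object, q_new, ...) {
  b <- object$boundaries
  q <- pmin(pmax(q_new, b[1]), b[length(b)])
  k <- findInterval(q, b, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), nrow(object$segments))
  object$segments$intercept[k] + object$segments$slope[k] * q
}

#' Progression Advance Score (PAS)
#'
#' The signed area between the fitted warp function and the diagonal,
#' normalised by the aligned query time span:
#' `PAS = sum_segments integral (fitted reference time - query time) dq /
#' (q_max - q_min)`. Positive PAS means the query is temporally advanced (a
#' given query time maps to a later reference time); negative PAS means the
#' query lags. A query delayed by a pure shift of `D` time units yields
#' `PAS = -D`.
#'
#' @param fit a (typically merged) `segmented_warp`.
#' @return PAS in the time units of the series.
#' @export
compute_pas <- function(fit) {
  stopifnot(inherits(fit, "segmented_warp"))
  b <- fit$boundaries
  span <- b[length(b)] - b[1]
  if (span <= 0)
    stop("aligned query span is zero; PAS undefined")
  segs <- fit$segments
  area <- 0
  for (k in seq_len(nrow(segs))) {
    lo <- b[k]; hi <- b[k + 1]
    area <- area + segs$intercept[k] * (hi - lo) +
      (segs$slope[k] - 1) * (hi^2 - lo^2) / 2
  }
  area / span
}

#' Condition-level progression score (c-PAS)
#'
#' Builds the condition-level warp as, per query time, the median aligned
#' reference time across all STP genes, then applies the same
#' fit/merge/score pipeline. To avoid edge artefacts only query times
#' retained by at least `min_frac` of the STP warps enter the median.
#'
#' @param stp_warps list of [warp_function()] objects (one per STP gene).
#' @param max_breaks,delta_slope passed to [fit_segments()] and
#'   [merge_segments()].
#' @param min_frac minimum fraction of warps that must retain a query time
#'   (default 0.5).
#' @return List with `c_pas`, the condition `warp`, and the merged `fit`.
#' @export
compute_cpas <- function(stp_warps, max_breaks = 10, delta_slope = 0.1,
                         min_frac = 0.5) {
  if (length(stp_warps) == 0)
    stop("no STP warp functions; c-PAS undefined")
  all_times <- sort(unique(unlist(lapply(stp_warps, `[[`, "q_times"))))
  counts <- vapply(all_times, function(t) {
    sum(vapply(stp_warps, function(w) any(w$q_times == t), logical(1)))
  }, numeric(1))
  keep <- all_times[counts >= min_frac * length(stp_warps)]
  if (length(keep) < 3)
    stop("fewer than 3 query times shared by >= ", min_frac * 100,
         "% of STP warps")
  med <- vapply(keep, function(t) {
    median(unlist(lapply(stp_warps, function(w) {
      w$r_mean_times[match(t, w$q_times)]
    })), na.rm = TRUE)
  }, numeric(1))
  warp <- warp_function(keep, cummax(med))
  fit <- merge_segments(fit_segments(warp, max_breaks = max_breaks),
                        delta_slope = delta_slope)
  list(c_pas = compute_pas(fit), warp = warp, fit = fit)
}

#' Adjusted PAS
#'
#' The per-gene progression difference not explained by the overall pace
#' difference between the two conditions: `PAS - c-PAS`.
#'
#' @param pas per-gene PAS.
#' @param c_pas condition-level PAS from [compute_cpas()].
#' @return `pas - c_pas`.
#' @export
adjusted_pas <- function(pas, c_pas) {
  pas - c_pas
}

#' Score differential progression for one aligned pair
#'
#' Convenience wrapper: warp function, BIC-selected piecewise fit, slope
#' merging, PAS.
#'
#' @param alignment truncated `warp_alignment`.
#' @param query,reference the aligned [time_series()] pair.
#' @param max_breaks,delta_slope see [fit_segments()] and
#'   [merge_segments()].
#' @return List with `warp`, merged `fit`, `pas` and `n_segments`.
#' @export
score_progression <- function(alignment, query, reference,
                              max_breaks = 10, delta_slope = 0.1) {
  warp <- build_warp_function(alignment, query, reference)
  fit <- merge_segments(fit_segments(warp, max_breaks = max_breaks),
                        delta_slope = delta_slope)
  list(warp = warp, fit = fit, pas = compute_pas(fit),
       n_segments = nrow(fit$segments))
}
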