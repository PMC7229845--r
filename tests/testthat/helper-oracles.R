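# Independent oracles used to guard the DTW and segmentation solvers.

# Exhaustive enumeration of all admissible warping paths (steps diagonal,
# query-advance, reference-advance) under the same weighting as the solver
# (diagonal 2, others 1; first cell weight 2). Returns the minimum cost and
# every cost-optimal path.
bf_dtw <- function(q, r) {
  n <- length(q)
  m <- length(r)
  best <- Inf
  best_paths <- list()
  rec <- function(i, j, cost, path) {
    if (cost > best + 1e-12) return()
    if (i == n && j == m) {
      if (cost < best - 1e-12) {
        best <<- cost
        best_paths <<- list(path)
      } else {
        best_paths[[length(best_paths) + 1]] <<- path
      }
      return()
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, cost + 2 * abs(q[i + 1] - r[j + 1]),
          rbind(path, c(i + 1, j + 1)))
    if (i < n)
      rec(i + 1, j, cost + abs(q[i + 1] - r[j]), rbind(path, c(i + 1, j)))
    if (j < m)
      rec(i, j + 1, cost + abs(q[i] - r[j + 1]), rbind(path, c(i, j + 1)))
  }
  rec(1, 1, 2 * abs(q[1] - r[1]), matrix(c(1, 1), 1))
  list(cost = best, paths = best_paths)
}

# Brute-force minimum total RSS over all partitions of the points into
# n_blocks contiguous blocks of >= 2 points, each fitted by lm().
bf_seg_rss <- function(x, y, n_blocks) {
  n <- length(x)
  rss_of <- function(idx) sum(resid(lm(y[idx] ~ x[idx]))^2)
  if (n_blocks == 1) return(rss_of(1:n))
  cuts <- combn(2:(n - 1), n_blocks - 1)
  best <- Inf
  for (c in seq_len(ncol(cuts))) {
    starts <- c(1, cuts[, c])
    ends <- c(cuts[, c] - 1, n)
    if (any(ends - starts < 1)) next
    tot <- sum(vapply(seq_along(starts),
                      function(k) rss_of(starts[k]:ends[k]), numeric(1)))
    best <- min(best, tot)
  }
  best
}

# Shorthand for a sigmoid series pair delayed by `shift` days on a daily
# 0..100-day grid (the canonical simulated example).
shift_pair <- function(shift, density = 1, noise = 0, seed = 1) {
  generate_pair(pattern_spec("shift", window = c(0, 100), density = density,
                             shift = shift, noise_level = noise, seed = seed))
}

truncated_alignment <- function(pair) {
  truncate_alignment(dtw_align(pair$query, pair$reference))
}
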