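test_that("warp function averages aligned reference times per query time", {
  # identity alignment: warp is y = x
  s <- time_series(0:9, seq(0, 1, length.out = 10))
  al <- truncate_alignment(dtw_align(s, s))
  w <- build_warp_function(al, s, s)
  expect_equal(w$r_mean_times, w$q_times)

  # 5-day shift: r_mean(t) = t - 5 over the retained span
  p5 <- shift_pair(5)
  al5 <- truncated_alignment(p5)
  w5 <- build_warp_function(al5, p5$query, p5$reference)
  expect_equal(w5$q_times, 5:100)
  expect_equal(w5$r_mean_times, w5$q_times - 5)

  # a query index aligned to reference indices at times 30 and 40 gets 35
  q <- time_series(c(0, 10, 20), c(0, 0.5, 1))
  r <- time_series(c(0, 10, 30, 40), c(0, 0.4, 0.8, 1))
  man <- tempoalign:::new_warp_alignment(
    cbind(c(1, 2, 3, 3), c(1, 2, 3, 4)), 3, 4, truncated = TRUE)
  w2 <- build_warp_function(man, q, r)
  expect_equal(w2$r_mean_times, c(0, 10, 35))
})

test_that("segmented fit recovers exact lines and two-regime warps", {
  # exact line y = x: one segment, slope 1, intercept 0
  w <- warp_function(0:20, 0:20)
  f <- fit_segments(w)
  expect_equal(nrow(f$segments), 1L)
  expect_equal(f$segments$slope, 1)
  expect_equal(f$segments$intercept, 0, tolerance = 1e-10)

  # noiseless two-regime warp (slope 2 to day 50, then slope 1)
  x <- 0:100
  y <- ifelse(x <= 50, 2 * x, x + 50)
  f2 <- fit_segments(warp_function(x, y))
  expect_equal(nrow(f2$segments), 2L)
  expect_equal(f2$segments$slope, c(2, 1), tolerance = 1e-9)
  expect_lt(abs(f2$breakpoints[1] - 50), 1.01)  # within one sampling step

  # all-collinear noisy-free input never splits
  f3 <- fit_segments(warp_function(seq(0, 10, 0.5), 3 + 2 * seq(0, 10, 0.5)))
  expect_equal(nrow(f3$segments), 1L)
})

test_that("dynamic-programming segmentation matches brute-force enumeration", {
  set.seed(7)
  for (trial in 1:30) {
    n <- sample(6:12, 1)
    x <- sort(runif(n, 0, 10))
    y <- 0.5 * x + rnorm(n, sd = 0.5)
    rssm <- tempoalign:::segment_rss_matrix(x, y)
    for (k in 1:3) {
      if (n < 2 * k) next
      dp <- tempoalign:::best_partition(rssm, k)$rss
      expect_equal(dp, bf_seg_rss(x, y, k), tolerance = 1e-6)
    }
  }
})

test_that("near-equal slopes merge by refitting on the combined points", {
  x <- seq(0, 15, by = 0.5)
  y <- ifelse(x <= 5, 2 * x, ifelse(x <= 10, 1.95 * x + 0.25, x + 9.75))
  f <- fit_segments(warp_function(x, y), max_breaks = 5)
  expect_equal(f$segments$slope, c(2, 1.95, 1), tolerance = 1e-9)
  m <- merge_segments(f, delta_slope = 0.1)
  expect_equal(nrow(m$segments), 2L)
  expect_equal(m$segments$slope[1], 1.977, tolerance = 1e-2)
  expect_equal(m$segments$slope[2], 1, tolerance = 1e-9)

  # slope gap of 1 >= deltaSlope: unchanged
  y2 <- ifelse(x <= 7.5, 2 * x, x + 7.5)
  f2 <- fit_segments(warp_function(x, y2))
  expect_equal(merge_segments(f2, 0.1)$segments$slope, f2$segments$slope)

  # single segment: unchanged
  f3 <- fit_segments(warp_function(x, x))
  expect_equal(nrow(merge_segments(f3, 0.1)$segments), 1L)
})

test_that("PAS is the normalised signed area between warp and diagonal", {
  # identity warp
  expect_equal(compute_pas(fit_segments(warp_function(0:50, 0:50))), 0)

  # single segment y = 2x over query span [0, 50]:
  # integral of (2q - q) dq / 50 = 25
  expect_equal(compute_pas(fit_segments(warp_function(0:50, 2 * (0:50)))), 25)

  # query delayed by 5 days: PAS = -5 (query lags), |PAS| = shift
  p5 <- shift_pair(5)
  al <- truncated_alignment(p5)
  pr <- score_progression(al, p5$query, p5$reference)
  expect_equal(pr$pas, -5, tolerance = 1e-9)
  expect_equal(pr$n_segments, 1L)

  # antisymmetry under query/reference swap for a pure shift
  al_sw <- truncate_alignment(dtw_align(p5$reference, p5$query))
  pr_sw <- score_progression(al_sw, p5$reference, p5$query)
  expect_equal(pr_sw$pas, 5, tolerance = 1e-9)
})

test_that("c-PAS summarises the condition-level median warp", {
  mk_shift_warp <- function(d, seed = 5) {
    p <- shift_pair(d, seed = seed)
    al <- truncated_alignment(p)
    build_warp_function(al, p$query, p$reference)
  }
  # identical identity-like warps: c-PAS = 0
  w0 <- lapply(1:3, function(i) mk_shift_warp(0))
  expect_equal(compute_cpas(w0)$c_pas, 0, tolerance = 1e-9)

  # all genes shifted by the same delta: |c-PAS| = delta
  w10 <- lapply(1:3, function(i) mk_shift_warp(10))
  expect_equal(compute_cpas(w10)$c_pas, -10, tolerance = 1e-9)

  # mixed shifts (-2, 0, +2): the median warp is the identity
  wm <- lapply(c(-2, 0, 2), mk_shift_warp)
  expect_equal(compute_cpas(wm)$c_pas, 0, tolerance = 1e-6)

  expect_error(compute_cpas(list()), "STP")
})

test_that("adjusted PAS is PAS minus c-PAS and centres a noisy-shift cohort", {
  expect_equal(adjusted_pas(5, 5), 0)
  expect_equal(adjusted_pas(-13.33, -13.33), 0)
  expect_equal(adjusted_pas(-10, -13), 3)

  # cohort with per-gene shifts 10 + eps, eps zero-median: the adjusted
  # PAS distribution centres at ~0 (within one sampling interval)
  set.seed(42)
  eps <- sample(rep(c(-2, -1, 0, 1, 2), 3))
  warps <- lapply(10 + eps, function(d) {
    p <- shift_pair(d, seed = 5)
    build_warp_function(truncated_alignment(p), p$query, p$reference)
  })
  cp <- compute_cpas(warps)
  pas <- vapply(warps, function(w)
    compute_pas(merge_segments(fit_segments(w), 0.1)), numeric(1))
  expect_lt(abs(median(adjusted_pas(pas, cp$c_pas))), 1)
})
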