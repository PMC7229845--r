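test_that("DTW path is the diagonal for identical series and valid generally", {
  s <- time_series(0:4, c(0, 0.2, 0.5, 0.9, 1))
  al <- dtw_align(s, s)
  expect_equal(al$pairs, cbind(query = 1:5, reference = 1:5))
  expect_equal(al$distance, 0)

  # reversed monotone ramp: the path is still monotone with unit steps and
  # endpoint-pinned, but cost is positive
  ramp <- time_series(0:9, seq(0, 1, length.out = 10))
  rev_ramp <- time_series(0:9, rev(ramp$values))
  al2 <- dtw_align(ramp, rev_ramp)
  expect_true(al2$distance > 0)
  expect_true(all(diff(al2$pairs[, 1]) %in% 0:1))
  expect_true(all(diff(al2$pairs[, 2]) %in% 0:1))
  expect_equal(al2$pairs[1, ], c(query = 1, reference = 1))
  expect_equal(al2$pairs[nrow(al2$pairs), ], c(query = 10, reference = 10))

  expect_error(dtw_align(time_series(0:1, c(0, 1)), ramp), "3 points")
})

test_that("DTW equals exhaustive path enumeration on small instances", {
  # 3x3 toy with a known asymmetry
  q <- c(0, 0.5, 1)
  r <- c(0, 0, 1)
  al <- dtw_align(time_series(0:2, q), time_series(0:2, r))
  o <- bf_dtw(q, r)
  expect_equal(al$distance, o$cost)
  expect_true(any(vapply(o$paths, function(p)
    nrow(p) == nrow(al$pairs) && all(p == al$pairs), logical(1))))

  set.seed(31)
  for (trial in 1:30) {
    nq <- sample(3:6, 1)
    nr <- sample(3:6, 1)
    qv <- round(runif(nq), 2)
    rv <- round(runif(nr), 2)
    al <- dtw_align(time_series(seq_len(nq), qv), time_series(seq_len(nr), rv))
    o <- bf_dtw(qv, rv)
    expect_equal(al$distance, o$cost, tolerance = 1e-12)
    expect_true(any(vapply(o$paths, function(p)
      nrow(p) == nrow(al$pairs) && all(p == al$pairs), logical(1))))
  }
})

test_that("truncation removes the shifted-out head and tail points", {
  # query delayed 5 days on a shared daily 0-100 day window: the first
  # 5 query days and the last 5 reference days fall outside the overlap
  al <- truncated_alignment(shift_pair(5))
  expect_equal(al$truncated_head_q, 5L)
  expect_equal(al$truncated_tail_r, 5L)
  expect_equal(al$q_keep, c(6L, 101L))   # query days 5..100
  expect_equal(al$r_keep, c(1L, 96L))    # reference days 0..95
  expect_true(all(diff(al$pairs[, 1]) %in% 0:1))  # contiguous path retained

  # identical series: truncation removes nothing
  s <- time_series(0:9, seq(0, 1, length.out = 10))
  al2 <- truncate_alignment(dtw_align(s, s))
  expect_equal(nrow(al2$pairs), 10L)
  expect_equal(al2$truncated_head_q + al2$truncated_head_r +
                 al2$truncated_tail_q + al2$truncated_tail_r, 0L)

  # query running 2x faster over the same window: the query plateau half
  # is tail-truncated
  sp <- generate_pair(pattern_spec("speed", speed_factor = 2, seed = 4))
  al3 <- truncated_alignment(sp)
  q_span <- sp$query$times[al3$q_keep]
  expect_lt(abs(q_span[2] - 50), 1.5)
  expect_equal(q_span[1], 0)
})

test_that("percentage of alignment is a time-interval ratio", {
  p5 <- shift_pair(5)
  al <- truncated_alignment(p5)
  expect_equal(pct_alignment(al, p5$query, "query"), 0.95)
  expect_equal(pct_alignment(al, p5$reference, "reference"), 0.95)

  s <- time_series(0:9, seq(0, 1, length.out = 10))
  al2 <- truncate_alignment(dtw_align(s, s))
  expect_equal(pct_alignment(al2, s, "query"), 1.0)

  p30 <- shift_pair(30)
  al3 <- truncated_alignment(p30)
  expect_equal(pct_alignment(al3, p30$query, "query"), 0.70)
  expect_equal(pct_alignment(al3, p30$reference, "reference"), 0.70)
})

test_that("aligned Spearman correlation matches hand-computed ranks", {
  p5 <- shift_pair(5)
  al <- truncated_alignment(p5)
  expect_equal(aligned_rho(al, p5$query, p5$reference), 1)

  # identity alignment of a ramp
  s <- time_series(0:9, seq(0, 1, length.out = 10))
  al2 <- truncate_alignment(dtw_align(s, s))
  expect_equal(aligned_rho(al2, s, s), 1)

  # length-5 pair with ranks (1,3,2,4,5) vs (1,2,3,4,5):
  # rho = 1 - 6 * 2 / (5 * 24) = 0.9
  q <- time_series(1:5, c(0.1, 0.4, 0.2, 0.8, 0.9))
  r <- time_series(1:5, c(0.2, 0.3, 0.5, 0.7, 1.0))
  ident <- tempoalign:::new_warp_alignment(cbind(1:5, 1:5), 5, 5,
                                           truncated = TRUE)
  expect_equal(aligned_rho(ident, q, r), 0.9)

  # zero variance in one aligned vector is NA, not an error
  flat <- time_series(1:5, rep(0.5, 5))
  expect_true(is.na(aligned_rho(ident, q, flat)))
})

test_that("shuffle p-value is deterministic, small for true shifts, and
           calibrated on exchangeable data", {
  p5 <- shift_pair(5)
  a <- shuffle_pvalue(p5$query, p5$reference, n_shuffles = 50, seed = 9)
  b <- shuffle_pvalue(p5$query, p5$reference, n_shuffles = 50, seed = 9)
  expect_identical(a, b)
  expect_lt(a$p_value, 1e-6)  # noiseless dense shift
  expect_equal(a$rho_observed, 1)

  # white-noise pairs: shuffling preserves the null distribution, so the
  # rejection rate at 0.05 stays inside the binomial 95% interval
  set.seed(123)
  ps <- vapply(1:100, function(i) {
    q <- time_series(1:20, runif(20))
    r <- time_series(1:20, runif(20))
    shuffle_pvalue(q, r, n_shuffles = 50, seed = sample.int(1e6, 1))$p_value
  }, numeric(1))
  rejections <- sum(ps < 0.05, na.rm = TRUE)
  expect_lte(rejections, qbinom(0.975, 100, 0.05))
})

test_that("STP classification applies the four joint thresholds", {
  th <- stp_thresholds()
  mk <- function(pq, pr, rho, p)
    list(pct_query = pq, pct_reference = pr, rho = rho, p_value = p,
         insufficient = FALSE)
  expect_true(classify_stp(mk(0.95, 0.95, 1.0, 1e-10), th)$is_stp)
  r1 <- classify_stp(mk(0.95, 0.49, 1.0, 1e-10), th)
  expect_false(r1$is_stp)
  expect_match(r1$reason_code, "pct_low")
  r2 <- classify_stp(mk(0.95, 0.95, 0.89, 1e-10), th)
  expect_false(r2$is_stp)
  expect_equal(r2$reason_code, "rho")
  r3 <- classify_stp(mk(0.79, 0.79, 0.95, 1e-10), th)
  expect_match(r3$reason_code, "pct_high")
  r4 <- classify_stp(mk(0.95, 0.95, 0.95, 0.06), th)
  expect_equal(r4$reason_code, "p_value")

  # degenerate truncation is reported, not crashed on
  tiny <- list(insufficient = TRUE)
  expect_equal(classify_stp(tiny, th)$reason_code, "insufficient_overlap")
  # thresholds are configurable
  loose <- stp_thresholds(rho_min = 0.8)
  expect_true(classify_stp(mk(0.95, 0.95, 0.89, 1e-10), loose)$is_stp)
})

test_that("assess_similarity reproduces the joint report for a shift pair", {
  p5 <- shift_pair(5)
  rep <- assess_similarity(p5$query, p5$reference, n_shuffles = 50, seed = 2)
  expect_true(rep$is_stp)
  expect_equal(rep$reason_code, "ok")
  expect_equal(rep$pct_query, 0.95)
  expect_equal(rep$pct_reference, 0.95)
  expect_equal(rep$rho, 1)
  expect_lt(rep$p_value, 1e-6)
  expect_true(rep$alignment$truncated)
})
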