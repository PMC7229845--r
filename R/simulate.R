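# Synthetic query/reference pair generator with known ground-truth warps.

base_curve_registry <- list(
  # Smooth monotone sigmoid rising across the window; defined on all of
  # time so shifted/warped evaluation points outside the window are valid.
  sigmoid = function(t, window) {
    stats::plogis((t - mean(window)) / (diff(window) / 10))
  },
  gompertz = function(t, window) {
    exp(-exp(-(t - mean(window)) / (diff(window) / 10)))
  },
  ramp = function(t, window) {
    pmin(pmax((t - window[1]) / diff(window), 0), 1)
  }
)

#' Specification of a simulated query/reference pair
#'
#' Describes one of four ground-truth temporal relationships between a
#' query and a reference trajectory sampled on a shared observation
#' window:
#' \describe{
#'   \item{shift}{the query is the reference delayed by `shift` time
#'     units: `q(t) = base(t - shift)`.}
#'   \item{speed}{the query progresses `speed_factor`-fold faster:
#'     `q(t) = base(t0 + k (t - t0))`.}
#'   \item{mixed}{piecewise speed regimes, e.g. 2-fold faster for the
#'     first 50 days then equal speed; `regimes` is a list of
#'     `c(span, factor)` pairs covering the query window. The reference is
#'     sampled on the warped image of the query window so every regime is
#'     observable.}
#'   \item{dissimilar}{both series are independent smoothed-Gaussian
#'     draws (kernel bandwidth 10% of the window), a calibration null for
#'     the shuffle p-value.}
#' }
#' Gaussian noise `K * N(0, 1)` is added independently to query and
#' reference values.
#'
#' @param kind one of `"shift"`, `"speed"`, `"mixed"`, `"dissimilar"`.
#' @param window numeric `c(t_start, t_end)` observation window for the
#'   query (and, except for `mixed`, the reference).
#' @param density samples per time unit (> 0); daily sampling on a day
#'   axis is `density = 1`.
#' @param shift delay of the query in time units (`shift` kind).
#' @param speed_factor fold-speed of the query (`speed` kind).
#' @param regimes list of `c(span, factor)` for the `mixed` kind; spans
#'   must sum to the window length.
#' @param noise_level noise multiplier `K >= 0` on the unit-amplitude
#'   curves.
#' @param seed integer seed making [generate_pair()] reproducible.
#' @param base_curve name in `"sigmoid"`, `"gompertz"`, `"ramp"`, or a
#'   `function(t, window)` template.
#' @return An object of class `pattern_spec`.
#' @export
#' @examples
#' pattern_spec("shift", shift = 5)
#' pattern_spec("mixed", regimes = list(c(50, 2), c(50, 1)))
pattern_spec <- function(kind = c("shift", "speed", "mixed", "dissimilar"),
                         window = c(0, 100), density = 1,
                         shift = 0, speed_factor = 1, regimes = NULL,
                         noise_level = 0, seed = 1L,
                         base_curve = "sigmoid") {
  kind <- match.arg(kind)
  stopifnot(length(window) == 2, window[2] > window[1], density > 0,
            noise_level >= 0)
  if (kind == "mixed") {
    if (is.null(regimes))
      stop("mixed kind requires regimes = list(c(span, factor), ...)")
    spans <- vapply(regimes, `[`, numeric(1), 1)
    if (abs(sum(spans) - diff(window)) > 1e-9)
      stop("regime spans must cover the window exactly (sum to ",
           diff(window), ")")
  }
  if (is.character(base_curve)) {
    if (!base_curve %in% names(base_curve_registry))
      stop("unknown base curve: ", base_curve)
  } else if (!is.function(base_curve)) {
    stop("base_curve must be a template name or a function(t, window)")
  }
  structure(list(kind = kind, window = window, density = density,
                 shift = shift, speed_factor = speed_factor,
                 regimes = regimes, noise_level = noise_level,
                 seed = as.integer(seed), base_curve = base_curve),
            class = "pattern_spec")
}

# Ground-truth warp: the reference time w(t) whose value the query shows
# at query time t.
true_warp <- function(spec) {
  t0 <- spec$window[1]
  switch(spec$kind,
    shift = function(t) t - spec$shift,
    speed = function(t) t0 + spec$speed_factor * (t - t0),
    mixed = {
      spans <- vapply(spec$regimes, `[`, numeric(1), 1)
      factors <- vapply(spec$regimes, `[`, numeric(1), 2)
      starts <- t0 + cumsum(c(0, spans[-length(spans)]))
      offsets <- t0 + cumsum(c(0, (spans * factors)[-length(spans)]))
      function(t) {
        k <- pmax(findInterval(t, starts), 1L)
        offsets[k] + factors[k] * (t - starts[k])
      }
    },
    dissimilar = NULL
  )
}

smooth_draw <- function(times, window) {
  bw <- 0.1 * diff(window)
  z <- rnorm(length(times))
  w <- exp(-0.5 * (outer(times, times, "-") / bw)^2)
  s <- as.numeric(w %*% z) / rowSums(w)
  (s - min(s)) / (max(s) - min(s))
}

#' Generate a simulated query/reference pair
#'
#' Samples the reference from the base curve on its window and the query
#' from the base curve evaluated at the ground-truth warped time (see
#' [pattern_spec()]), then adds `K * N(0, 1)` noise to both series.
#' Bit-for-bit reproducible given the spec (which includes the seed).
#'
#' @param spec a [pattern_spec()].
#' @return List of class `sim_pair` with `query` and `reference`
#'   [time_series()], the `spec`, and `warp_true` (the ground-truth warp
#'   function of query time, `NULL` for dissimilar pairs).
#' @export
#' @examples
#' p <- generate_pair(pattern_spec("shift", shift = 5, seed = 7))
#' range(p$reference$values)
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  set.seed(spec$seed)
  step <- 1 / spec$density
  tq <- seq(spec$window[1], spec$window[2], by = step)
  base <- if (is.function(spec$base_curve)) spec$base_curve
          else base_curve_registry[[spec$base_curve]]
  w <- true_warp(spec)
  if (spec$kind == "mixed") {
    r_window <- c(spec$window[1], w(spec$window[2]))
  } else {
    r_window <- spec$window
  }
  tr <- seq(r_window[1], r_window[2], by = step)
  if (spec$kind == "dissimilar") {
    qv <- smooth_draw(tq, spec$window)
    rv <- smooth_draw(tr, r_window)
  } else {
    rv <- base(tr, spec$window)
    qv <- base(w(tq), spec$window)
  }
  if (spec$noise_level > 0) {
    qv <- qv + spec$noise_level * rnorm(length(qv))
    rv <- rv + spec$noise_level * rnorm(length(rv))
  }
  structure(list(query = time_series(tq, qv, "query"),
                 reference = time_series(tr, rv, "reference"),
                 spec = spec, warp_true = w),
            class = "sim_pair")
}

#' Power sweep over simulation conditions
#'
#' For each spec in the grid, generates `n_reps` independent pairs (seeds
#' derived from `seed`, the spec index and the repetition) and assesses
#' similarity; reports the fraction of repetitions with `p < alpha`
#' (power) and the median p-value.
#'
#' @param specs list of [pattern_spec()] objects (their `seed` fields are
#'   overridden by derived per-repetition seeds).
#' @param n_reps repetitions per grid cell.
#' @param n_shuffles shuffles per similarity assessment.
#' @param seed master seed.
#' @param alpha rejection threshold on the shuffle p-value.
#' @param thresholds [stp_thresholds()] used for the STP call rate.
#' @return Data frame with one row per spec: the spec descriptors,
#'   `power`, `median_p` and `stp_rate`.
#' @export
sweep_power <- function(specs, n_reps = 50, n_shuffles = 100, seed = 1L,
                        alpha = 0.05, thresholds = stp_thresholds()) {
  rows <- lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    p_vals <- numeric(n_reps)
    stp <- logical(n_reps)
    for (rep in seq_len(n_reps)) {
      key <- paste(si, rep, sep = "/")
      spec_i <- spec
      spec_i$seed <- stream_seed(seed, paste0("sim/", key))
      pair <- generate_pair(spec_i)
      rep_out <- assess_similarity(pair$query, pair$reference,
                                   thresholds = thresholds,
                                   n_shuffles = n_shuffles,
                                   seed = stream_seed(seed, paste0("shuf/", key)))
      p_vals[rep] <- if (is.na(rep_out$p_value)) 1 else rep_out$p_value
      stp[rep] <- isTRUE(rep_out$is_stp)
    }
    data.frame(kind = spec$kind, shift = spec$shift,
               speed_factor = spec$speed_factor,
               noise_level = spec$noise_level, density = spec$density,
               n_reps = n_reps, power = mean(p_vals < alpha),
               median_p = median(p_vals), stp_rate = mean(stp))
  })
  do.call(rbind, rows)
}

#' Assemble simulated pairs into a query/reference matrix pair
#'
#' Stacks the query (resp. reference) series of several simulated pairs
#' sharing a common sampling grid into the two-matrix layout consumed by
#' the pipeline, optionally multiplying by an abundance amplitude so the
#' values resemble expression units rather than unit-scaled curves.
#'
#' @param pairs named list of `sim_pair` objects (names become gene ids);
#'   all query grids must agree, likewise all reference grids.
#' @param amplitude scalar multiplier applied to all values (default 100).
#' @return List with `query` and `reference` [expression_matrix()]
#'   objects.
#' @export
pairs_to_matrices <- function(pairs, amplitude = 100) {
  stopifnot(length(pairs) >= 1, !is.null(names(pairs)),
            all(nzchar(names(pairs))))
  tq <- pairs[[1]]$query$times
  tr <- pairs[[1]]$reference$times
  for (p in pairs) {
    if (!isTRUE(all.equal(p$query$times, tq)) ||
        !isTRUE(all.equal(p$reference$times, tr)))
      stop("all pairs must share the same query and reference grids")
  }
  qv <- do.call(rbind, lapply(pairs, function(p) p$query$values)) * amplitude
  rv <- do.call(rbind, lapply(pairs, function(p) p$reference$values)) * amplitude
  rownames(qv) <- rownames(rv) <- names(pairs)
  list(query = expression_matrix(pmax(qv, 0), tq),
       reference = expression_matrix(pmax(rv, 0), tr))
}
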