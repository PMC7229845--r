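# End-to-end run: preprocessing, per-gene similarity, progression scoring.

serialize_segments <- function(segments) {
  paste(sprintf("%.6g:%.6g:%.6g", segments$slope, segments$q_start,
                segments$q_end), collapse = ";")
}

preprocess_matrix <- function(mat, divisor = 1, normalize = TRUE,
                              fold_threshold = 2) {
  if (divisor != 1)
    mat <- expression_matrix(mat$values / divisor, mat$times)
  n_in <- nrow(mat$values)
  if (normalize)
    mat <- normalize_median_ratio(mat)
  mat <- merge_replicates(mat)
  mat <- log_and_filter(mat, fold_threshold = fold_threshold)
  list(matrix = mat, n_in = n_in, n_filtered = attr(mat, "n_filtered"),
       n_retained = nrow(mat$values))
}

#' Run the full similarity and progression pipeline on two matrices
#'
#' Steps: optional per-matrix scalar rescaling; median-of-ratios
#' normalisation; replicate merging; `log10(x + 1)` with fold-change
#' filtering; joint unit scaling of the shared genes; optional pseudo-time
#' conversion; per-gene DTW alignment, truncation, four similarity metrics
#' and STP classification; for STP genes, warp-function construction,
#' piecewise fitting and PAS; condition-level c-PAS from the median STP
#' warp; adjusted PAS per gene. Gene pairing is by shared identifier.
#' Deterministic given `seed` (per-gene shuffle streams are derived from
#' the seed and the gene id, so results are independent of gene order).
#'
#' @param query,reference [expression_matrix()] objects or file paths
#'   accepted by [read_expression_matrix()].
#' @param query_replicate_map,reference_replicate_map optional replicate
#'   maps (see [read_expression_matrix()]); used only for path inputs.
#' @param query_divisor,reference_divisor scalar divisors applied before
#'   normalisation (for heterogeneous units, e.g. transcripts-per-embryo
#'   vs TPM).
#' @param normalize apply median-of-ratios normalisation (disable for
#'   pre-normalised input).
#' @param fold_threshold temporal fold-change filter (default 2).
#' @param joint_scaling share per-gene min/max across the two series when
#'   unit-scaling (see [scale_pair()]).
#' @param pseudotime replace times by their rank order before alignment
#'   (for unevenly sampled series).
#' @param thresholds [stp_thresholds()].
#' @param n_shuffles shuffles per gene for the p-value.
#' @param max_breaks,delta_slope segmented-regression controls.
#' @param seed master seed.
#' @param verbose log per-stage counts to stderr.
#' @return Object of class `tempoalign_run`: `similarity` (data frame,
#'   one row per shared gene), `progression` (STP genes only, with PAS,
#'   c-PAS, adjusted PAS and the serialized segment table),
#'   `condition_warp` (data frame), `c_pas`, and `manifest` (config,
#'   seed, version, per-stage counts).
#' @export
run_pipeline <- function(query, reference,
                         query_replicate_map = NULL,
                         reference_replicate_map = NULL,
                         query_divisor = 1, reference_divisor = 1,
                         normalize = TRUE, fold_threshold = 2,
                         joint_scaling = TRUE, pseudotime = FALSE,
                         thresholds = stp_thresholds(),
                         n_shuffles = 100, max_breaks = 10,
                         delta_slope = 0.1, seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(query))
    query <- read_expression_matrix(query, query_replicate_map)
  if (is.character(reference))
    reference <- read_expression_matrix(reference, reference_replicate_map)
  stopifnot(inherits(query, "expr_matrix"), inherits(reference, "expr_matrix"))

  pq <- preprocess_matrix(query, query_divisor, normalize, fold_threshold)
  pr <- preprocess_matrix(reference, reference_divisor, normalize,
                          fold_threshold)
  say("query: %d genes in, %d filtered, %d retained",
      pq$n_in, pq$n_filtered, pq$n_retained)
  say("reference: %d genes in, %d filtered, %d retained",
      pr$n_in, pr$n_filtered, pr$n_retained)

  shared <- intersect(rownames(pq$matrix$values), rownames(pr$matrix$values))
  if (length(shared) == 0)
    stop("no shared gene ids between query and reference after filtering")
  say("%d shared genes", length(shared))

  qm <- expression_matrix(pq$matrix$values[shared, , drop = FALSE],
                          pq$matrix$times)
  rm_ <- expression_matrix(pr$matrix$values[shared, , drop = FALSE],
                           pr$matrix$times)
  scaled <- scale_pair(qm, rm_, joint = joint_scaling)
  qm <- scaled$query
  rm_ <- scaled$reference
  if (pseudotime) {
    qm <- to_pseudotime(qm)
    rm_ <- to_pseudotime(rm_)
  }

  reports <- lapply(shared, function(g) {
    assess_similarity(gene_series(qm, g), gene_series(rm_, g),
                      thresholds = thresholds, n_shuffles = n_shuffles,
                      seed = stream_seed(seed, g))
  })
  names(reports) <- shared
  similarity <- do.call(rbind, lapply(shared, function(g) {
    r <- reports[[g]]
    data.frame(gene_id = g, pct_query = r$pct_query,
               pct_reference = r$pct_reference, rho = r$rho,
               p_value = r$p_value, mu_null = r$mu_null,
               sigma_null = r$sigma_null, is_stp = r$is_stp,
               reason_code = r$reason_code, stringsAsFactors = FALSE)
  }))
  stp_genes <- shared[vapply(reports, function(r) isTRUE(r$is_stp),
                             logical(1))]
  say("%d STP genes", length(stp_genes))

  progression <- data.frame(gene_id = character(0), pas = numeric(0),
                            c_pas = numeric(0), adjusted_pas = numeric(0),
                            n_segments = integer(0),
                            segments = character(0),
                            stringsAsFactors = FALSE)
  condition_warp <- NULL
  c_pas <- NA_real_
  if (length(stp_genes) > 0) {
    warps <- lapply(stp_genes, function(g) {
      build_warp_function(reports[[g]]$alignment, gene_series(qm, g),
                          gene_series(rm_, g))
    })
    names(warps) <- stp_genes
    cp <- tryCatch(
      compute_cpas(warps, max_breaks = max_breaks,
                   delta_slope = delta_slope),
      error = function(e) NULL)
    if (!is.null(cp)) {
      c_pas <- cp$c_pas
      condition_warp <- data.frame(q_time = cp$warp$q_times,
                                   r_median_time = cp$warp$r_mean_times)
    }
    progression <- do.call(rbind, lapply(stp_genes, function(g) {
      fit <- merge_segments(fit_segments(warps[[g]],
                                         max_breaks = max_breaks),
                            delta_slope = delta_slope)
      pas <- compute_pas(fit)
      data.frame(gene_id = g, pas = pas, c_pas = c_pas,
                 adjusted_pas = adjusted_pas(pas, c_pas),
                 n_segments = nrow(fit$segments),
                 segments = serialize_segments(fit$segments),
                 stringsAsFactors = FALSE)
    }))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tempoalign")),
    seed = seed, n_shuffles = n_shuffles, fold_threshold = fold_threshold,
    normalize = normalize, joint_scaling = joint_scaling,
    pseudotime = pseudotime, pct_high = thresholds$pct_high,
    pct_low = thresholds$pct_low, rho_min = thresholds$rho_min,
    p_max = thresholds$p_max, max_breaks = max_breaks,
    delta_slope = delta_slope,
    pas_sign_convention = "positive = query advanced",
    query_genes_in = pq$n_in, query_genes_filtered = pq$n_filtered,
    query_genes_retained = pq$n_retained,
    reference_genes_in = pr$n_in, reference_genes_filtered = pr$n_filtered,
    reference_genes_retained = pr$n_retained,
    shared_genes = length(shared), stp_genes = length(stp_genes)
  )
  structure(list(similarity = similarity, progression = progression,
                 condition_warp = condition_warp, c_pas = c_pas,
                 reports = reports, manifest = manifest),
            class = "tempoalign_run")
}

#' @export
print.tempoalign_run <- function(x, ...) {
  cat(sprintf(
    "<tempoalign_run> %d shared genes, %d STP, c-PAS = %s\n",
    x$manifest$shared_genes, x$manifest$stp_genes,
    if (is.na(x$c_pas)) "NA" else sprintf("%.3f", x$c_pas)))
  invisible(x)
}
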