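#' Expression time-course matrix
#'
#' Lightweight container for a genes-by-time expression grid. Column times
#' are numeric and non-decreasing; duplicated times denote replicate columns
#' (collapse them with [merge_replicates()] before alignment, after which
#' times are strictly increasing).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param times numeric vector of sampling times, one per column, in
#'   arbitrary units (hours, days, stages); must be non-decreasing.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the rownames of `values`.
#' @return An object of class `expr_matrix` with elements `values`
#'   (rownames set to `gene_ids`) and `times`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3), times = c(0, 1, 2))
expression_matrix <- function(values, times, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  if (is.null(gene_ids))
    gene_ids <- paste0("gene", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (anyDuplicated(gene_ids))
    stop("gene ids must be unique")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (is.unsorted(times))
    stop("times must be non-decreasing (sort columns by time)")
  rownames(values) <- gene_ids
  colnames(values) <- NULL
  structure(list(values = values, times = times), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, times %s..%s\n",
              nrow(x$values), ncol(x$values),
              format(x$times[1]), format(x$times[length(x$times)])))
  invisible(x)
}

#' Median-of-ratios normalisation
#'
#' Standard size-factor normalisation: for each gene expressed (> 0) in
#' every sample, compute the ratio of each sample's value to the gene's
#' geometric mean across samples; a sample's size factor is the median of
#' those ratios, and its column is divided by it. Genes with a zero in any
#' sample do not contribute to size-factor estimation but are retained (and
#' rescaled) in the output.
#'
#' @param matrix an [expression_matrix()] of non-negative abundances
#'   (e.g. TPM), at least two samples.
#' @return The normalised `expr_matrix`, with the per-sample size factors
#'   in `attr(, "size_factors")`.
#' @export
#' @examples
#' m <- expression_matrix(cbind(a = c(2, 4, 8), b = c(4, 8, 16)), c(0, 1))
#' attr(normalize_median_ratio(m), "size_factors")  # 1/sqrt(2), sqrt(2)
normalize_median_ratio <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (ncol(v) < 2)
    stop("normalisation needs at least 2 samples")
  if (any(v < 0))
    stop("expression values must be non-negative before normalisation")
  all_pos <- rowSums(v > 0) == ncol(v)
  if (!any(all_pos))
    stop("no gene is expressed (> 0) in every sample; ",
         "size factors cannot be estimated")
  lv <- log(v[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lv)
  size_factors <- exp(apply(lv - log_geo, 2, median))
  out <- expression_matrix(sweep(v, 2, size_factors, "/"), matrix$times)
  attr(out, "size_factors") <- size_factors
  out
}

#' Average replicate columns sharing a time point
#'
#' Columns with identical sampling times are replaced by one column holding
#' their arithmetic mean (normalise first; merging follows normalisation).
#'
#' @param matrix an [expression_matrix()]; replicates are encoded as
#'   duplicated entries in `times`.
#' @return An `expr_matrix` with strictly increasing times.
#' @export
merge_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  ut <- unique(matrix$times)
  merged <- vapply(ut, function(t) {
    rowMeans(matrix$values[, matrix$times == t, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (nrow(matrix$values) == 1L) merged <- matrix(merged, nrow = 1L)
  rownames(merged) <- rownames(matrix$values)
  expression_matrix(merged, ut)
}

#' Log-transform and filter genes by temporal fold change
#'
#' Retains genes whose normalised trajectory changes at least
#' `fold_threshold`-fold over the time course, then replaces values by
#' `log10(value + 1)`. To keep genes with a zero minimum well-defined the
#' fold change is computed as `(max + 1) / (min + 1)`, mirroring the
#' pseudo-count of the log transform.
#'
#' @param matrix normalised, replicate-merged [expression_matrix()].
#' @param fold_threshold minimum fold change (>= 1) for a gene to be kept.
#' @return Filtered, log10-transformed `expr_matrix`; the number of genes
#'   removed is in `attr(, "n_filtered")`.
#' @export
log_and_filter <- function(matrix, fold_threshold = 2) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (fold_threshold < 1)
    stop("fold_threshold must be >= 1")
  v <- matrix$values
  if (any(v < 0))
    stop("expression values must be non-negative before log transform")
  fc <- (apply(v, 1, max) + 1) / (apply(v, 1, min) + 1)
  keep <- fc >= fold_threshold
  out <- expression_matrix(log10(v[keep, , drop = FALSE] + 1), matrix$times)
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Scale each gene's trajectory to the unit interval
#'
#' Maps each gene to `(x - x_min) / (x_max - x_min)` so its minimum becomes
#' 0 and its maximum 1. For query/reference pairs scale jointly with
#' [scale_pair()] so the shared per-gene range is used.
#'
#' @param matrix log-transformed [expression_matrix()]; every gene must
#'   have `max > min` (flat genes should have been filtered).
#' @return The scaled `expr_matrix`.
#' @export
scale_unit <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  flat <- hi == lo
  if (any(flat))
    stop("flat gene(s) cannot be scaled (filter first): ",
         paste(head(rownames(v)[flat], 5), collapse = ", "))
  expression_matrix((v - lo) / (hi - lo), matrix$times)
}

#' Jointly scale a query/reference matrix pair to the unit interval
#'
#' With `joint = TRUE` (default) the per-gene minimum and maximum are taken
#' over both series, so the two trajectories remain comparable on a common
#' scale; `joint = FALSE` scales each matrix independently, which suits
#' cross-platform inputs whose absolute units are not comparable.
#'
#' @param query,reference [expression_matrix()] objects with identical
#'   gene sets (same order).
#' @param joint logical; share per-gene min/max across the two matrices.
#' @return List with scaled elements `query` and `reference`.
#' @export
scale_pair <- function(query, reference, joint = TRUE) {
  stopifnot(inherits(query, "expr_matrix"), inherits(reference, "expr_matrix"))
  if (!identical(rownames(query$values), rownames(reference$values)))
    stop("query and reference must contain the same genes in the same order")
  if (!joint)
    return(list(query = scale_unit(query), reference = scale_unit(reference)))
  lo <- pmin(apply(query$values, 1, min), apply(reference$values, 1, min))
  hi <- pmax(apply(query$values, 1, max), apply(reference$values, 1, max))
  flat <- hi == lo
  if (any(flat))
    stop("flat gene(s) cannot be scaled (filter first): ",
         paste(head(rownames(query$values)[flat], 5), collapse = ", "))
  list(
    query = expression_matrix((query$values - lo) / (hi - lo), query$times),
    reference = expression_matrix((reference$values - lo) / (hi - lo),
                                  reference$times)
  )
}

#' Replace sampling times by their rank order (pseudo-time)
#'
#' Unevenly sampled series (large gaps in real time) bias both the warping
#' and the segmented regression; replacing times by their order
#' `0, 1, ..., n - 1` aligns series in time order instead.
#'
#' @param x an [expression_matrix()] or [time_series()].
#' @return The same object with times `0:(n - 1)`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 2), times = c(0, 24, 504))
#' to_pseudotime(m)$times  # 0 1 2
to_pseudotime <- function(x) {
  UseMethod("to_pseudotime")
}

#' @export
to_pseudotime.expr_matrix <- function(x) {
  if (anyDuplicated(x$times))
    stop("merge replicates before converting to pseudo-time")
  expression_matrix(x$values, seq_along(x$times) - 1)
}

#' @export
to_pseudotime.time_series <- function(x) {
  time_series(seq_along(x$times) - 1, x$values, x$label)
}
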