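#' Single-gene expression trajectory
#'
#' @param times strictly increasing numeric sampling times.
#' @param values numeric expression values, one per time (typically scaled
#'   to `[0, 1]` before alignment).
#' @param label optional identifier (gene id and condition).
#' @return An object of class `time_series`.
#' @export
#' @examples
#' time_series(0:4, c(0, .2, .5, .9, 1), "Sox2/query")
time_series <- function(times, values, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  structure(list(times = times, values = values, label = as.character(label)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d points, t = %s..%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), format(x$times[1]),
              format(x$times[length(x$times)])))
  invisible(x)
}

#' Extract one gene's trajectory from an expression matrix
#'
#' @param matrix an [expression_matrix()] (replicate-merged).
#' @param gene gene identifier (must be present).
#' @param label label for the resulting series; defaults to the gene id.
#' @return A [time_series()].
#' @export
gene_series <- function(matrix, gene, label = gene) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!gene %in% rownames(matrix$values))
    stop("gene not found: ", gene)
  time_series(matrix$times, matrix$values[gene, ], label)
}
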