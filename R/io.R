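# Delimited-text input/output for expression matrices and result tables.

#' Read an expression matrix from delimited text
#'
#' Expected layout: first column gene id, remaining column headers numeric
#' sampling times (repeated headers encode replicates). Alternatively a
#' sidecar replicate map (two-column TSV: `column_name`, `time`) assigns
#' times to arbitrarily named columns.
#'
#' @param path TSV/CSV file (delimiter inferred from the extension;
#'   anything not ending in `.csv` is read as tab-separated).
#' @param replicate_map optional path to a replicate-map TSV, or a data
#'   frame with columns `column_name` and `time`.
#' @return An [expression_matrix()] (columns sorted by time).
#' @export
read_expression_matrix <- function(path, replicate_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("expected a gene-id column plus at least 2 sample columns")
  gene_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  headers <- colnames(df)[-1]
  if (!is.null(replicate_map)) {
    map <- if (is.character(replicate_map)) {
      read.delim(replicate_map, sep = "\t", stringsAsFactors = FALSE)
    } else {
      as.data.frame(replicate_map)
    }
    if (!all(c("column_name", "time") %in% colnames(map)))
      stop("replicate map needs columns 'column_name' and 'time'")
    missing <- setdiff(map$column_name, headers)
    if (length(missing) > 0)
      stop("replicate map references missing column(s): ",
           paste(missing, collapse = ", "))
    unmapped <- setdiff(headers, map$column_name)
    if (length(unmapped) > 0)
      stop("column(s) not covered by replicate map: ",
           paste(unmapped, collapse = ", "))
    times <- map$time[match(headers, map$column_name)]
  } else {
    times <- suppressWarnings(as.numeric(headers))
    if (anyNA(times))
      stop("malformed time header(s): ",
           paste(headers[is.na(times)], collapse = ", "),
           " (use a replicate map for non-numeric column names)")
  }
  ord <- order(times)
  expression_matrix(values[, ord, drop = FALSE], times[ord], gene_ids)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, then one
#' column per sample headed by its numeric time.
#'
#' @param matrix an [expression_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", format(matrix$times, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all result tables of a pipeline run
#'
#' Emits `similarity.tsv` (one row per shared gene), `progression.tsv`
#' (STP genes only), `condition_warp.tsv` (query time, median aligned
#' reference time) and `manifest.tsv` (key-value run metadata) into `dir`.
#'
#' @param run result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "tempoalign_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$similarity, file.path(dir, "similarity.tsv"))
  write_tsv(run$progression, file.path(dir, "progression.tsv"))
  if (!is.null(run$condition_warp))
    write_tsv(run$condition_warp, file.path(dir, "condition_warp.tsv"))
  manifest <- data.frame(key = names(run$manifest),
                         value = vapply(run$manifest, function(v)
                           paste(format(v, trim = TRUE), collapse = ","),
                           character(1)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
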