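# Cell-type expression profiling of passing genes: quantile normalization,
# per-type mean/SEM with a log-display offset, specificity and enrichment.

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every column to share one reference distribution: the cross-column
#' mean of order statistics. Ties within a column receive the mean of the
#' corresponding reference values. A single-column matrix is returned
#' unchanged.
#'
#' @param m numeric matrix without missing values.
#' @return the normalized matrix (dimnames and the `cell_types` attribute
#'   preserved).
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("matrix must not contain missing values", call. = FALSE)
  if (ncol(m) == 1L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  attr(out, "cell_types") <- attr(m, "cell_types")
  out
}

ct_types <- function(m, cell_types) {
  ct <- cell_types %||% attr(m, "cell_types")
  if (is.null(ct) || length(ct) != ncol(m)) {
    stop("cell_types must label every column", call. = FALSE)
  }
  ct
}

#' Per-cell-type expression profile of one gene
#'
#' Mean and standard error of the mean over replicate columns per cell type,
#' plus the log-display value (mean + 0.001, so zeros remain representable
#' on a log axis). A single-replicate type has no defined SEM; it is reported
#' as 0 with `sem_defined = FALSE`.
#'
#' @param m genes x columns matrix (typically quantile-normalized).
#' @param gene gene symbol (rowname).
#' @param cell_types character vector labelling columns; defaults to the
#'   matrix's `cell_types` attribute.
#' @param log_offset constant added for log display, default 0.001.
#' @return data.frame: cell_type, mean, sem, n_replicates, sem_defined,
#'   log_ready.
#' @export
celltype_profile <- function(m, gene, cell_types = NULL, log_offset = 0.001) {
  if (!gene %in% rownames(m)) stop("gene absent: ", gene, call. = FALSE)
  ct <- ct_types(m, cell_types)
  vals <- m[gene, ]
  types <- unique(ct)
  rows <- lapply(types, function(tt) {
    v <- vals[ct == tt]
    r <- length(v)
    sem_def <- r >= 2L
    data.frame(cell_type = tt, mean = mean(v),
               sem = if (sem_def) stats::sd(v) / sqrt(r) else 0,
               n_replicates = r, sem_defined = sem_def,
               log_ready = mean(v) + log_offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cell-type specificity of one gene
#'
#' Each cell type's mean expression divided by the sum of cell-type means;
#' the values sum to 1.
#'
#' @inheritParams celltype_profile
#' @return named numeric vector over cell types.
#' @export
specificity <- function(m, gene, cell_types = NULL) {
  if (!gene %in% rownames(m)) stop("gene absent: ", gene, call. = FALSE)
  ct <- ct_types(m, cell_types)
  vals <- m[gene, ]
  means <- vapply(unique(ct), function(tt) mean(vals[ct == tt]), numeric(1))
  tot <- sum(means)
  if (tot == 0) stop("gene has zero total expression; specificity undefined",
                     call. = FALSE)
  means / tot
}

#' Cell-type enrichment (within-type vs out-of-type fold change)
#'
#' Mean expression in the cell type divided by the mean over all other
#' columns.
#'
#' @inheritParams celltype_profile
#' @return named numeric vector over cell types (Inf when the out-of-type
#'   mean is 0).
#' @export
celltype_enrichment <- function(m, gene, cell_types = NULL) {
  if (!gene %in% rownames(m)) stop("gene absent: ", gene, call. = FALSE)
  ct <- ct_types(m, cell_types)
  vals <- m[gene, ]
  vapply(unique(ct), function(tt) {
    mean(vals[ct == tt]) / mean(vals[ct != tt])
  }, numeric(1))
}
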