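# Over-representation analysis: upper-tail hypergeometric test per gene set
# with Bonferroni correction across the sets tested.

#' Hypergeometric over-representation test of a hit list against gene sets
#'
#' For each set, with population N = |background|, K = |set intersect
#' background| annotated genes, n = |hits| draws and k = |hits intersect set|
#' observed, the raw p-value is the upper tail P(X >= k) of the
#' hypergeometric distribution. Bonferroni correction multiplies by the
#' number of sets tested (capped at 1); significance is strict
#' p_bonferroni < alpha.
#'
#' @param hits character vector of passing genes (must lie in `background`).
#' @param gene_sets named list of gene vectors, or a single vector.
#' @param background character vector: the declared gene universe.
#' @param alpha significance level for the Bonferroni-corrected p, default 0.05.
#' @return data.frame (class `imgtx_enrichment`): set, n_hits, set_size,
#'   background_size, hit_list_size, p_raw, p_bonferroni, significant.
#' @export
hypergeometric_enrichment <- function(hits, gene_sets, background,
                                      alpha = 0.05) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  if (length(hits) == 0L) stop("empty hit list", call. = FALSE)
  background <- unique(background)
  hits <- unique(hits)
  outside <- setdiff(hits, background)
  if (length(outside)) {
    stop("hit(s) outside the background universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(hits)
  m <- length(gene_sets)
  res <- lapply(names(gene_sets) %||% seq_along(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    K <- length(set)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_hits = k, set_size = K, background_size = N,
               hit_list_size = n, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, m = m)
  out$significant <- out$p_bonferroni < alpha
  class(out) <- c("imgtx_enrichment", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m number of tests, default `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, m * p)
}
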