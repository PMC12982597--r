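# Donor expression bundle preprocessing: representative probe selection,
# hemisphere restriction, donor-wise z-score normalization, and resampling
# of a contrast map at donor sample coordinates.

#' Construct a donor expression bundle
#'
#' @param donor_id donor label.
#' @param expression probe x sample numeric matrix (dimnames required).
#' @param probes data.frame with columns probe_id, gene_symbol.
#' @param samples data.frame with columns sample_id, x, y, z (mm, in the
#'   contrast map's reference frame; negative x = left hemisphere).
#' @param normalized whether rows are already donor-wise z-scores.
#' @return an object of class `donor_bundle`.
#' @export
donor_bundle <- function(donor_id, expression, probes, samples,
                         normalized = FALSE) {
  stopifnot(is.matrix(expression),
            all(c("probe_id", "gene_symbol") %in% names(probes)),
            all(c("sample_id", "x", "y", "z") %in% names(samples)))
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("expression matrix needs probe rownames and sample colnames", call. = FALSE)
  }
  if (!setequal(rownames(expression), probes$probe_id)) {
    stop("expression rows and probe table disagree", call. = FALSE)
  }
  if (!setequal(colnames(expression), samples$sample_id)) {
    stop("expression columns and sample table disagree", call. = FALSE)
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("a probe must map to exactly one gene", call. = FALSE)
  }
  structure(list(donor_id = donor_id,
                 expression = expression[probes$probe_id, samples$sample_id, drop = FALSE],
                 probes = probes, samples = samples,
                 normalized = isTRUE(normalized)),
            class = "donor_bundle")
}

#' Select the representative probe per gene (least-skewed distribution)
#'
#' Pools each probe's expression values across all donors' samples, computes
#' the adjusted Fisher-Pearson sample skewness, and keeps, per gene, the
#' probe minimizing |skewness|; exact ties (including all-constant probes)
#' break to the lexicographically smallest probe_id.
#'
#' @param bundles list of `donor_bundle` (unnormalized).
#' @param genes genes to resolve; default all genes present.
#' @return named character vector gene_symbol -> probe_id.
#' @export
select_representative_probe <- function(bundles, genes = NULL) {
  stopifnot(length(bundles) >= 1L)
  probes <- bundles[[1]]$probes
  if (is.null(genes)) genes <- sort(unique(probes$gene_symbol))
  absent <- setdiff(genes, probes$gene_symbol)
  if (length(absent)) {
    stop("gene(s) absent from bundles: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  pooled <- do.call(cbind, lapply(bundles, function(b) {
    b$expression[probes$probe_id, , drop = FALSE]
  }))
  skew <- apply(pooled, 1L, function(x) {
    if (stats::sd(x) == 0) Inf else abs(e1071::skewness(x, type = 2))
  })
  vapply(genes, function(g) {
    cand <- probes$probe_id[probes$gene_symbol == g]
    cand <- cand[order(skew[cand], cand)]
    cand[[1]]
  }, character(1))
}

#' Reduce a bundle from probes to genes via a representative-probe map
#'
#' @param bundle a `donor_bundle`.
#' @param probe_map named character vector gene_symbol -> probe_id (from
#'   [select_representative_probe()]).
#' @return a `donor_bundle` whose expression rows are genes.
#' @export
reduce_to_genes <- function(bundle, probe_map) {
  stopifnot(inherits(bundle, "donor_bundle"))
  missing_probes <- setdiff(unname(probe_map), rownames(bundle$expression))
  if (length(missing_probes)) {
    stop("probe(s) absent from bundle: ", paste(missing_probes, collapse = ", "),
         call. = FALSE)
  }
  expr <- bundle$expression[unname(probe_map), , drop = FALSE]
  rownames(expr) <- names(probe_map)
  donor_bundle(bundle$donor_id, expr,
               data.frame(probe_id = names(probe_map),
                          gene_symbol = names(probe_map),
                          stringsAsFactors = FALSE),
               bundle$samples, normalized = bundle$normalized)
}

#' Donor-wise z-score normalization of expression rows
#'
#' Each row (gene or probe) is centered and scaled to sample SD 1 over this
#' donor's samples: z = (x - mean) / sd. Rows with zero variance are marked
#' missing (all NA) for this donor rather than erroring.
#'
#' @param bundle an unnormalized `donor_bundle`.
#' @return the bundle with z-scored rows, `normalized = TRUE`, and attribute
#'   `missing_rows` naming zero-variance rows.
#' @export
normalize_donor <- function(bundle) {
  stopifnot(inherits(bundle, "donor_bundle"))
  if (bundle$normalized) stop("bundle is already normalized", call. = FALSE)
  if (ncol(bundle$expression) < 2L) {
    stop("need at least 2 samples to normalize", call. = FALSE)
  }
  mu <- rowMeans(bundle$expression)
  sd_ <- col_sds(t(bundle$expression))
  z <- (bundle$expression - mu) / sd_
  z[sd_ == 0, ] <- NA_real_
  out <- donor_bundle(bundle$donor_id, z, bundle$probes, bundle$samples,
                      normalized = TRUE)
  attr(out, "missing_rows") <- rownames(bundle$expression)[sd_ == 0]
  out
}

#' Restrict a bundle to left-hemisphere samples (x strictly negative)
#'
#' Midline samples (x = 0) are excluded by the strict rule.
#'
#' @param bundle a `donor_bundle`.
#' @return the restricted bundle with attribute `n_retained`.
#' @export
restrict_left_hemisphere <- function(bundle) {
  stopifnot(inherits(bundle, "donor_bundle"))
  keep <- bundle$samples$x < 0
  if (!any(keep)) {
    stop("no left-hemisphere samples retained for donor ", bundle$donor_id,
         call. = FALSE)
  }
  samples <- bundle$samples[keep, , drop = FALSE]
  out <- donor_bundle(bundle$donor_id,
                      bundle$expression[, samples$sample_id, drop = FALSE],
                      bundle$probes, samples, normalized = bundle$normalized)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Average a contrast map inside a cubic window at each sample coordinate
#'
#' For each coordinate, averages the defined (masked, suprathreshold)
#' t-values of voxels whose centers fall inside the axis-aligned cube of edge
#' `window_mm` centered on the coordinate (boundary-inclusive). Samples whose
#' window holds no defined voxel are dropped (`retained = FALSE`); retained
#' raw averages are then z-scored across this donor's samples.
#'
#' @param map a `contrast_map` (typically light-thresholded at p < 0.01).
#' @param coords data.frame with sample_id, x, y, z in mm.
#' @param window_mm cube edge length in mm, default 5.
#' @return data.frame (class `imgtx_image_samples`) with sample_id, raw, z,
#'   n_voxels, retained; attribute `degenerate` is TRUE when the retained
#'   raw values have zero variance (z undefined).
#' @export
sample_image_at_coords <- function(map, coords, window_mm = 5) {
  stopifnot(inherits(map, "contrast_map"))
  d <- dim(map$t)
  half <- window_mm / 2 + 1e-9
  centers <- lapply(1:3, function(a) axis_centers(d[a], map$voxel_mm[a], map$origin_mm[a]))
  defined <- map$mask & !is.na(map$t)
  n <- nrow(coords)
  raw <- numeric(n)
  nvx <- integer(n)
  for (i in seq_len(n)) {
    cc <- c(coords$x[i], coords$y[i], coords$z[i])
    ix <- which(abs(centers[[1]] - cc[1]) <= half)
    iy <- which(abs(centers[[2]] - cc[2]) <= half)
    iz <- which(abs(centers[[3]] - cc[3]) <= half)
    if (!length(ix) || !length(iy) || !length(iz)) {
      raw[i] <- NA_real_
      next
    }
    sub <- expand.grid(ix, iy, iz)
    lin <- sub[[1]] + (sub[[2]] - 1L) * d[1] + (sub[[3]] - 1L) * d[1] * d[2]
    lin <- lin[defined[lin]]
    nvx[i] <- length(lin)
    raw[i] <- if (length(lin)) mean(map$t[lin]) else NA_real_
  }
  retained <- !is.na(raw)
  if (!any(retained)) {
    stop("all samples fell outside the defined map", call. = FALSE)
  }
  z <- rep(NA_real_, n)
  s <- stats::sd(raw[retained])
  degenerate <- !is.na(s) && s == 0
  if (!degenerate && sum(retained) >= 2L) {
    z[retained] <- (raw[retained] - mean(raw[retained])) / s
  }
  out <- data.frame(sample_id = coords$sample_id, raw = raw, z = z,
                    n_voxels = nvx, retained = retained,
                    stringsAsFactors = FALSE)
  class(out) <- c("imgtx_image_samples", "data.frame")
  attr(out, "degenerate") <- degenerate
  out
}

#' Standard donor preprocessing pipeline
#'
#' Applies the fixed order: restrict to the left hemisphere, select one
#' representative probe per gene (pooled skewness across the restricted
#' donors), reduce to genes, then z-score each gene per donor.
#'
#' @param bundles list of unnormalized `donor_bundle`s.
#' @param genes genes to keep; default all.
#' @return list with `bundles` (restricted, gene-level, normalized) and
#'   `probe_map`.
#' @export
prepare_donors <- function(bundles, genes = NULL) {
  restricted <- lapply(bundles, restrict_left_hemisphere)
  probe_map <- select_representative_probe(restricted, genes)
  prepped <- lapply(restricted, function(b) {
    normalize_donor(reduce_to_genes(b, probe_map))
  })
  list(bundles = prepped, probe_map = probe_map)
}
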