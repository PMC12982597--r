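# Voxel-wise binary degree centrality from masked resting-state time series.

#' Build a gray-matter mask by thresholding a probability volume
#'
#' A voxel is included iff its gray-matter probability is >= `threshold`
#' (inclusive rule, so boundary voxels at exactly the threshold are kept).
#'
#' @param gm_probability 3-D volume with values in \[0, 1\].
#' @param threshold inclusion threshold, default 0.20.
#' @return logical 3-D array with attribute `n_voxels` (count included).
#' @export
make_gm_mask <- function(gm_probability, threshold = 0.20) {
  stopifnot_dim3(gm_probability, "gm_probability")
  if (any(gm_probability < 0 | gm_probability > 1, na.rm = TRUE)) {
    stop("gm_probability values must lie in [0, 1]", call. = FALSE)
  }
  mask <- !is.na(gm_probability) & gm_probability >= threshold
  if (!any(mask)) {
    stop(sprintf("empty gray-matter mask at threshold %g", threshold), call. = FALSE)
  }
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

new_centrality_map <- function(subject_id, values, mask, transform = "none") {
  structure(list(subject_id = subject_id, values = values, mask = mask,
                 transform_applied = transform),
            class = "centrality_map")
}

#' Voxel-wise binary degree centrality
#'
#' The degree of a masked voxel is the number of other masked voxels whose
#' time-series Pearson correlation with it is strictly greater than
#' `r_threshold` (only positive correlations above the cut contribute; the
#' self-correlation is excluded). Voxels with a constant time series cannot
#' carry a correlation and are dropped from the mask with a warning.
#'
#' @param timeseries 4-D array (x, y, z, t).
#' @param mask logical 3-D array on the same grid.
#' @param r_threshold correlation cut, default 0.25 (strictly greater).
#' @return a `centrality_map` with integer degrees on the (possibly reduced)
#'   mask, `NA` outside it, and `transform_applied = "none"`.
#' @export
degree_centrality <- function(timeseries, mask, r_threshold = 0.25) {
  if (!is.array(timeseries) || length(dim(timeseries)) != 4L) {
    stop("timeseries must be a 4-D array", call. = FALSE)
  }
  d <- dim(timeseries)
  if (!identical(dim(mask), d[1:3])) stop("mask grid mismatch", call. = FALSE)
  if (d[4] < 3L) stop("need at least 3 timepoints", call. = FALSE)
  idx <- which(mask)
  if (length(idx) < 2L) stop("need at least 2 masked voxels", call. = FALSE)
  m <- matrix(timeseries, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  sds <- col_sds(t(m))
  if (all(sds == 0)) stop("all masked time series are constant", call. = FALSE)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance voxel(s) removed from the mask")
    keep <- sds > 0
    idx <- idx[keep]
    m <- m[keep, , drop = FALSE]
    mask <- array(FALSE, dim = d[1:3])
    mask[idx] <- TRUE
  }
  if (length(idx) < 2L) stop("fewer than 2 usable masked voxels", call. = FALSE)
  r <- stats::cor(t(m))
  # diag(r) = 1 always exceeds the cut; subtract the self-connection
  deg <- colSums(r > r_threshold) - 1L
  values <- array(NA_real_, dim = d[1:3])
  values[idx] <- deg
  new_centrality_map(NULL, values, mask, "none")
}

#' Transform a degree-centrality map for group analysis
#'
#' `z_standardized` (default) removes subject-level scale by centering and
#' scaling the within-mask degrees to mean 0 / sample SD 1. `fisher_like`
#' rescales degree to \[0, 1) by dividing by V - 1 and applies atanh, the
#' literal variance-stabilizing reading; degrees equal to V - 1 map to +Inf
#' with a warning.
#'
#' @param map a `centrality_map` with `transform_applied = "none"`.
#' @param mode `"z_standardized"` or `"fisher_like"`.
#' @return a transformed `centrality_map`.
#' @export
transform_centrality <- function(map, mode = c("z_standardized", "fisher_like")) {
  stopifnot(inherits(map, "centrality_map"))
  mode <- match.arg(mode)
  if (map$transform_applied != "none") {
    stop("map is already transformed", call. = FALSE)
  }
  v <- map$values[map$mask]
  out <- map$values
  if (mode == "z_standardized") {
    s <- stats::sd(v)
    if (s == 0) stop("degenerate map: within-mask SD is 0", call. = FALSE)
    out[map$mask] <- (v - mean(v)) / s
  } else {
    V <- sum(map$mask)
    p <- v / (V - 1)
    if (any(p >= 1)) warning("degree equal to V-1 maps to +Inf under fisher_like")
    out[map$mask] <- atanh(pmin(p, 1))
  }
  new_centrality_map(map$subject_id, out, map$mask, mode)
}

#' Compute transformed centrality maps for every subject of a cohort
#'
#' Convenience driver: builds the gray-matter mask, then runs
#' [degree_centrality()] and [transform_centrality()] per subject.
#'
#' @param cohort an `imgtx_cohort`.
#' @param gm_threshold mask threshold, default 0.20.
#' @param r_threshold correlation cut, default 0.25.
#' @param transform transform mode passed to [transform_centrality()], or
#'   `"none"` for raw degrees.
#' @return named list of `centrality_map`, one per subject.
#' @export
cohort_centrality <- function(cohort, gm_threshold = 0.20, r_threshold = 0.25,
                              transform = "z_standardized") {
  stopifnot(inherits(cohort, "imgtx_cohort"))
  mask <- make_gm_mask(cohort$gm_probability, gm_threshold)
  maps <- lapply(names(cohort$subjects), function(id) {
    cm <- degree_centrality(cohort$subjects[[id]], mask, r_threshold)
    cm$subject_id <- id
    if (!identical(transform, "none")) cm <- transform_centrality(cm, transform)
    cm
  })
  names(maps) <- names(cohort$subjects)
  maps
}
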