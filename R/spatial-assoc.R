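# Per-gene spatial cross-correlation between an image sample vector and
# multi-donor expression: parcel alignment across donors, PCA regressors
# (>= 95% variance), weighted regression, bootstrap chance likelihood, donor
# autocorrelation, and the association filter.

#' Align donors and image samples on common observation units
#'
#' Donors are sampled at donor-specific coordinates, but one PCA must run
#' across donors, so samples are aggregated into common spatial units:
#' regular cubic parcels of `parcel_edge_vox` voxels per axis (default 3),
#' or exact shared coordinates when `mode = "sample"`. Per unit and donor,
#' the unit expression value is the mean of that donor's z-scored samples in
#' the parcel; the unit image value is the mean image z over all contributing
#' samples; the regression weight is the total contributing sample count.
#' Units lacking any donor are dropped.
#'
#' @param bundles list of normalized, restricted gene-level `donor_bundle`s.
#' @param image_samples list of [sample_image_at_coords()] results, one per
#'   donor, in the same order.
#' @param parcel_edge_vox parcel edge in voxels (parcel mode); the default 2
#'   (4 mm at 2-mm voxels) is commensurate with the 5-mm sampling window and
#'   keeps enough donor-complete units at desk scale.
#' @param voxel_mm,origin_mm grid geometry of the sampled map.
#' @param mode `"parcel"` (default) or `"sample"` (donors must share
#'   coordinates exactly; one unit per coordinate).
#' @return object of class `imgtx_aligned`: list with `units`, `genes`,
#'   `X` (unit x donor x gene array), `y`, `w`, `counts` (unit x donor).
#' @export
align_units <- function(bundles, image_samples, parcel_edge_vox = 2L,
                        voxel_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                        mode = c("parcel", "sample")) {
  mode <- match.arg(mode)
  stopifnot(length(bundles) >= 2L, length(bundles) == length(image_samples))
  genes <- rownames(bundles[[1]]$expression)
  n_donors <- length(bundles)
  donor_unit <- vector("list", n_donors)
  for (d in seq_len(n_donors)) {
    b <- bundles[[d]]
    if (!b$normalized) stop("bundles must be normalized first", call. = FALSE)
    im <- image_samples[[d]]
    if (isTRUE(attr(im, "degenerate"))) {
      stop("degenerate image sampling for donor ", b$donor_id, call. = FALSE)
    }
    use <- im$retained & !is.na(im$z)
    ids <- im$sample_id[use]
    sm <- b$samples[match(ids, b$samples$sample_id), , drop = FALSE]
    if (anyNA(sm$sample_id)) stop("image samples not found in bundle", call. = FALSE)
    key <- if (mode == "parcel") {
      edge_mm <- parcel_edge_vox * voxel_mm
      corner <- origin_mm - voxel_mm / 2
      paste(floor((sm$x - corner[1]) / edge_mm[1]),
            floor((sm$y - corner[2]) / edge_mm[2]),
            floor((sm$z - corner[3]) / edge_mm[3]), sep = "_")
    } else {
      paste(signif(sm$x, 10), signif(sm$y, 10), signif(sm$z, 10), sep = "_")
    }
    E <- b$expression[, ids, drop = FALSE]            # gene x sample (z-scores)
    grp <- factor(key)
    cnt <- as.integer(table(grp))
    names(cnt) <- levels(grp)
    esum <- t(rowsum(t(E), grp))                      # gene x unit sums
    emean <- sweep(esum, 2L, cnt[colnames(esum)], "/")
    ysum <- rowsum(im$z[use], grp)[, 1]
    donor_unit[[d]] <- list(units = levels(grp), emean = emean,
                            count = cnt, ysum = ysum)
  }
  common <- Reduce(intersect, lapply(donor_unit, `[[`, "units"))
  if (length(common) < 3L) stop("fewer than 3 usable units", call. = FALSE)
  common <- sort(common)
  X <- array(NA_real_, dim = c(length(common), n_donors, length(genes)),
             dimnames = list(common, vapply(bundles, `[[`, "", "donor_id"), genes))
  counts <- matrix(0L, length(common), n_donors,
                   dimnames = list(common, dimnames(X)[[2]]))
  ysum <- numeric(length(common))
  for (d in seq_len(n_donors)) {
    du <- donor_unit[[d]]
    X[, d, ] <- t(du$emean[, common, drop = FALSE])
    counts[, d] <- du$count[common]
    ysum <- ysum + du$ysum[common]
  }
  w <- rowSums(counts)
  y <- ysum / w
  structure(list(units = common, genes = genes, X = X, y = y, w = w,
                 counts = counts),
            class = "imgtx_aligned")
}

#' Extract one gene's aligned regression data
#'
#' Keeps only units with a complete expression row for this gene (a donor
#' with zero expression variance contributes NA for all its units).
#'
#' @param aligned an `imgtx_aligned`.
#' @param gene gene symbol.
#' @return list with `gene`, `X` (unit x donor matrix), `y`, `w`.
#' @export
gene_data <- function(aligned, gene) {
  stopifnot(inherits(aligned, "imgtx_aligned"))
  if (!gene %in% aligned$genes) stop("gene not aligned: ", gene, call. = FALSE)
  Xg <- aligned$X[, , gene]
  ok <- stats::complete.cases(Xg)
  list(gene = gene, X = Xg[ok, , drop = FALSE],
       y = aligned$y[ok], w = aligned$w[ok])
}

#' PCA regressors explaining at least a target share of variance
#'
#' Column-centered principal component analysis of the unit x donor matrix;
#' keeps the smallest number of components whose cumulative explained
#' variance reaches `var_target`.
#'
#' @param X unit x donor matrix, no missing values.
#' @param var_target cumulative explained-variance target, default 0.95.
#' @return list with `scores` (unit x k), `k`, `variance_explained`,
#'   `loadings`.
#' @export
pca_regressors <- function(X, var_target = 0.95) {
  stopifnot(is.matrix(X), ncol(X) >= 2L)
  if (anyNA(X)) stop("X must be complete", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- La.svd(Xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total == 0) stop("zero total variance", call. = FALSE)
  cum <- cumsum(ev) / total
  k <- which(cum >= var_target - 1e-12)[1]
  scores <- Xc %*% t(sv$vt[seq_len(k), , drop = FALSE])
  list(scores = scores, k = k, variance_explained = cum[k],
       loadings = t(sv$vt[seq_len(k), , drop = FALSE]))
}

# Weighted R^2 of y on [1, S]; the workhorse of the bootstrap. w >= 0.
wls_r2 <- function(y, S, w) {
  sw <- sqrt(w)
  Z <- cbind(sw, S * sw)
  fit <- stats::.lm.fit(Z, y * sw)
  rss <- sum(fit$residuals^2)
  mu <- sum(w * y) / sum(w)
  tss <- sum(w * (y - mu)^2)
  if (tss == 0) return(NA_real_)
  1 - rss / tss
}

# Weighted Pearson correlation.
weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) return(NA_real_)
  cxy / sqrt(cxx * cyy)
}

#' Weighted multiple regression of image values on PCA regressors
#'
#' Weighted least squares of y on an intercept plus the component scores;
#' reports the weighted R^2, the small-sample adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1), and the direction of the
#' imaging-genomic association: the sign of the weighted Pearson correlation
#' between y and the across-donor mean expression.
#'
#' @param y unit image values.
#' @param components unit x k score matrix.
#' @param w nonnegative unit weights (not all zero).
#' @param expression_mean optional across-donor mean expression per unit;
#'   required for `direction`.
#' @return list with `r2`, `r2_adjusted`, `direction`, `n`, `k`, `undefined`.
#' @export
weighted_regression <- function(y, components, w, expression_mean = NULL) {
  components <- as.matrix(components)
  n <- length(y)
  k <- ncol(components)
  stopifnot(nrow(components) == n, length(w) == n)
  if (all(w == 0)) stop("weights must not all be zero", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (n <= k + 1L) {
    warning("n <= k + 1: adjusted R^2 undefined")
    return(list(r2 = NA_real_, r2_adjusted = NA_real_, direction = NA_real_,
                n = n, k = k, undefined = TRUE))
  }
  r2 <- wls_r2(y, components, w)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  dir <- if (is.null(expression_mean)) NA_real_ else {
    sign(weighted_cor(y, expression_mean, w))
  }
  list(r2 = r2, r2_adjusted = r2_adj, direction = dir, n = n, k = k,
       undefined = FALSE)
}

#' Bootstrap chance likelihood of a gene's spatial association
#'
#' Resamples the genomic data `n_boot` times by permuting the rows of the
#' unit x donor expression matrix (all donor columns together) while the
#' image values and weights stay fixed, re-runs PCA -> weighted regression,
#' and returns the fraction of resampled R^2 strictly exceeding the observed
#' R^2. Permuting rows leaves the column-centered PCA loadings and component
#' count unchanged and permutes the scores by the same row order, so each
#' resample is computed exactly as the weighted regression of y on the
#' row-permuted scores (bit-identical to re-running the full PCA, at a
#' fraction of the cost).
#'
#' @param gd a [gene_data()] list (fields X, y, w).
#' @param n_boot number of resamples, default 1000.
#' @param seed integer seed.
#' @param var_target PCA explained-variance target.
#' @return chance likelihood in \[0, 1\], with attributes `r2_observed` and
#'   `k`.
#' @export
chance_likelihood <- function(gd, n_boot = 1000L, seed = 1L, var_target = 0.95) {
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  pca <- pca_regressors(gd$X, var_target)
  r2_or <- wls_r2(gd$y, pca$scores, gd$w)
  n <- length(gd$y)
  S <- pca$scores
  sw <- sqrt(gd$w)
  ysw <- gd$y * sw
  mu <- sum(gd$w * gd$y) / sum(gd$w)
  tss <- sum(gd$w * (gd$y - mu)^2)
  Z <- cbind(sw, S)                      # col 1 fixed; cols 2..k+1 refilled
  exceed <- 0L
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      perm <- sample.int(n)
      Z[, -1L] <- S[perm, , drop = FALSE] * sw
      rss <- sum(stats::.lm.fit(Z, ysw)$residuals^2)
      r2_b <- 1 - rss / tss
      if (r2_b > r2_or) exceed <- exceed + 1L
    }
  })
  structure(exceed / n_boot, r2_observed = r2_or, k = pca$k)
}

#' Mean pairwise donor correlation of a gene's regional expression
#'
#' Pearson correlation over shared units for every unordered donor pair;
#' pairs involving a zero-variance donor column are skipped. Returns NA when
#' no pair is computable.
#'
#' @param X unit x donor matrix.
#' @return mean pairwise correlation in \[-1, 1\], or NA.
#' @export
donor_autocorrelation <- function(X) {
  stopifnot(is.matrix(X), ncol(X) >= 2L)
  sds <- col_sds(X)
  usable <- which(sds > 0)
  if (length(usable) < 2L) return(NA_real_)
  r <- stats::cor(X[, usable, drop = FALSE])
  mean(r[upper.tri(r)])
}

#' Per-gene spatial association with bootstrap null and filter
#'
#' Runs, for every aligned gene: PCA regressors, weighted regression
#' (adjusted R^2 and direction), the bootstrap chance likelihood, and the
#' donor autocorrelation; then applies the association filter
#' (chance likelihood < `cl_max`, autocorrelation >= `ac_min`,
#' adjusted R^2 >= `r2_min`).
#'
#' @param aligned an `imgtx_aligned`.
#' @param n_boot bootstrap resamples per gene, default 1000.
#' @param seed integer master seed; gene g uses seed + g.
#' @param var_target PCA explained-variance target, default 0.95.
#' @param cl_max,ac_min,r2_min filter thresholds (defaults 0.001, 0.2, 0.15).
#' @return data.frame (class `imgtx_assoc`) with one row per gene: gene,
#'   r2_adjusted, direction, chance_likelihood, autocorrelation,
#'   n_components, n_units, passes_filter.
#' @export
gene_association <- function(aligned, n_boot = 1000L, seed = 1L,
                             var_target = 0.95, cl_max = 0.001,
                             ac_min = 0.2, r2_min = 0.15) {
  stopifnot(inherits(aligned, "imgtx_aligned"))
  rows <- lapply(seq_along(aligned$genes), function(g) {
    gene <- aligned$genes[g]
    gd <- gene_data(aligned, gene)
    if (length(gd$y) < ncol(gd$X) + 2L) {
      return(data.frame(gene = gene, r2_adjusted = NA_real_,
                        direction = NA_real_, chance_likelihood = NA_real_,
                        autocorrelation = NA_real_, n_components = NA_integer_,
                        n_units = length(gd$y), passes_filter = FALSE,
                        stringsAsFactors = FALSE))
    }
    pca <- pca_regressors(gd$X, var_target)
    reg <- weighted_regression(gd$y, pca$scores, gd$w,
                               expression_mean = rowMeans(gd$X))
    cl <- chance_likelihood(gd, n_boot = n_boot, seed = seed + g,
                            var_target = var_target)
    ac <- donor_autocorrelation(gd$X)
    data.frame(gene = gene, r2_adjusted = reg$r2_adjusted,
               direction = reg$direction, chance_likelihood = as.numeric(cl),
               autocorrelation = ac, n_components = pca$k,
               n_units = length(gd$y),
               passes_filter = isTRUE(as.numeric(cl) < cl_max && !is.na(ac) &&
                                        ac >= ac_min && !is.na(reg$r2_adjusted) &&
                                        reg$r2_adjusted >= r2_min),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("imgtx_assoc", "data.frame")
  out
}

#' Filter association results by the reliability criteria
#'
#' Strict `<` for chance likelihood; inclusive `>=` for autocorrelation and
#' adjusted R^2.
#'
#' @param results an `imgtx_assoc` data.frame.
#' @param cl_max,ac_min,r2_min thresholds (defaults 0.001, 0.2, 0.15).
#' @return sorted character vector of passing gene symbols.
#' @export
filter_genes <- function(results, cl_max = 0.001, ac_min = 0.2, r2_min = 0.15) {
  if (nrow(results) == 0L) return(character(0))
  ok <- !is.na(results$chance_likelihood) & results$chance_likelihood < cl_max &
    !is.na(results$autocorrelation) & results$autocorrelation >= ac_min &
    !is.na(results$r2_adjusted) & results$r2_adjusted >= r2_min
  sort(results$gene[ok])
}
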