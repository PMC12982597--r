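# Voxel-wise general linear model group contrasts, cluster-extent
# thresholding and minimum-statistic conjunction analysis.

#' Build a group design matrix with nuisance covariates
#'
#' Cell-means coding for group (one indicator per level, no intercept) plus
#' age and treatment-coded sex and scanner indicators, mirroring a full
#' factorial group model with nuisance covariates.
#'
#' @param covariates data.frame with columns subject_id, group, age, sex,
#'   scanner (extra columns ignored).
#' @param covariate_cols nuisance columns to adjust for; default
#'   `c("age", "sex", "scanner")`. Use `character(0)` for a group-only design.
#' @return list with `X` (numeric matrix, rownames = subject_id),
#'   `group_levels`, and `columns` (colnames of X).
#' @export
group_design <- function(covariates, covariate_cols = c("age", "sex", "scanner")) {
  need <- c("subject_id", "group", covariate_cols)
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- covariates
  df$group <- factor(df$group)
  for (cc in covariate_cols) {
    if (is.character(df[[cc]])) df[[cc]] <- factor(df[[cc]])
  }
  rhs <- paste(c("0", "group", covariate_cols), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
  rownames(X) <- df$subject_id
  list(X = X, group_levels = levels(df$group), columns = colnames(X))
}

#' Contrast vector for a difference of group means
#'
#' @param design a [group_design()] result.
#' @param positive,negative group levels entering with weight +1 / -1.
#' @return named numeric vector over the design columns.
#' @export
group_contrast <- function(design, positive, negative) {
  cvec <- stats::setNames(numeric(length(design$columns)), design$columns)
  pos_col <- paste0("group", positive)
  neg_col <- paste0("group", negative)
  if (!all(c(pos_col, neg_col) %in% design$columns)) {
    stop("group level not present in design: ",
         paste(setdiff(c(pos_col, neg_col), design$columns), collapse = ", "),
         call. = FALSE)
  }
  cvec[pos_col] <- 1
  cvec[neg_col] <- -1
  cvec
}

new_contrast_map <- function(t_values, mask, dof, label = "",
                             direction = "greater", threshold = NULL,
                             voxel_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  structure(list(t = t_values, mask = mask, dof = dof, label = label,
                 direction = direction, threshold = threshold,
                 voxel_mm = voxel_mm, origin_mm = origin_mm),
            class = "contrast_map")
}

#' Voxel-wise OLS contrast of centrality maps
#'
#' Fits, per masked voxel, an ordinary least-squares model of the map values
#' on the design matrix and returns the contrast t-statistic
#' t = c'beta / SE(c'beta) with dof = n - rank(design). Voxels with zero
#' residual variance are flagged missing (NA).
#'
#' @param maps list of `centrality_map` sharing one mask, in design row order.
#' @param design a [group_design()] result (or list with an `X` matrix).
#' @param contrast numeric contrast vector over the design columns.
#' @param label contrast label stored on the map.
#' @param direction `"greater"` or `"less"`: which tail is of interest when
#'   the map is later thresholded.
#' @param voxel_mm,origin_mm grid geometry to carry on the result.
#' @return a `contrast_map` (unthresholded).
#' @export
fit_voxelwise_glm <- function(maps, design, contrast, label = "",
                              direction = c("greater", "less"),
                              voxel_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  direction <- match.arg(direction)
  X <- design$X
  n <- nrow(X)
  if (length(maps) != n) stop("number of maps must match design rows", call. = FALSE)
  mask <- maps[[1]]$mask
  for (m in maps) {
    if (!identical(which(m$mask), which(mask))) {
      stop("all maps must share one mask", call. = FALSE)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(contrast) != ncol(X)) {
    stop("contrast length must equal the number of design columns", call. = FALSE)
  }
  Y <- vapply(maps, function(m) m$values[mask], numeric(sum(mask)))
  Y <- t(Y)                                   # n x V
  beta <- qr.coef(qrX, Y)                     # p x V
  res <- Y - X %*% beta
  dof <- n - qrX$rank
  if (dof <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- colSums(res^2) / dof
  cXXc <- drop(t(contrast) %*% solve(crossprod(X)) %*% contrast)
  se <- sqrt(sigma2 * cXXc)
  tvals <- drop(crossprod(contrast, beta)) / se
  tvals[se == 0 | !is.finite(tvals)] <- NA_real_
  tvol <- array(NA_real_, dim = dim(mask))
  tvol[mask] <- tvals
  new_contrast_map(tvol, mask, dof, label, direction,
                   voxel_mm = voxel_mm, origin_mm = origin_mm)
}

# 3-D connected-component labelling by iterative flood fill.
# connectivity: 6 = faces, 18 = faces + edges, 26 = full neighbourhood.
label_components <- function(mask3d, connectivity = 18L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(mask3d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = s == 1L, "18" = s >= 1L & s <= 2L, "26" = s >= 1L)
  offs <- as.matrix(offs[keep, ])
  labels <- array(0L, dim = d)
  current <- 0L
  todo <- which(mask3d)
  coords <- arrayInd(todo, d)
  pos_of <- array(0L, dim = d)
  pos_of[todo] <- seq_along(todo)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      p <- coords[pos_of[v], ]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > d)) next
        lin <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
        if (mask3d[lin] && labels[lin] == 0L) {
          labels[lin] <- current
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

#' Threshold a contrast map at a voxel p-value with a cluster-extent rule
#'
#' A voxel survives iff its one-sided p-value from the t distribution with
#' the map's dof is strictly below `p_voxel`; surviving voxels are grouped
#' into 18-connected components and components smaller than `k` voxels are
#' removed.
#'
#' @param cm unthresholded `contrast_map`.
#' @param p_voxel voxel-level one-sided p threshold (strict <).
#' @param k minimum cluster extent in voxels (>= 1).
#' @param connectivity 6, 18 (default) or 26.
#' @return a `contrast_map` whose `t` is NA outside surviving clusters, with
#'   `threshold` recording (p_voxel, k, connectivity) and `cluster_sizes`.
#' @export
threshold_map <- function(cm, p_voxel = 0.001, k = 20L, connectivity = 18L) {
  stopifnot(inherits(cm, "contrast_map"))
  if (!is.null(cm$threshold)) stop("map is already thresholded", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (p_voxel <= 0 || p_voxel >= 1) stop("p_voxel must be in (0, 1)", call. = FALSE)
  p <- array(NA_real_, dim = dim(cm$t))
  ok <- cm$mask & !is.na(cm$t)
  p[ok] <- if (cm$direction == "greater") {
    stats::pt(cm$t[ok], df = cm$dof, lower.tail = FALSE)
  } else {
    stats::pt(cm$t[ok], df = cm$dof, lower.tail = TRUE)
  }
  supra <- !is.na(p) & p < p_voxel
  labels <- label_components(supra, connectivity)
  sizes <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer(0)
  keep_labels <- which(sizes >= k)
  surviving <- array(labels %in% keep_labels, dim = dim(labels))
  tout <- cm$t
  tout[!surviving] <- NA_real_
  out <- new_contrast_map(tout, cm$mask, cm$dof, cm$label, cm$direction,
                          threshold = list(p_voxel = p_voxel, k = as.integer(k),
                                           connectivity = as.integer(connectivity)),
                          voxel_mm = cm$voxel_mm, origin_mm = cm$origin_mm)
  out$cluster_sizes <- sort(sizes[keep_labels], decreasing = TRUE)
  out
}

#' Minimum-statistic conjunction of two contrast maps
#'
#' The conjunction statistic at a voxel is the less significant of the two
#' t-values (elementwise min for `"greater"` contrasts, max for `"less"`),
#' so thresholding the output requires both contrasts to be suprathreshold
#' (test of the conjunction null).
#'
#' @param cm_a,cm_b unthresholded `contrast_map`s on the same mask with the
#'   same direction.
#' @return an unthresholded `contrast_map`; dof is the conservative
#'   min(dof_a, dof_b).
#' @export
conjunction <- function(cm_a, cm_b) {
  stopifnot(inherits(cm_a, "contrast_map"), inherits(cm_b, "contrast_map"))
  if (!identical(which(cm_a$mask), which(cm_b$mask))) {
    stop("conjunction requires identical masks", call. = FALSE)
  }
  if (!identical(cm_a$direction, cm_b$direction)) {
    stop("conjunction requires the same direction", call. = FALSE)
  }
  tv <- if (cm_a$direction == "greater") pmin(cm_a$t, cm_b$t) else pmax(cm_a$t, cm_b$t)
  new_contrast_map(tv, cm_a$mask, min(cm_a$dof, cm_b$dof),
                   label = paste0("conj(", cm_a$label, ",", cm_b$label, ")"),
                   direction = cm_a$direction,
                   voxel_mm = cm_a$voxel_mm, origin_mm = cm_a$origin_mm)
}
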