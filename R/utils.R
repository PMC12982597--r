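# Internal helpers: seeded evaluation, voxel-grid geometry, validation.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the Mersenne-Twister generator seeded at `seed`, then
#' restores the caller's RNG state, so no global state leaks out of package
#' functions. All package randomness flows through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Voxel-center world coordinates along one axis: origin is the center of the
# first voxel, successive centers are voxel_mm apart.
axis_centers <- function(n, voxel_mm, origin_mm) {
  origin_mm + (seq_len(n) - 1) * voxel_mm
}

# Default symmetric origin: voxel centers straddle 0 on every axis, so a
# negative first (x) coordinate is the left hemisphere and no center sits on
# the midline when the axis has an even number of voxels.
default_origin <- function(dim, voxel_mm) {
  -(dim - 1) / 2 * voxel_mm
}

stopifnot_dim3 <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(what, " must be a 3-D array", call. = FALSE)
  }
}

# Sample standard deviation of matrix columns without apply() overhead.
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows for a sample SD", call. = FALSE)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
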