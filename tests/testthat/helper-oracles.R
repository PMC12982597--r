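# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive re-derivation (double loops, exact
# enumeration, closed forms) kept free of the package's own code paths.

# Brute-force degree centrality: O(V^2) double loop over voxel pairs.
oracle_degree <- function(mat_t_by_v, r_threshold) {
  V <- ncol(mat_t_by_v)
  deg <- integer(V)
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      if (stats::cor(mat_t_by_v[, i], mat_t_by_v[, j]) > r_threshold) {
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
  }
  deg
}

# Classical pooled-variance two-sample t (group1 - group2).
oracle_two_sample_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Connected-component sizes of a 3-D logical mask via igraph.
oracle_cluster_sizes <- function(mask3d, connectivity = 18L) {
  d <- dim(mask3d)
  idx <- which(mask3d)
  if (!length(idx)) return(integer(0))
  coords <- arrayInd(idx, d)
  id_of <- stats::setNames(seq_along(idx), idx)
  edges <- integer(0)
  for (a in seq_along(idx)) {
    p <- coords[a, ]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      s <- abs(dx) + abs(dy) + abs(dz)
      ok <- switch(as.character(connectivity),
                   "6" = s == 1, "18" = s >= 1 && s <= 2, "26" = s >= 1)
      if (!ok) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      lin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
      if (mask3d[lin] && lin > idx[a]) {
        edges <- c(edges, a, id_of[[as.character(lin)]])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  sort(as.integer(igraph::components(g)$csize))
}

# Adjusted Fisher-Pearson sample skewness (the G1 estimator), by formula.
oracle_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

# Exact hypergeometric upper tail by enumerating every draw of size n.
oracle_hyper_enum <- function(N, K, n, k) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# Naive chance likelihood: re-runs the full PCA -> weighted regression on the
# row-permuted expression matrix for every resample.
oracle_chance_likelihood <- function(gd, n_boot, seed, var_target = 0.95) {
  pca <- pca_regressors(gd$X, var_target)
  reg <- weighted_regression(gd$y, pca$scores, gd$w)
  r2_or <- reg$r2
  n <- length(gd$y)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister")
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    perm <- sample.int(n)
    pca_b <- pca_regressors(gd$X[perm, , drop = FALSE], var_target)
    r2_b <- weighted_regression(gd$y, pca_b$scores, gd$w)$r2
    if (r2_b > r2_or) exceed <- exceed + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  exceed / n_boot
}

# Tiny synthetic contrast map: a dense smooth-ish field defined on the whole
# grid (every voxel masked and finite), for association tests that need full
# sample retention.
make_dense_map <- function(dims = c(10, 10, 10), voxel_mm = 2, seed = 1,
                           dof = 30L) {
  set.seed(seed)
  centers <- lapply(1:3, function(a) seq_len(dims[a]))
  base <- array(0, dim = dims)
  # sum of a few radial bumps => spatially smooth field
  for (b in 1:4) {
    ctr <- runif(3, 1, dims)
    amp <- rnorm(1, 0, 2)
    for (z in seq_len(dims[3])) {
      dz2 <- (z - ctr[3])^2
      for (y in seq_len(dims[2])) {
        dy2 <- (y - ctr[2])^2
        dx2 <- (seq_len(dims[1]) - ctr[1])^2
        base[, y, z] <- base[, y, z] + amp * exp(-(dx2 + dy2 + dz2) / 18)
      }
    }
  }
  base <- base + array(rnorm(prod(dims), sd = 0.1), dim = dims)
  imgtx:::new_contrast_map(base, array(TRUE, dim = dims), dof,
                           label = "synthetic_field", direction = "greater",
                           voxel_mm = rep(voxel_mm, 3),
                           origin_mm = imgtx:::default_origin(dims, voxel_mm))
}

# Shared-coordinate atlas + alignment at the sample level: the exact-recovery
# configuration (one unit per shared coordinate, no parcel aggregation).
make_shared_aligned <- function(map, n_samples = 110, n_genes = 30,
                                n_coupled = 10, beta = 1, noise_sd = 1,
                                seed = 1) {
  cfg <- sim_config(grid_shape = dim(map$t), voxel_mm = map$voxel_mm[1],
                    n_samples_per_donor = n_samples, n_genes = n_genes,
                    n_coupled_genes = n_coupled, coupling_beta = beta,
                    expression_noise_sd = noise_sd, n_probes_per_gene = 1L,
                    shared_donor_coords = TRUE, seed = seed)
  atlas <- generate_donor_atlas(cfg, map)
  prep <- prepare_donors(atlas$bundles)
  ims <- lapply(prep$bundles, function(b) {
    sample_image_at_coords(map, b$samples, window_mm = 5)
  })
  aligned <- align_units(prep$bundles, ims, voxel_mm = map$voxel_mm,
                         origin_mm = map$origin_mm, mode = "sample")
  list(aligned = aligned, truth = atlas$truth, config = cfg)
}

# Small cohort config used in several tests.
tiny_sim <- function(...) {
  sim_config(grid_shape = c(6, 6, 6), n_timepoints = 50,
             n_per_group = c(control = 8, patient = 8),
             n_genes = 12, n_coupled_genes = 4, n_samples_per_donor = 80,
             ...)
}
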