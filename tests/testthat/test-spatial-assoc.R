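test_that("sample-level alignment reproduces shared-coordinate matrices exactly", {
  map <- make_dense_map(c(8, 8, 8), seed = 2)
  sh <- make_shared_aligned(map, n_samples = 60, n_genes = 8, n_coupled = 3,
                            seed = 4)
  al <- sh$aligned
  # every unit is one shared coordinate; donor columns must equal the donors'
  # z-scored expression at that sample
  cfg <- sh$config
  atlas <- generate_donor_atlas(cfg, map)
  prep <- prepare_donors(atlas$bundles)
  b1 <- prep$bundles[[1]]
  ims <- sample_image_at_coords(map, b1$samples, 5)
  g <- al$genes[1]
  for (u in sample(seq_along(al$units), 5)) {
    key <- al$units[u]
    xyz <- as.numeric(strsplit(key, "_")[[1]])
    j <- which(abs(b1$samples$x - xyz[1]) < 1e-9)
    expect_length(j, 1)
    expect_equal(al$X[u, 1, g], unname(b1$expression[g, j]))
  }
  expect_true(all(al$counts == 1L))
  expect_true(all(al$w == length(prep$bundles)))
})

test_that("parcel aggregation equals a brute-force group-by over samples", {
  set.seed(13)
  map <- make_dense_map(c(8, 8, 8), seed = 9)
  cfg <- sim_config(grid_shape = c(8, 8, 8), n_samples_per_donor = 300,
                    n_genes = 6, n_coupled_genes = 2, n_probes_per_gene = 1,
                    seed = 14)
  atlas <- generate_donor_atlas(cfg, map)
  prep <- prepare_donors(atlas$bundles)
  ims <- lapply(prep$bundles, function(b) sample_image_at_coords(map, b$samples, 5))
  al <- align_units(prep$bundles, ims, parcel_edge_vox = 2,
                    voxel_mm = rep(2, 3),
                    origin_mm = imgtx:::default_origin(c(8, 8, 8), 2))
  # brute force for donor 3, gene 2
  b <- prep$bundles[[3]]
  im <- ims[[3]]
  use <- im$retained & !is.na(im$z)
  corner <- imgtx:::default_origin(c(8, 8, 8), 2) - 1
  key <- paste(floor((b$samples$x[use] - corner[1]) / 4),
               floor((b$samples$y[use] - corner[2]) / 4),
               floor((b$samples$z[use] - corner[3]) / 4), sep = "_")
  gene <- al$genes[2]
  vals <- b$expression[gene, im$sample_id[use]]
  for (u in al$units) {
    expect_equal(unname(al$X[u, 3, gene]), mean(vals[key == u]))
    expect_identical(unname(al$counts[u, 3]), sum(key == u))
  }
  # y is the count-weighted pooled mean of image z over donors
  ysum <- rep(0, length(al$units))
  names(ysum) <- al$units
  wsum <- ysum
  for (d in seq_along(prep$bundles)) {
    bd <- prep$bundles[[d]]; imd <- ims[[d]]
    ud <- imd$retained & !is.na(imd$z)
    kd <- paste(floor((bd$samples$x[ud] - corner[1]) / 4),
                floor((bd$samples$y[ud] - corner[2]) / 4),
                floor((bd$samples$z[ud] - corner[3]) / 4), sep = "_")
    for (u in al$units) {
      ysum[u] <- ysum[u] + sum(imd$z[ud][kd == u])
      wsum[u] <- wsum[u] + sum(kd == u)
    }
  }
  expect_equal(unname(al$y), unname(ysum / wsum))
  expect_equal(unname(al$w), unname(wsum))
})

test_that("PCA regressors honor the 95% variance rule", {
  X1 <- matrix(rep(rnorm(20), 4), 20, 4)
  p1 <- pca_regressors(X1)
  expect_identical(p1$k, 1L)
  expect_equal(p1$variance_explained, 1)

  # two orthogonal, equal-variance centered columns: one PC explains 50%
  a <- c(1, -1, 1, -1, 1, -1, 1, -1)
  b <- c(1, 1, -1, -1, 1, 1, -1, -1)
  p2 <- pca_regressors(cbind(a, b))
  expect_identical(p2$k, 2L)

  expect_error(pca_regressors(matrix(3, 5, 4)), "zero total variance")

  set.seed(15)
  X <- matrix(rnorm(30 * 6), 30, 6)
  p <- pca_regressors(X, 0.95)
  ev <- eigen(cov(X))
  lam <- ev$values * (nrow(X) - 1)
  cum <- cumsum(lam) / sum(lam)
  expect_identical(p$k, which(cum >= 0.95)[1])
  # loadings match eigenvectors up to sign
  for (j in seq_len(p$k)) {
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # scores are the centered data projected on the loadings
  expect_equal(p$scores, sweep(X, 2, colMeans(X)) %*% p$loadings,
               tolerance = 1e-12)
})

test_that("weighted regression reduces to OLS and flags undefined fits", {
  set.seed(16)
  n <- 25
  S <- matrix(rnorm(n * 3), n)
  y <- drop(S %*% c(1, -2, 0.5)) + rnorm(n)
  w <- rep(1, n)
  reg <- weighted_regression(y, S, w, expression_mean = rowMeans(S))
  fit <- lm(y ~ S)
  expect_equal(reg$r2, summary(fit)$r.squared, tolerance = 1e-10)
  expect_equal(reg$r2_adjusted, summary(fit)$adj.r.squared, tolerance = 1e-10)

  # weighted case against lm(weights=)
  w2 <- runif(n, 0.5, 4)
  reg2 <- weighted_regression(y, S, w2)
  fit2 <- lm(y ~ S, weights = w2)
  expect_equal(reg2$r2, summary(fit2)$r.squared, tolerance = 1e-10)

  # perfect fit on the first component
  reg3 <- weighted_regression(S[, 1], S, w)
  expect_equal(reg3$r2, 1, tolerance = 1e-12)
  expect_equal(reg3$r2_adjusted, 1, tolerance = 1e-12)

  expect_warning(r <- weighted_regression(rnorm(4), matrix(rnorm(12), 4), rep(1, 4)),
                 "undefined")
  expect_true(r$undefined)
  expect_error(weighted_regression(y, S, rep(0, n)), "zero")
})

test_that("null-coupled regressors give non-positive adjusted R^2 on average", {
  set.seed(17)
  vals <- replicate(200, {
    S <- matrix(rnorm(20 * 3), 20)
    weighted_regression(rnorm(20), S, rep(1, 20))$r2_adjusted
  })
  expect_lt(mean(vals), 0.02)
})

test_that("fast chance likelihood is identical to the naive full-PCA oracle", {
  set.seed(18)
  for (rep in 1:3) {
    n <- 15 + 5 * rep
    X <- matrix(rnorm(n * 4), n) + rnorm(n) # correlated donor columns
    gd <- list(X = X, y = rnorm(n), w = runif(n, 1, 3))
    fast <- chance_likelihood(gd, n_boot = 60, seed = 100 + rep)
    naive <- oracle_chance_likelihood(gd, n_boot = 60, seed = 100 + rep)
    expect_identical(as.numeric(fast), naive)
  }
})

test_that("chance likelihood is 0 for a noiseless perfect fit and deterministic", {
  set.seed(19)
  X <- matrix(rnorm(30 * 4), 30)
  pca <- pca_regressors(X)
  gd <- list(X = X, y = drop(pca$scores[, 1]), w = rep(1, 30))
  cl <- chance_likelihood(gd, n_boot = 200, seed = 7)
  expect_equal(as.numeric(cl), 0)

  gd2 <- list(X = X, y = rnorm(30), w = rep(1, 30))
  cl_a <- chance_likelihood(gd2, n_boot = 150, seed = 42)
  cl_b <- chance_likelihood(gd2, n_boot = 150, seed = 42)
  expect_identical(as.numeric(cl_a), as.numeric(cl_b))
  expect_error(chance_likelihood(gd2, n_boot = 0, seed = 1), "n_boot")
})

test_that("donor autocorrelation is the mean over all unordered pairs", {
  x <- rnorm(12)
  expect_equal(donor_autocorrelation(cbind(x, x, x)), 1)
  expect_equal(donor_autocorrelation(cbind(x, -x)), -1)

  set.seed(20)
  X <- matrix(rnorm(12 * 6), 12)
  pairsum <- 0
  npair <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    pairsum <- pairsum + cor(X[, i], X[, j])
    npair <- npair + 1
  }
  expect_equal(donor_autocorrelation(X), pairsum / npair, tolerance = 1e-12)

  Xz <- cbind(X[, 1:2], rep(2, 12))
  expect_equal(donor_autocorrelation(Xz), cor(X[, 1], X[, 2]))
  expect_true(is.na(donor_autocorrelation(cbind(rep(1, 5), rep(2, 5)))))
})

test_that("gene filter applies strict and inclusive thresholds as stated", {
  res <- data.frame(
    gene = c("A", "B", "C"),
    r2_adjusted = c(0.15, 0.9, 0.9),
    direction = 1,
    chance_likelihood = c(0.0009, 0.001, 0.0005),
    autocorrelation = c(0.2, 0.9, 0.19),
    n_components = 2L, n_units = 30L,
    passes_filter = NA)
  expect_identical(filter_genes(res), "A")
  expect_identical(filter_genes(res[0, ]), character(0))
})

test_that("association statistics are invariant to positive rescaling of y", {
  map <- make_dense_map(c(8, 8, 8), seed = 21)
  sh <- make_shared_aligned(map, n_samples = 70, n_genes = 6, n_coupled = 3,
                            seed = 22)
  al <- sh$aligned
  g <- al$genes[1]
  gd <- gene_data(al, g)
  pca <- pca_regressors(gd$X)
  base <- weighted_regression(gd$y, pca$scores, gd$w, rowMeans(gd$X))
  cl_base <- chance_likelihood(gd, 100, seed = 9)
  gd2 <- gd
  gd2$y <- gd$y * 37.5
  scaled <- weighted_regression(gd2$y, pca$scores, gd2$w, rowMeans(gd2$X))
  cl_scaled <- chance_likelihood(gd2, 100, seed = 9)
  expect_equal(scaled$r2_adjusted, base$r2_adjusted, tolerance = 1e-12)
  expect_identical(scaled$direction, base$direction)
  expect_identical(as.numeric(cl_scaled), as.numeric(cl_base))
})

test_that("gene_association recovers planted genes in shared-coordinate mode", {
  map <- make_dense_map(c(8, 8, 8), seed = 23)
  sh <- make_shared_aligned(map, n_samples = 100, n_genes = 12, n_coupled = 4,
                            beta = 2, noise_sd = 0.5, seed = 24)
  res <- gene_association(sh$aligned, n_boot = 300, seed = 3)
  coupled <- sh$truth$genes$gene_symbol[sh$truth$genes$coupled]
  expect_true(all(coupled %in% filter_genes(res)))
  expect_true(all(res$direction[res$gene %in% coupled] == 1))
})
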