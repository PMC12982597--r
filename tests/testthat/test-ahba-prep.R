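# Builders for tiny donor bundles.
mini_bundle <- function(donor_id, expr, xs = NULL, genes = NULL) {
  np <- nrow(expr); ns <- ncol(expr)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("p%02d", seq_len(np))
  if (is.null(colnames(expr))) {
    colnames(expr) <- sprintf("%s_s%02d", donor_id, seq_len(ns))
  }
  if (is.null(genes)) genes <- rep("G1", np)
  if (is.null(xs)) xs <- rep(-5, ns)
  donor_bundle(donor_id, expr,
               data.frame(probe_id = rownames(expr), gene_symbol = genes,
                          stringsAsFactors = FALSE),
               data.frame(sample_id = colnames(expr), x = xs,
                          y = seq_len(ns), z = 0, stringsAsFactors = FALSE))
}

test_that("probe selection keeps the least-skewed probe, ties to smallest id", {
  a <- c(-2, -1, 0, 1, 2)
  expr <- rbind(pA = a, pB = exp(a))
  b1 <- mini_bundle("d1", expr, genes = c("G1", "G1"))
  sel <- select_representative_probe(list(b1))
  expect_identical(unname(sel["G1"]), "pA")
  # oracle check of the skewness ranking itself
  expect_lt(abs(oracle_skewness(a)), abs(oracle_skewness(exp(a))))
  expect_equal(e1071::skewness(exp(a), type = 2), oracle_skewness(exp(a)),
               tolerance = 1e-12)

  single <- mini_bundle("d1", matrix(rnorm(6), 1,
                                     dimnames = list("p9", NULL)),
                        genes = "G2")
  expect_identical(unname(select_representative_probe(list(single))["G2"]), "p9")

  tied <- mini_bundle("d1", rbind(p2 = a, p1 = a), genes = c("G3", "G3"))
  expect_identical(unname(select_representative_probe(list(tied))["G3"]), "p1")

  expect_error(select_representative_probe(list(b1), "NOPE"), "NOPE")
})

test_that("probe selection pools donors and ignores donor/sample order", {
  set.seed(6)
  e1 <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(c("pA", "pB", "pC"), NULL))
  e2 <- matrix(rexp(3 * 8), 3, 8, dimnames = list(c("pA", "pB", "pC"), NULL))
  g <- c("G1", "G1", "G1")
  sel <- select_representative_probe(list(mini_bundle("d1", e1, genes = g),
                                          mini_bundle("d2", e2, genes = g)))
  sel_swapped <- select_representative_probe(
    list(mini_bundle("d2", e2, genes = g), mini_bundle("d1", e1, genes = g)))
  sel_shuffled <- select_representative_probe(
    list(mini_bundle("d1", e1[, sample(8)], genes = g),
         mini_bundle("d2", e2[, sample(8)], genes = g)))
  expect_identical(sel, sel_swapped)
  expect_identical(sel, sel_shuffled)
})

test_that("donor normalization yields exact per-gene z-scores", {
  b <- mini_bundle("d1", rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5)),
                   genes = c("g1", "g2"))
  nb <- normalize_donor(b)
  expect_equal(unname(nb$expression["g1", ]), c(-1, 0, 1))
  expect_true(all(is.na(nb$expression["g2", ])))
  expect_identical(attr(nb, "missing_rows"), "g2")
  expect_true(nb$normalized)
  expect_error(normalize_donor(nb), "already normalized")

  set.seed(10)
  big <- mini_bundle("d2", matrix(rnorm(20 * 30), 20, 30) * 5 + 2)
  nbig <- normalize_donor(big)
  expect_true(all(abs(rowMeans(nbig$expression)) < 1e-10))
  expect_true(all(abs(apply(nbig$expression, 1, sd) - 1) < 1e-10))
})

test_that("left-hemisphere restriction keeps strictly negative x only", {
  b <- mini_bundle("d1", matrix(rnorm(2 * 5), 2), xs = c(-10, -10, -10, -10, -10))
  expect_identical(attr(restrict_left_hemisphere(b), "n_retained"), 5L)

  xs <- c(-3, 0, 2, -0.001, 5)
  b2 <- mini_bundle("d1", matrix(rnorm(2 * 5), 2), xs = xs)
  r2 <- restrict_left_hemisphere(b2)
  expect_identical(r2$samples$sample_id,
                   b2$samples$sample_id[xs < 0])
  expect_identical(colnames(r2$expression), b2$samples$sample_id[xs < 0])

  b3 <- mini_bundle("d1", matrix(rnorm(2 * 2), 2), xs = c(0, 4))
  expect_error(restrict_left_hemisphere(b3), "no left-hemisphere")
})

test_that("window averaging matches a brute-force voxel-center oracle", {
  set.seed(12)
  dims <- c(7, 6, 5)
  map <- make_dense_map(dims, voxel_mm = 2, seed = 3)
  # knock out some voxels so masking matters
  drop <- sample(prod(dims), 40)
  map$t[drop] <- NA
  coords <- data.frame(sample_id = sprintf("s%d", 1:25),
                       x = runif(25, -8, 8), y = runif(25, -7, 7),
                       z = runif(25, -6, 6))
  res <- sample_image_at_coords(map, coords, window_mm = 5)

  centers <- lapply(1:3, function(a) {
    map$origin_mm[a] + (seq_len(dims[a]) - 1) * map$voxel_mm[a]
  })
  for (i in 1:25) {
    vals <- c()
    for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
      if (abs(centers[[1]][ix] - coords$x[i]) <= 2.5 + 1e-9 &&
          abs(centers[[2]][iy] - coords$y[i]) <= 2.5 + 1e-9 &&
          abs(centers[[3]][iz] - coords$z[i]) <= 2.5 + 1e-9 &&
          !is.na(map$t[ix, iy, iz])) {
        vals <- c(vals, map$t[ix, iy, iz])
      }
    }
    if (length(vals)) {
      expect_equal(res$raw[i], mean(vals))
      expect_identical(res$n_voxels[i], length(vals))
    } else {
      expect_false(res$retained[i])
    }
  }
  # z-scores across retained samples
  expect_lt(abs(mean(res$z[res$retained])), 1e-10)
  expect_lt(abs(sd(res$z[res$retained]) - 1), 1e-10)
})

test_that("a single-voxel window returns that voxel's value", {
  dims <- c(4, 4, 4)
  map <- make_dense_map(dims, voxel_mm = 2, seed = 5)
  coords <- data.frame(sample_id = c("a", "b"),
                       x = map$origin_mm[1] + c(0, 2),
                       y = map$origin_mm[2], z = map$origin_mm[3])
  res <- sample_image_at_coords(map, coords, window_mm = 2)
  expect_equal(res$raw, c(map$t[1, 1, 1], map$t[2, 1, 1]))
  expect_identical(res$n_voxels, c(1L, 1L))
})

test_that("constant maps flag degenerate z-scoring", {
  dims <- c(4, 4, 4)
  map <- imgtx:::new_contrast_map(array(2.5, dims), array(TRUE, dims), 10L,
                                  voxel_mm = c(2, 2, 2),
                                  origin_mm = imgtx:::default_origin(dims, 2))
  coords <- data.frame(sample_id = c("a", "b", "c"), x = c(-2, 0, 2),
                       y = 0, z = 0)
  res <- sample_image_at_coords(map, coords, 5)
  expect_true(attr(res, "degenerate"))
  expect_true(all(res$raw == 2.5))
  expect_true(all(is.na(res$z)))
})

test_that("window averaging is translation-equivariant", {
  dims <- c(5, 5, 5)
  map <- make_dense_map(dims, voxel_mm = 2, seed = 8)
  coords <- data.frame(sample_id = sprintf("s%d", 1:10),
                       x = runif(10, -4, 4), y = runif(10, -4, 4),
                       z = runif(10, -4, 4))
  res <- sample_image_at_coords(map, coords, 5)
  shift <- c(7.3, -2.1, 0.6)
  map2 <- map
  map2$origin_mm <- map$origin_mm + shift
  coords2 <- coords
  coords2$x <- coords$x + shift[1]
  coords2$y <- coords$y + shift[2]
  coords2$z <- coords$z + shift[3]
  res2 <- sample_image_at_coords(map2, coords2, 5)
  expect_equal(res2$raw, res$raw)
  expect_identical(res2$n_voxels, res$n_voxels)
})

test_that("pipeline order restrict -> select -> normalize is what prepare_donors runs", {
  cfg <- tiny_sim(seed = 31)
  map <- make_dense_map(cfg$grid_shape, voxel_mm = 2, seed = 31)
  atlas <- generate_donor_atlas(cfg, map)
  prep <- prepare_donors(atlas$bundles)
  for (b in prep$bundles) {
    expect_true(all(b$samples$x < 0))
    expect_true(b$normalized)
    ok <- rowSums(is.na(b$expression)) == 0
    expect_true(all(abs(rowMeans(b$expression[ok, , drop = FALSE])) < 1e-10))
  }
  # representative probes selected on the restricted sample set
  restricted <- lapply(atlas$bundles, restrict_left_hemisphere)
  expect_identical(prep$probe_map, select_representative_probe(restricted))
})
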