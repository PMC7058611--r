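# Spin permutations, Moran spectral randomization, Moran's I, p-values.

test_that("sampled rotations are orthogonal, proper, and seed-deterministic", {
  for (seed in 1:20) {
    r <- sample_rotation(seed = seed)
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-12)
    expect_equal(det(r), 1, tolerance = 1e-12)
  }
  expect_identical(sample_rotation(seed = 7), sample_rotation(seed = 7))
  # rotations are approximately uniform: the image of a fixed vector
  # averages toward zero
  imgs <- vapply(1:2000, function(i) sample_rotation(seed = i) %*% c(0, 0, 1),
                 numeric(3))
  expect_lt(sqrt(sum(rowMeans(imgs)^2)), 0.07)
})

test_that("spin surrogates resample the input value multiset and fix the identity", {
  ico <- make_icosphere(2)
  u <- smooth_field(ico, n_smooth = 8, seed = 71)

  # identity rotation is a fixed point of the resampling
  idx <- nearest_neighbor_map(ico$vertices %*% diag(3), ico$vertices)
  expect_identical(u[idx], u)

  ens <- spin_permutation(u, ico, n_perm = 20, seed = 72)
  expect_identical(dim(ens$surrogates), c(20L, length(u)))
  for (i in 1:20) {
    expect_true(all(ens$surrogates[i, ] %in% u))
  }

  # determinism
  ens2 <- spin_permutation(u, ico, n_perm = 20, seed = 72)
  expect_identical(ens$surrogates, ens2$surrogates)

  # masked sources propagate as NA
  mask <- rep(TRUE, length(u))
  mask[1:10] <- FALSE
  ensm <- spin_permutation(scalar_map(u, mask), ico, n_perm = 5, seed = 73)
  expect_true(anyNA(ensm$surrogates))
  expect_true(all(ensm$surrogates[!is.na(ensm$surrogates)] %in% u[mask]))

  expect_error(spin_permutation(u[1:10], ico, n_perm = 2),
               class = "gradmap_length_mismatch")
})

test_that("spin surrogates approximately preserve Moran's I of a smooth field", {
  ico <- make_icosphere(3)  # 642 vertices
  w <- build_spatial_weights(ico)
  u <- smooth_field(ico, n_smooth = 10, seed = 74)
  i_obs <- morans_i(u, w)
  ens <- spin_permutation(u, ico, n_perm = 100, seed = 75)
  i_null <- apply(ens$surrogates, 1L, morans_i, weights = w)
  expect_lt(abs(mean(i_null) - i_obs) / abs(i_obs), 0.25)
})

test_that("the Moran basis is orthonormal, centered, and matches dense brute force", {
  tet <- unit_tetrahedron()
  w <- build_spatial_weights(tet, scheme = "binary")
  b <- moran_basis(w)
  m <- b$vectors
  expect_lte(ncol(m), 3)
  expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-10)
  expect_lt(max(abs(colSums(m))), 1e-10)
  # brute-force double centering of the dense matrix
  wd <- as.matrix(w)
  h <- diag(4) - matrix(1 / 4, 4, 4)
  ev <- eigen(h %*% wd %*% h, symmetric = TRUE)
  keep <- abs(ev$values) >= 1e-10 * max(abs(ev$values))
  expect_equal(b$eigenvalues, ev$values[keep], tolerance = 1e-10)

  ico <- make_icosphere(2)
  bi <- moran_basis(build_spatial_weights(ico))
  expect_lte(ncol(bi$vectors), nrow(ico$vertices) - 1)
  expect_lt(max(abs(colSums(bi$vectors))), 1e-8)
})

test_that("MSR singleton surrogates preserve Moran's I, mean, and sd", {
  ico <- make_icosphere(2)
  w <- build_spatial_weights(ico)
  b <- moran_basis(w)
  u <- smooth_field(ico, n_smooth = 6, seed = 81)
  ens <- msr_randomize(u, b, "singleton", n_perm = 25, seed = 82)
  i_obs <- oracle_morans_i(u, w)
  for (i in 1:25) {
    z <- ens$surrogates[i, ]
    expect_equal(mean(z), mean(u), tolerance = 1e-10)
    expect_equal(sd(z), sd(u), tolerance = 1e-10)
    expect_equal(morans_i(z, w), i_obs, tolerance = 1e-8)
  }
  # determinism
  ens2 <- msr_randomize(u, b, "singleton", n_perm = 25, seed = 82)
  expect_identical(ens$surrogates, ens2$surrogates)
})

test_that("the all-positive-sign draw reproduces the input exactly", {
  ico <- make_icosphere(1)
  b <- moran_basis(build_spatial_weights(ico))
  u <- smooth_field(ico, n_smooth = 4, seed = 83)
  r <- as.vector(cor(u, b$vectors))
  z <- gradmap:::msr_reconstruct(mean(u), sd(u), length(u), b$vectors, r)
  expect_lt(max(abs(as.vector(z) - u)), 1e-8)
})

test_that("MSR pair surrogates preserve moments exactly and autocorrelation partially", {
  ico <- make_icosphere(2)
  w <- build_spatial_weights(ico)
  b <- moran_basis(w)
  u <- smooth_field(ico, n_smooth = 6, seed = 84)
  ens <- msr_randomize(u, b, "pair", n_perm = 200, seed = 85)
  i_obs <- morans_i(u, w)
  i_null <- apply(ens$surrogates, 1L, morans_i, weights = w)
  for (i in c(1L, 100L, 200L)) {
    expect_equal(mean(ens$surrogates[i, ]), mean(u), tolerance = 1e-10)
    expect_equal(sd(ens$surrogates[i, ]), sd(u), tolerance = 1e-10)
  }
  # random pairing rotates energy between eigenvalue bands, so Moran's I
  # shrinks toward the spectrum mean: on average about half the observed
  # value for a smooth field, but still far above the permutation null
  # -1/(l-1), and never exactly equal.
  expect_gt(mean(i_null), 0.3 * i_obs)
  expect_lt(mean(i_null), 0.75 * i_obs)
  expect_gt(mean(i_null), 10 / (nrow(ico$vertices) - 1))
  expect_gt(min(abs(i_null - i_obs)), 1e-12)
})

test_that("MSR enforces the singleton capacity bound and rejects constant maps", {
  tet <- unit_tetrahedron()
  b <- moran_basis(build_spatial_weights(tet))
  expect_error(msr_randomize(c(1, 2, 3, 4), b, "singleton", n_perm = 100),
               "2\\^", class = "gradmap_capacity")
  expect_error(msr_randomize(rep(1, 4), b, "singleton", n_perm = 2),
               class = "gradmap_constant_input")
})

test_that("Moran's I matches brute force, ape, and the permutation-null expectation", {
  # path graph, alternating signs
  n <- 8
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    w[i, i + 1] <- 1
    w[i + 1, i] <- 1
  }
  u <- rep(c(1, -1), length.out = n)
  expect_equal(morans_i(u, w), oracle_morans_i(u, w), tolerance = 1e-12)

  ico <- make_icosphere(1)
  wi <- build_spatial_weights(ico)
  u <- smooth_field(ico, n_smooth = 3, seed = 91)
  expect_equal(morans_i(u, wi), oracle_morans_i(u, as.matrix(wi)),
               tolerance = 1e-12)
  # ape cross-check on a regular graph (ape row-normalizes its weights,
  # which is a pure rescaling only when all degrees are equal)
  skip_if_not_installed("ape")
  ic0 <- make_icosphere(0)
  w0 <- build_spatial_weights(ic0, scheme = "binary")
  u0 <- smooth_field(ic0, 2, seed = 95)
  ref <- ape::Moran.I(u0, as.matrix(w0))
  expect_equal(morans_i(u0, w0), ref$observed, tolerance = 1e-10)

  # random relabeling: E[I] = -1/(l-1)
  set.seed(92)
  l <- nrow(ico$vertices)
  i_perm <- replicate(1000, morans_i(u[sample(l)], wi))
  mc_se <- sd(i_perm) / sqrt(1000)
  expect_lt(abs(mean(i_perm) - (-1 / (l - 1))), 3 * mc_se)

  # the leading Moran eigenvector attains the maximal I among basis columns
  b <- moran_basis(wi)
  i_cols <- apply(b$vectors, 2L, morans_i, weights = wi)
  expect_equal(which.max(i_cols), 1L)
})

test_that("empirical p-values follow the (1+k)/(1+n) estimator with tie counting", {
  nulls <- seq_len(1000) / 1000
  expect_equal(empirical_pvalue(2, nulls, "right"), 1 / 1001)
  expect_equal(empirical_pvalue(-1, nulls, "left"), 1 / 1001)
  # observation at the median of symmetric nulls: two-tailed capped at 1
  expect_equal(empirical_pvalue(0.5, nulls, "two"), 1)
  # an exactly tied null counts as at least as extreme
  expect_equal(empirical_pvalue(1, c(0.2, 1, 0.4), "right"), 2 / 4)
  expect_error(empirical_pvalue(1, numeric(0)), class = "gradmap_empty_input")
})

test_that("null_association_test wires observed statistic and p-value together", {
  ico <- make_icosphere(2)
  u <- smooth_field(ico, n_smooth = 8, seed = 93)
  ens <- spin_permutation(u, ico, n_perm = 99, seed = 94)
  res <- null_association_test(u, u, ens, stat = "spearman", tail = "right")
  expect_equal(res$observed, 1)
  expect_equal(res$p, empirical_pvalue(1, res$nulls, "right"))
})
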