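# PCA, Laplacian eigenmaps and diffusion maps.

test_that("PCA recovers rank-1 structure and matches the covariance oracle", {
  x <- cbind(1:10, 2 * (1:10))
  res <- pca_embedding(x, m = 2)
  expect_equal(res$variance_explained[1], 1)
  expect_lt(res$variance_explained[2], 1e-12)

  # oracle: eigendecomposition of the covariance matrix of X_d
  set.seed(21)
  x <- matrix(rnorm(15 * 6), 15, 6)
  res <- pca_embedding(x, m = 4)
  xd <- scale(x, scale = FALSE)
  ev <- eigen(crossprod(xd), symmetric = TRUE)
  scores <- xd %*% ev$vectors[, 1:4]
  # canonicalize the oracle's signs the same way
  for (k in 1:4) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  expect_lt(max(abs(res$gradients - scores)), 1e-10)
  expect_equal(res$lambdas, sqrt(ev$values[1:4]), tolerance = 1e-10)

  # duplicated seeds give duplicated gradient rows
  xdup <- rbind(x, x[3, ])
  resd <- pca_embedding(xdup, m = 2)
  expect_equal(resd$gradients[3, ], resd$gradients[16, ])

  expect_error(pca_embedding(x, m = 15), class = "gradmap_bad_components")
  expect_error(pca_embedding(matrix(5, 4, 4), m = 2),
               class = "gradmap_degenerate_input")
})

test_that("Laplacian eigenmaps reproduce closed forms on small graphs", {
  # path graph P3: generalized eigenvalues {0, 1, 2}, first gradient ~ [1,0,-1]
  a3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  res <- laplacian_eigenmaps(a3, m = 2)
  expect_equal(res$lambdas, c(1, 2), tolerance = 1e-10)
  g1 <- res$gradients[, 1]
  expect_lt(abs(g1[2]), 1e-10)
  expect_equal(g1[1], -g1[3], tolerance = 1e-10)
  expect_gt(abs(g1[1]), 0.1)

  # ring C32: first two gradients span the first Fourier pair
  n <- 32
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ring[i, (i %% n) + 1] <- 1
    ring[(i %% n) + 1, i] <- 1
  }
  res <- laplacian_eigenmaps(ring, m = 2)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cc <- canonical_correlation(res$gradients, cbind(cos(theta), sin(theta)))
  expect_gt(min(cc), 1 - 1e-6)

  # complete graph K4: all non-trivial eigenvalues equal
  k4 <- matrix(1, 4, 4) - diag(4)
  res <- laplacian_eigenmaps(k4, m = 3)
  expect_lt(diff(range(res$lambdas)), 1e-10)
})

test_that("Laplacian eigenmaps reject disconnected graphs with component count", {
  blocks <- matrix(0, 6, 6)
  blocks[1:3, 1:3] <- 1
  blocks[4:6, 4:6] <- 1
  diag(blocks) <- 0
  expect_error(laplacian_eigenmaps(blocks, m = 1), "2 connected components",
               class = "gradmap_disconnected")
  a <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  expect_error(laplacian_eigenmaps(a, m = 1), class = "gradmap_zero_degree")
})

test_that("diffusion operator is row-stochastic and alpha=0 matches the random-walk oracle", {
  set.seed(31)
  x <- matrix(rnorm(12 * 8), 12, 8)
  a <- unclass(compute_affinity(x, "normalized_angle"))

  # row-stochasticity of P_alpha, rebuilt explicitly
  for (alpha in c(0, 0.5, 1)) {
    d <- rowSums(a)
    w <- diag(d^-alpha) %*% a %*% diag(d^-alpha)
    p <- diag(1 / rowSums(w)) %*% w
    expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  }

  # alpha = 0: gradients match a direct eigensolve of D^{-1} A up to the
  # lambda/(1-lambda) scaling and sign convention
  res <- diffusion_maps(a, m = 3, alpha = 0)
  p <- diag(1 / rowSums(a)) %*% a
  ev <- eigen(p)  # non-symmetric oracle route
  ord <- order(Re(ev$values), decreasing = TRUE)
  vals <- Re(ev$values[ord])
  vecs <- Re(ev$vectors[, ord])
  expect_equal(res$lambdas, vals[2:4], tolerance = 1e-8)
  for (k in 1:3) {
    v <- vecs[, k + 1]
    v <- v / sqrt(sum(v^2))
    lam <- vals[k + 1]
    v <- v * lam / (1 - lam)
    g <- res$gradients[, k]
    err <- min(max(abs(g - v)), max(abs(g + v)))
    expect_lt(err, 1e-8)
  }
})

test_that("diffusion time scales gradients by lambda^t", {
  set.seed(32)
  x <- matrix(rnorm(10 * 6), 10, 6)
  a <- compute_affinity(x, "normalized_angle")
  t1 <- diffusion_maps(a, m = 3, t = 1)
  t2 <- diffusion_maps(a, m = 3, t = 2)
  expect_equal(t2$gradients,
               t1$gradients %*% diag(t1$lambdas), tolerance = 1e-10)
})

test_that("two-block affinity separates blocks in the first diffusion gradient", {
  a <- matrix(0.1, 10, 10)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 1
  res <- diffusion_maps(a, m = 1)
  s <- sign(res$gradients[, 1])
  expect_true(all(s[1:5] == s[1]) && all(s[6:10] == -s[1]))
})

test_that("embeddings are invariant to positive rescaling of the affinity", {
  set.seed(33)
  x <- matrix(rnorm(9 * 7), 9, 7)
  a <- unclass(compute_affinity(x, "normalized_angle"))
  le1 <- laplacian_eigenmaps(a, m = 2)
  le2 <- laplacian_eigenmaps(3.7 * a, m = 2)
  expect_equal(le1$gradients, le2$gradients, tolerance = 1e-10)
  dm1 <- diffusion_maps(a, m = 2, t = 1)
  dm2 <- diffusion_maps(3.7 * a, m = 2, t = 1)
  expect_equal(dm1$gradients, dm2$gradients, tolerance = 1e-10)
})

test_that("permuting seeds permutes gradient rows identically", {
  set.seed(34)
  x <- matrix(rnorm(11 * 6), 11, 6)
  a <- unclass(compute_affinity(x, "normalized_angle"))
  perm <- sample(11)
  for (fn in list(function(m) laplacian_eigenmaps(m, 2),
                  function(m) diffusion_maps(m, 2))) {
    g <- fn(a)$gradients
    gp <- fn(a[perm, perm])$gradients
    expect_equal(gp, g[perm, ], tolerance = 1e-8)
  }
})

test_that("fit_gradients composes the workflow deterministically and recovers planted structure", {
  sim <- planted_gradient_connectome(n_seeds = 100, noise_sd = 0.05, seed = 7)
  g1 <- fit_gradients(sim$x, approach = "dm", m = 2)
  g2 <- fit_gradients(sim$x, approach = "dm", m = 2)
  expect_identical(g1, g2)
  expect_gt(abs(cor(g1$gradients[, 1], sim$latent[, 1], method = "spearman")), 0.95)

  # the composition equals its parts
  xs <- sparsify_rows(sim$x, keep_fraction = 0.1)
  manual <- diffusion_maps(compute_affinity(xs, "cosine"), m = 2)
  expect_equal(g1$gradients, manual$gradients)

  # PCA branch embeds the sparsified feature matrix directly
  gp <- fit_gradients(sim$x, approach = "pca", m = 2)
  expect_equal(gp$gradients, pca_embedding(xs, m = 2)$gradients)

  expect_error(fit_gradients(sim$x, m = 100), class = "gradmap_bad_components")
})
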