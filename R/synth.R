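# Deterministic, seedable generators for every input the toolbox
# consumes: planted-manifold connectomes, icospheres, spatially
# autocorrelated surface fields, and multi-subject cohorts.

#' Planted-manifold connectome
#'
#' Generates a symmetric seed-by-seed similarity matrix whose dominant
#' axis of variation is a known latent coordinate: latent positions
#' `theta_i` are sampled uniformly on `[0,1]^d` and
#' `X_ij = exp(-|theta_i - theta_j| / tau)` plus symmetric Gaussian noise,
#' with unit diagonal. The exponential (rather than Gaussian) latent
#' kernel has heavier tails and yields a cleaner single dominant gradient.
#' The true latent is returned alongside, enabling recovery checks of the
#' embedding methods.
#'
#' @param n_seeds number of seed regions (>= 10).
#' @param latent_dim latent dimension, 1 or 2.
#' @param length_scale kernel length scale `tau` (latent-coordinate units).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the output is a pure function of the
#'   arguments.
#' @return a list with `x` (the `n x n` matrix) and `latent`
#'   (`n x latent_dim` true coordinates).
#' @export
planted_gradient_connectome <- function(n_seeds = 100L, latent_dim = 1L,
                                        length_scale = 0.2, noise_sd = 0.05,
                                        seed = 1L) {
  if (n_seeds < 10L) stop_gradmap("bad_input", "n_seeds must be >= 10")
  if (!latent_dim %in% c(1L, 2L)) {
    stop_gradmap("bad_input", "latent_dim must be 1 or 2")
  }
  if (length_scale <= 0) stop_gradmap("bad_input", "length_scale must be > 0")
  if (noise_sd < 0) stop_gradmap("bad_input", "noise_sd must be >= 0")
  with_seed(seed, {
    theta <- matrix(stats::runif(n_seeds * latent_dim), n_seeds, latent_dim)
    x <- exp(-as.matrix(stats::dist(theta)) / length_scale)
    dimnames(x) <- NULL
    if (noise_sd > 0) {
      e <- matrix(stats::rnorm(n_seeds^2, sd = noise_sd), n_seeds, n_seeds)
      x <- x + (e + t(e)) / 2
    }
    diag(x) <- 1
    list(x = x, latent = theta)
  })
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: `10 * 4^s + 2`
#' vertices at `s` subdivisions. A deterministic stand-in for spherical
#' surface registrations of the cortex.
#'
#' @param subdivisions number of 4-fold subdivisions, 0 to 6.
#' @param radius sphere radius.
#' @return a [sphere_mesh()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  if (!is.numeric(subdivisions) || subdivisions != round(subdivisions) ||
      subdivisions < 0 || subdivisions > 6) {
    stop_gradmap("bad_input", "subdivisions must be an integer in [0, 6]")
  }
  if (radius <= 0) stop_gradmap("bad_input", "radius must be > 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)
  )
  for (s in seq_len(subdivisions)) {
    cache <- new.env(parent = emptyenv())
    nextv <- nrow(v)  # 0-based index of the next new vertex
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[i + 1L, ] + v[j + 1L, ]) / 2)
      assign(key, nextv, envir = cache)
      idx <- nextv
      nextv <<- nextv + 1L
      idx
    }
    for (t_ in seq_len(nrow(f))) {
      a <- f[t_, 1]; b <- f[t_, 2]; c_ <- f[t_, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * (t_ - 1L) + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    f <- newf
  }
  v <- v * (radius / sqrt(rowSums(v^2)))
  sphere_mesh(v, f)
}

#' Spatially autocorrelated field on a mesh
#'
#' White Gaussian noise, iteratively replaced by the mean of its 1-ring
#' neighbors `n_smooth` times, then re-standardized to zero mean and unit
#' sd. Moran's I increases with `n_smooth`, emulating smooth cortical
#' maps such as thickness or myelin intensity.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_smooth number of neighbor-averaging sweeps (>= 0).
#' @param seed integer seed.
#' @return a numeric vector, one value per vertex.
#' @export
smooth_field <- function(mesh, n_smooth = 10L, seed = 1L) {
  if (!inherits(mesh, "triangle_mesh")) {
    stop_gradmap("bad_input", "mesh must be a triangle_mesh")
  }
  if (n_smooth < 0) stop_gradmap("bad_input", "n_smooth must be >= 0")
  adj <- build_spatial_weights(mesh, scheme = "binary")
  deg <- Matrix::rowSums(adj)
  z <- with_seed(seed, stats::rnorm(nrow(mesh$vertices)))
  for (i in seq_len(n_smooth)) {
    z <- as.vector(adj %*% z) / deg
  }
  as.vector(scale(z))
}

#' Multi-subject cohort of planted connectomes
#'
#' Each subject's matrix is a shared planted connectome plus
#' subject-specific symmetric noise. Group 2 optionally sees a contracted
#' latent range (its latent coordinates pulled toward the centre by
#' `perturbation`), emulating a group difference in manifold spread for
#' end-to-end template-alignment demonstrations.
#'
#' @param n_subjects subjects per group.
#' @param n_seeds seed regions.
#' @param perturbation contraction of group 2's latent range, in `[0, 1)`;
#'   0 makes the groups exchangeable.
#' @param noise_sd subject-level noise sd.
#' @param length_scale latent kernel length scale.
#' @param seed integer seed.
#' @return a list with `group1` and `group2` (lists of `n x n` matrices)
#'   and `latent` (the shared latent coordinates).
#' @export
two_group_gradients <- function(n_subjects = 10L, n_seeds = 100L,
                                perturbation = 0, noise_sd = 0.05,
                                length_scale = 0.2, seed = 1L) {
  if (n_subjects < 1L) stop_gradmap("bad_input", "n_subjects must be >= 1")
  if (perturbation < 0 || perturbation >= 1) {
    stop_gradmap("bad_input", "perturbation must lie in [0, 1)")
  }
  with_seed(seed, {
    theta <- matrix(stats::runif(n_seeds), n_seeds, 1L)
    theta2 <- 0.5 + (theta - 0.5) * (1 - perturbation)
    base1 <- exp(-as.matrix(stats::dist(theta)) / length_scale)
    base2 <- exp(-as.matrix(stats::dist(theta2)) / length_scale)
    dimnames(base1) <- dimnames(base2) <- NULL
    subject <- function(base) {
      e <- matrix(stats::rnorm(n_seeds^2, sd = noise_sd), n_seeds, n_seeds)
      x <- base + (e + t(e)) / 2
      diag(x) <- 1
      x
    }
    list(
      group1 = lapply(seq_len(n_subjects), function(i) subject(base1)),
      group2 = lapply(seq_len(n_subjects), function(i) subject(base2)),
      latent = theta
    )
  })
}
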