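# Spatial-autocorrelation-preserving null models: spin permutations on
# spherical meshes and Moran spectral randomization (MSR), plus Moran's I
# and empirical p-values.

#' Sample a uniform random rotation
#'
#' Haar-uniform over SO(3) via the quaternion method: four independent
#' standard normals, normalized to a unit quaternion, converted to a
#' rotation matrix (always `det = +1`).
#'
#' @param seed optional integer; when given, the sample is a pure function
#'   of the seed and the caller's RNG state is untouched.
#' @return a 3x3 orthogonal matrix with determinant +1.
#' @export
sample_rotation <- function(seed = NULL) {
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

check_sphere <- function(sphere) {
  if (!inherits(sphere, "sphere_mesh")) {
    # accept a triangle_mesh whose vertices satisfy the sphere invariant
    if (inherits(sphere, "triangle_mesh")) {
      sphere <- sphere_mesh(sphere$vertices, sphere$faces)
    } else {
      stop_gradmap("bad_input", "sphere must be a sphere_mesh")
    }
  }
  sphere
}

#' Spin permutation indices
#'
#' The resampling maps of a spin ensemble: for each of `n_perm` uniform
#' rotations `R_i`, vertex `v` of the rotated sphere `V R_i` is matched to
#' its nearest neighbor on the original sphere `V`. The indices depend
#' only on the sphere and the rotations, not on any data, so one index
#' matrix can generate surrogates for any number of maps on the same
#' sphere.
#'
#' @param sphere a [sphere_mesh()].
#' @param n_perm number of rotations.
#' @param seed optional integer seed for the rotation stream.
#' @return an `n_perm x l` integer matrix; row `i` holds, for each target
#'   vertex, the source vertex (1-based) whose data it receives.
#' @export
spin_indices <- function(sphere, n_perm, seed = NULL) {
  sphere <- check_sphere(sphere)
  v <- sphere$vertices
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      r <- sample_rotation()
      nearest_neighbor_map(v %*% r, v)
    }, integer(nrow(v))))
  })
}

#' Spin permutation null maps
#'
#' Generates autocorrelation-preserving surrogates of a vertex map by
#' rotating the spherical surface registration and resampling by nearest
#' neighbor. Every surrogate value is drawn from the original value
#' multiset; masked source vertices propagate their masked status to the
#' surrogate positions they land on.
#'
#' @param data numeric vector or [scalar_map()], one value per sphere
#'   vertex.
#' @param sphere a [sphere_mesh()].
#' @param n_perm number of surrogate maps.
#' @param seed optional integer seed.
#' @return a `surrogate_ensemble`; `surrogates` is `n_perm x l` with `NA`
#'   where a masked vertex was resampled.
#' @export
spin_permutation <- function(data, sphere, n_perm = 1000L, seed = NULL) {
  sphere <- check_sphere(sphere)
  sm <- as_scalar_map(data)
  l <- nrow(sphere$vertices)
  if (length(sm$values) != l) {
    stop_gradmap("length_mismatch",
                 sprintf("map has %d values but sphere has %d vertices",
                         length(sm$values), l))
  }
  vals <- sm$values
  if (!is.null(sm$mask)) vals[!sm$mask] <- NA_real_
  idx <- spin_indices(sphere, n_perm, seed = seed)
  surr <- matrix(vals[idx], nrow = n_perm, ncol = l)
  new_surrogate_ensemble(surr, "spin", seed)
}

#' Moran eigenvector basis of a spatial weight matrix
#'
#' Doubly centers the spatial weight matrix (`H W H` with
#' `H = I - 11'/l`) and eigendecomposes it; the eigenvectors are the Moran
#' eigenvector maps, each orthogonal to the constant vector. Eigenvectors
#' with (numerically) zero eigenvalue are dropped.
#'
#' @param weights symmetric spatial weight matrix (sparse or dense), e.g.
#'   from [build_spatial_weights()].
#' @param mask optional logical vector; `FALSE` rows/columns are removed
#'   before centering so masked vertices never enter the basis.
#' @return a list of class `moran_basis`: `vectors` (`l_eff x q`,
#'   orthonormal columns), `eigenvalues` (length `q`, descending), `mask`.
#' @export
moran_basis <- function(weights, mask = NULL) {
  w <- as.matrix(weights)
  check_square_symmetric(w, "spatial weight matrix")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != nrow(w)) {
      stop_gradmap("length_mismatch", "mask length must match weight matrix")
    }
    w <- w[mask, mask, drop = FALSE]
  }
  l <- nrow(w)
  if (l < 3L) stop_gradmap("bad_input", "need at least 3 (unmasked) vertices")
  rm_ <- rowMeans(w)
  hwh <- w - rm_ - rep(rm_, each = l) + mean(w)
  eig <- eigen((hwh + t(hwh)) / 2, symmetric = TRUE)
  keep <- abs(eig$values) >= 1e-10 * max(abs(eig$values))
  structure(list(vectors = eig$vectors[, keep, drop = FALSE],
                 eigenvalues = eig$values[keep],
                 mask = mask),
            class = "moran_basis")
}

#' Moran spectral randomization
#'
#' Generates surrogates that preserve the spatial autocorrelation of the
#' input map by redistributing its loadings on the Moran eigenvector maps.
#' Writing `r` for the correlations of the map with each basis column, a
#' surrogate is `z = u_bar + sigma_u * sqrt(l - 1) * M %*% a` where the
#' coefficient vector `a` is a randomization of `r`: the `singleton`
#' procedure flips each sign independently (`a_i = +/- r_i`), preserving
#' Moran's I, mean and sd exactly; the `pair` procedure rotates randomly
#' chosen disjoint pairs through a uniform angle
#' (`a_i = q_ij cos(phi), a_j = q_ij sin(phi)`,
#' `q_ij = sqrt(r_i^2 + r_j^2)`), preserving mean and sd exactly but the
#' autocorrelation only approximately; an odd leftover element falls back
#' to singleton.
#'
#' @param u numeric vector or [scalar_map()] (non-constant).
#' @param basis a [moran_basis()] built from the same surface (and mask).
#' @param procedure `"singleton"` or `"pair"`.
#' @param n_perm number of surrogates; for `singleton` it may not exceed
#'   the `2^(l-1)` unique sign assignments.
#' @param seed optional integer seed.
#' @return a `surrogate_ensemble`; masked positions are `NA`.
#' @export
msr_randomize <- function(u, basis, procedure = c("singleton", "pair"),
                          n_perm = 1000L, seed = NULL) {
  procedure <- match.arg(procedure)
  if (!inherits(basis, "moran_basis")) {
    stop_gradmap("bad_input", "basis must be a moran_basis")
  }
  sm <- as_scalar_map(u)
  full_l <- length(sm$values)
  mask <- basis$mask
  if (!is.null(mask) && length(mask) != full_l) {
    stop_gradmap("length_mismatch", "map length does not match basis mask")
  }
  uu <- if (is.null(mask)) sm$values else sm$values[mask]
  m <- basis$vectors
  if (length(uu) != nrow(m)) {
    stop_gradmap("length_mismatch",
                 sprintf("map has %d (unmasked) values but basis has %d rows",
                         length(uu), nrow(m)))
  }
  l <- length(uu)
  su <- stats::sd(uu)
  if (su == 0) stop_gradmap("constant_input", "constant map: sigma_u = 0")
  if (procedure == "singleton" && log2(n_perm) > (l - 1)) {
    stop_gradmap("capacity",
                 sprintf("n_perm = %d exceeds 2^(l-1), the maximum number of unique singleton randomizations for l = %d",
                         n_perm, l))
  }
  r <- as.vector(stats::cor(uu, m))
  q <- length(r)
  amat <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      if (procedure == "singleton") {
        sample(c(-1, 1), q, replace = TRUE) * r
      } else {
        ord <- sample.int(q)
        a <- r
        npair <- q %/% 2L
        for (k in seq_len(npair)) {
          i1 <- ord[2 * k - 1L]; i2 <- ord[2 * k]
          qij <- sqrt(r[i1]^2 + r[i2]^2)
          phi <- stats::runif(1, 0, 2 * pi)
          a[i1] <- qij * cos(phi)
          a[i2] <- qij * sin(phi)
        }
        if (q %% 2L == 1L) {
          a[ord[q]] <- sample(c(-1, 1), 1) * r[ord[q]]
        }
        a
      }
    }, numeric(q)))
  })
  z <- msr_reconstruct(mean(uu), su, l, m, amat)  # n_perm x l
  if (!is.null(mask)) {
    out <- matrix(NA_real_, n_perm, full_l)
    out[, mask] <- z
    z <- out
  }
  new_surrogate_ensemble(z, paste0("msr_", procedure), seed)
}

# Deterministic MSR reconstruction z = u_bar + sigma_u sqrt(l-1) M a' for
# a matrix of coefficient rows `amat` (n_perm x q). Shared by
# msr_randomize() and by forced-coefficient checks.
msr_reconstruct <- function(u_bar, sigma_u, l, m, amat) {
  if (!is.matrix(amat)) amat <- matrix(amat, nrow = 1L)
  u_bar + sigma_u * sqrt(l - 1) * tcrossprod(amat, m)
}

#' Moran's I spatial autocorrelation coefficient
#'
#' `I = (l / sum(W)) * sum_ij(w_ij (u_i - u_bar)(u_j - u_bar)) /`
#' `sum_i((u_i - u_bar)^2)` over the unmasked vertices.
#'
#' @param u numeric vector or [scalar_map()] (non-constant); `NA` entries
#'   are treated as masked.
#' @param weights symmetric spatial weight matrix.
#' @param mask optional logical vector overriding/extending the map mask.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(u, weights, mask = NULL) {
  if (inherits(u, "scalar_map")) {
    if (is.null(mask)) mask <- u$mask
    u <- u$values
  }
  u <- as.numeric(u)
  keep <- !is.na(u)
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  w <- as.matrix(weights)
  if (length(u) != nrow(w)) {
    stop_gradmap("length_mismatch", "map length does not match weight matrix")
  }
  u <- u[keep]
  w <- w[keep, keep, drop = FALSE]
  l <- length(u)
  uc <- u - mean(u)
  denom <- sum(uc^2)
  if (denom == 0) stop_gradmap("constant_input", "constant map")
  s0 <- sum(w)
  (l / s0) * as.numeric(crossprod(uc, w %*% uc)) / denom
}

#' Empirical permutation p-value
#'
#' `(1 + k) / (1 + n_perm)` where `k` counts null values at least as
#' extreme as the observation (ties count as extreme); the two-tailed
#' value is `2 * min(left, right)` capped at 1.
#'
#' @param observed observed test statistic.
#' @param null_values numeric vector of null statistics (`NA` dropped).
#' @param tail `"two"`, `"left"` or `"right"`.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_values, tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  if (n == 0L) stop_gradmap("empty_input", "no null values")
  p_right <- (1 + sum(null_values >= observed)) / (1 + n)
  p_left <- (1 + sum(null_values <= observed)) / (1 + n)
  switch(tail,
         right = p_right,
         left = p_left,
         two = min(1, 2 * min(p_left, p_right)))
}

#' Test a gradient-map association against a null ensemble
#'
#' Correlates `x` with `y`, then with each surrogate of `y` (the
#' randomized variable should be the non-gradient map), and returns the
#' empirical p-value. Vertices that are `NA` in any surrogate or input are
#' dropped pairwise.
#'
#' @param x,y numeric vectors (e.g. a gradient column and a cortical map).
#' @param nulls a `surrogate_ensemble` of `y`, or an `n_perm x l` matrix.
#' @param stat `"spearman"` or `"pearson"`.
#' @param tail passed to [empirical_pvalue()].
#' @return a list with `observed`, `nulls` (vector of null statistics) and
#'   `p`.
#' @export
null_association_test <- function(x, y, nulls, stat = c("spearman", "pearson"),
                                  tail = c("two", "left", "right")) {
  stat <- match.arg(stat)
  tail <- match.arg(tail)
  surr <- if (inherits(nulls, "surrogate_ensemble")) nulls$surrogates else as.matrix(nulls)
  x <- as.numeric(x); y <- as.numeric(y)
  observed <- stats::cor(x, y, method = stat, use = "pairwise.complete.obs")
  null_stats <- apply(surr, 1L, function(z) {
    stats::cor(x, z, method = stat, use = "pairwise.complete.obs")
  })
  list(observed = observed, nulls = null_stats,
       p = empirical_pvalue(observed, null_stats, tail = tail))
}
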