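# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit double loops, dense algebra) so they share
# no code with the implementation paths they check.

# Two-loop kernel oracles (no clamping, raw values).
oracle_kernel <- function(x, kernel, gamma = 1) {
  n <- nrow(x)
  a <- matrix(NA_real_, n, n)
  cossim <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j && kernel != "gaussian") {
        a[i, j] <- 1  # exact analytic self-similarity
        next
      }
      u <- x[i, ]; v <- x[j, ]
      a[i, j] <- switch(kernel,
        gaussian = exp(-gamma * sum((u - v)^2)),
        cosine = cossim(u, v),
        normalized_angle = 1 - acos(min(1, max(-1, cossim(u, v)))) / pi,
        pearson = cossim(u - mean(u), v - mean(v)),
        spearman = {
          ru <- rank(u); rv <- rank(v)
          cossim(ru - mean(ru), rv - mean(rv))
        })
    }
  }
  a
}

# Brute-force Moran's I by explicit double loop.
oracle_morans_i <- function(u, w) {
  w <- as.matrix(w)
  l <- length(u)
  ub <- mean(u)
  num <- 0
  s0 <- 0
  for (i in seq_len(l)) {
    for (j in seq_len(l)) {
      num <- num + w[i, j] * (u[i] - ub) * (u[j] - ub)
      s0 <- s0 + w[i, j]
    }
  }
  (l / s0) * num / sum((u - ub)^2)
}

# Brute-force O(n^2) nearest-neighbor search with lowest-index ties.
oracle_nearest <- function(query, reference) {
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(rowSums((reference - matrix(query[i, ], nrow(reference), 3,
                                          byrow = TRUE))^2))
    out[i] <- which.min(d)
  }
  out
}

# Random orthogonal matrix (Haar via QR with sign fix).
random_orthogonal <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  q %*% diag(sample(c(-1, 1), m, replace = TRUE), m)
}

# First canonical correlation between the column spaces of two matrices.
canonical_correlation <- function(a, b) {
  qa <- qr.Q(qr(scale(a, scale = FALSE)))
  qb <- qr.Q(qr(scale(b, scale = FALSE)))
  svd(crossprod(qa, qb))$d
}

# Align eigenvector signs of `b` to `a`, column by column (for comparing
# eigendecompositions from different solvers).
match_signs <- function(a, b) {
  for (k in seq_len(ncol(a))) {
    if (sum(a[, k] * b[, k]) < 0) b[, k] <- -b[, k]
  }
  b
}

# Small regular tetrahedron with unit edge length.
unit_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  f <- rbind(c(0, 1, 2), c(0, 1, 3), c(0, 2, 3), c(1, 2, 3))
  triangle_mesh(v, f)
}
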