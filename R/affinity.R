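# Affinity construction: row-wise sparsity thresholding and kernel
# similarity between seed rows.

#' Row-wise sparsity thresholding
#'
#' Keeps, for each row, the `k = ceiling(keep_fraction * p)` largest entries
#' and zeroes the rest, so that only strong (potentially less noisy)
#' connections contribute to the manifold solution. Ties are broken by
#' keeping the lowest column index.
#'
#' Terminology note: `sparsity` is the fraction of entries *zeroed* per row,
#' so `sparsity = 0.9` and `keep_fraction = 0.1` both keep the top 10%.
#' Exactly one of the two may be given.
#'
#' @param x numeric matrix (seeds x features).
#' @param sparsity fraction of entries zeroed per row, in `[0, 1)`.
#' @param keep_fraction fraction of entries kept per row, in `(0, 1]`;
#'   alias for `1 - sparsity`.
#' @return a matrix of the same shape with the smaller entries of each row
#'   set to zero. The input is not modified.
#' @export
#' @examples
#' sparsify_rows(rbind(c(5, 1, 3, 2), c(1, 1, 1, 1)), sparsity = 0.5)
sparsify_rows <- function(x, sparsity = NULL, keep_fraction = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(sparsity) && is.null(keep_fraction)) {
    stop_gradmap("bad_sparsity", "give either sparsity or keep_fraction")
  }
  if (!is.null(sparsity) && !is.null(keep_fraction) &&
      abs(sparsity - (1 - keep_fraction)) > 1e-12) {
    stop_gradmap("bad_sparsity", "sparsity and keep_fraction disagree")
  }
  if (is.null(sparsity)) sparsity <- 1 - keep_fraction
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity < 0 || sparsity >= 1) {
    stop_gradmap("bad_sparsity", "sparsity must lie in [0, 1)")
  }
  if (sparsity == 0) return(x)
  p <- ncol(x)
  k <- as.integer(ceiling((1 - sparsity) * p))
  out <- x
  for (i in seq_len(nrow(x))) {
    keep <- order(-x[i, ])[seq_len(k)]  # stable: ties keep lowest index
    drop <- setdiff(seq_len(p), keep)
    out[i, drop] <- 0
  }
  out
}

#' Kernel specification
#'
#' @param kernel one of `"gaussian"`, `"cosine"`, `"normalized_angle"`,
#'   `"pearson"`, `"spearman"`, `"precomputed"`.
#' @param gamma inverse width of the Gaussian kernel (`A_ij =
#'   exp(-gamma * ||x_i - x_j||^2)`); ignored by other kernels. `NULL`
#'   selects `1 / (2 * median squared pairwise distance)`, a scale-free
#'   heuristic.
#' @param clamp_negative set negative similarities to zero (default `TRUE`),
#'   the standard mitigation for correlation-type kernels whose range is
#'   `[-1, 1]`.
#' @return a list of class `kernel_spec`.
#' @export
kernel_spec <- function(kernel = c("cosine", "normalized_angle", "gaussian",
                                   "pearson", "spearman", "precomputed"),
                        gamma = NULL, clamp_negative = TRUE) {
  kernel <- match.arg(kernel)
  if (!is.null(gamma) && (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)) {
    stop_gradmap("bad_kernel", "gamma must be a positive scalar")
  }
  structure(list(kernel = kernel, gamma = gamma,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "kernel_spec")
}

# Median-squared-distance heuristic for the Gaussian inverse width.
# Deterministic: all pairs when feasible, an evenly strided subsample of
# ~1000 pairs otherwise.
default_gamma <- function(x) {
  n <- nrow(x)
  npairs <- n * (n - 1) / 2
  if (npairs <= 1e6) {
    d2 <- as.vector(stats::dist(x))^2
  } else {
    stride <- max(1L, floor(n / 46L))  # ~46 rows -> ~1035 pairs
    idx <- seq(1L, n, by = stride)
    d2 <- as.vector(stats::dist(x[idx, , drop = FALSE]))^2
  }
  med <- stats::median(d2)
  if (med <= 0) {
    stop_gradmap("degenerate_input",
                 "median pairwise distance is zero; cannot set gaussian gamma")
  }
  1 / (2 * med)
}

row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

#' Compute a kernel affinity matrix
#'
#' Transforms a seed-by-feature matrix into an `n x n` symmetric affinity
#' matrix using one of five kernels: Gaussian
#' `exp(-gamma ||x - y||^2)`, cosine similarity, normalized angle
#' `1 - acos(cossim(x, y)) / pi`, Pearson correlation (cosine similarity of
#' the row-demeaned vectors), or Spearman rank correlation (Pearson on
#' average ranks). `kernel = "precomputed"` requires `x` to be square
#' symmetric and returns it as the affinity directly.
#'
#' @param x numeric matrix (seeds x features), e.g. output of
#'   [sparsify_rows()].
#' @param kernel kernel name, or a [kernel_spec()].
#' @param gamma,clamp_negative see [kernel_spec()].
#' @return an `affinity_matrix`: a symmetric numeric matrix with attributes
#'   `kernel` and `params`.
#' @export
#' @examples
#' x <- matrix(rnorm(30), 6, 5)
#' a <- compute_affinity(x, "normalized_angle")
#' range(a)  # within [0, 1]
compute_affinity <- function(x, kernel = "cosine", gamma = NULL,
                             clamp_negative = TRUE) {
  spec <- if (inherits(kernel, "kernel_spec")) kernel else
    kernel_spec(kernel, gamma = gamma, clamp_negative = clamp_negative)
  x <- as_feature_matrix(x)
  n <- nrow(x)

  if (spec$kernel == "precomputed") {
    if (nrow(x) != ncol(x)) {
      stop_gradmap("not_square", "precomputed affinity must be square")
    }
    check_square_symmetric(x, "precomputed affinity")
    a <- (x + t(x)) / 2
  } else if (spec$kernel == "gaussian") {
    g <- spec$gamma %||% default_gamma(x)
    d2 <- as.matrix(stats::dist(x))^2
    dimnames(d2) <- NULL
    a <- exp(-g * d2)
    spec$gamma <- g
  } else {
    if (spec$kernel %in% c("cosine", "normalized_angle")) {
      norms <- sqrt(rowSums(x^2))
      if (any(norms == 0)) {
        stop_gradmap("zero_norm_row",
                     sprintf("row(s) with zero norm: %s",
                             paste(utils::head(which(norms == 0), 5), collapse = ", ")))
      }
      cs <- tcrossprod(x / norms)
    } else {
      xr <- if (spec$kernel == "spearman") row_ranks(x) else x
      sds <- apply(xr, 1L, stats::sd)
      if (any(sds == 0)) {
        stop_gradmap("zero_variance_row",
                     sprintf("row(s) with zero variance: %s",
                             paste(utils::head(which(sds == 0), 5), collapse = ", ")))
      }
      xc <- xr - rowMeans(xr)
      cs <- tcrossprod(xc / sqrt(rowSums(xc^2)))
    }
    cs <- pmin(pmax(cs, -1), 1)
    a <- if (spec$kernel == "normalized_angle") 1 - acos(cs) / pi else cs
  }

  a <- (a + t(a)) / 2
  if (spec$kernel %in% c("cosine", "normalized_angle", "pearson", "spearman")) {
    diag(a) <- 1
  }
  if (spec$clamp_negative) a <- pmax(a, 0)
  new_affinity(a, spec$kernel,
               list(gamma = spec$gamma, clamp_negative = spec$clamp_negative))
}

# Cross-dataset kernel block: similarity between rows of x and rows of y
# under the same kernel definitions as compute_affinity(). Used by the
# joint-embedding block assembly.
compute_affinity_cross <- function(x, y, spec) {
  if (spec$kernel == "precomputed") {
    stop_gradmap("bad_kernel",
                 "precomputed kernel has no cross-dataset block")
  }
  if (ncol(x) != ncol(y)) {
    stop_gradmap("shape_mismatch",
                 "cross-affinity requires matrices with the same features")
  }
  if (spec$kernel == "gaussian") {
    g <- spec$gamma %||% default_gamma(rbind(x, y))
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2 <- pmax(d2, 0)
    return(exp(-g * d2))
  }
  prep <- function(m) {
    if (spec$kernel == "spearman") m <- row_ranks(m)
    if (spec$kernel %in% c("pearson", "spearman")) m <- m - rowMeans(m)
    norms <- sqrt(rowSums(m^2))
    if (any(norms == 0)) {
      stop_gradmap("zero_norm_row", "row with zero norm/variance in cross-affinity")
    }
    m / norms
  }
  cs <- pmin(pmax(tcrossprod(prep(x), prep(y)), -1), 1)
  a <- if (spec$kernel == "normalized_angle") 1 - acos(cs) / pi else cs
  if (spec$clamp_negative) a <- pmax(a, 0)
  a
}
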