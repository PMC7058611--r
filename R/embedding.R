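# Dimensionality reduction: PCA (SVD), Laplacian eigenmaps (generalized
# eigenproblem L g = lambda D g) and diffusion maps (anisotropic operator
# P_alpha = D_alpha^{-1} W_alpha with W_alpha = D^{-alpha} A D^{-alpha}).
#
# All solvers are dense symmetric eigendecompositions; eigenvector signs
# are canonicalized (largest-magnitude entry positive) so results are
# deterministic and invariant to the solver's arbitrary sign choice.

check_connected <- function(a) {
  deg <- rowSums(a) - diag(a)
  if (any(deg == 0)) {
    stop_gradmap("zero_degree",
                 sprintf("node(s) with zero degree: %s",
                         paste(utils::head(which(deg == 0), 5), collapse = ", ")))
  }
  off <- a
  diag(off) <- 0
  ncomp <- count_components(off)
  if (ncomp > 1L) {
    stop_gradmap("disconnected",
                 sprintf("affinity graph has %d connected components; embedding requires a connected graph",
                         ncomp))
  }
  invisible(TRUE)
}

check_m <- function(m, n) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop_gradmap("bad_components", "m must be a positive integer")
  }
  if (m > n - 1L) {
    stop_gradmap("bad_components",
                 sprintf("m = %d too large: at most n - 1 = %d gradients", m, n - 1L))
  }
  as.integer(m)
}

#' Principal component analysis embedding
#'
#' Column-demeans the input and factorizes it by singular value
#' decomposition `X_d = U S V'`; the gradients are the scores `U S` of the
#' first `m` components.
#'
#' @param x numeric matrix (seeds x features).
#' @param m number of gradients (components) to return.
#' @return a `gradient_result` with `lambdas` the singular values and
#'   `variance_explained` the per-component fractions `s_k^2 / sum(s^2)`.
#' @export
pca_embedding <- function(x, m = 2L) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  m <- check_m(m, n)
  if (m > ncol(x)) {
    stop_gradmap("bad_components",
                 sprintf("m = %d exceeds the number of features p = %d", m, ncol(x)))
  }
  xd <- sweep(x, 2L, colMeans(x))
  sv <- svd(xd)
  if (max(sv$d) <= 0 || all(sv$d < 1e-12 * max(1, max(abs(x))))) {
    stop_gradmap("degenerate_input", "constant matrix: all singular values are zero")
  }
  u <- canonicalize_signs(sv$u[, seq_len(m), drop = FALSE])
  g <- u %*% diag(sv$d[seq_len(m)], m)
  new_gradient_result(
    gradients = g,
    lambdas = sv$d[seq_len(m)],
    method = "pca",
    params = list(m = m),
    variance_explained = (sv$d[seq_len(m)]^2) / sum(sv$d^2)
  )
}

#' Laplacian eigenmaps embedding
#'
#' Builds the graph Laplacian `L = D - A` of a symmetric non-negative
#' affinity and solves the generalized eigenvalue problem
#' `L g = lambda D g`. The embedding uses the eigenvectors of the `m`
#' smallest eigenvalues, excluding the trivial constant eigenvector at
#' `lambda = 0`; eigenvalues are returned in ascending order. Eigenvectors
#' are normalized to `g' D g = 1`.
#'
#' @param a symmetric non-negative affinity matrix (the graph must be
#'   connected).
#' @param m number of gradients.
#' @param normalized if `TRUE`, embed with the symmetric normalized
#'   Laplacian `L_S = D^{-1/2} L D^{-1/2}` (ordinary eigenproblem) instead
#'   of the generalized problem.
#' @return a `gradient_result` with ascending `lambdas`.
#' @export
laplacian_eigenmaps <- function(a, m = 2L, normalized = FALSE) {
  a <- as_affinity_values(a)
  n <- nrow(a)
  m <- check_m(m, n)
  check_connected(a)
  d <- rowSums(a)
  dis <- 1 / sqrt(d)
  # D^{-1/2} L D^{-1/2} = I - D^{-1/2} A D^{-1/2}; shares eigenvalues with
  # the generalized problem, eigenvectors map back via g = D^{-1/2} y.
  s <- diag(n) - (dis * a) * rep(dis, each = n)
  s <- (s + t(s)) / 2
  eig <- eigen(s, symmetric = TRUE)
  ord <- rev(seq_len(n))  # ascending eigenvalues
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  sel <- seq.int(2L, m + 1L)
  g <- if (normalized) {
    vecs[, sel, drop = FALSE]
  } else {
    dis * vecs[, sel, drop = FALSE]
  }
  # unit-norm columns: invariant to positive rescaling of the affinity
  g <- g / rep(sqrt(colSums(g^2)), each = n)
  g <- canonicalize_signs(g)
  new_gradient_result(
    gradients = g,
    lambdas = pmax(vals[sel], 0),
    method = "le",
    params = list(m = m, normalized = normalized)
  )
}

#' Diffusion map embedding
#'
#' Normalizes the affinity with the anisotropic diffusion parameter
#' `alpha`, `W_alpha = D^-alpha A D^-alpha`, and embeds with the
#' eigenvectors of the row-stochastic diffusion operator
#' `P_alpha = D_alpha^{-1} W_alpha`. The stationary eigenvector (largest
#' eigenvalue, `lambda = 1`) is omitted; the k-th gradient is
#' `lambda_k^t g_k`. At `alpha = 0` the operator reduces to the random-walk
#' normalization `D^{-1} A`; `alpha = 0.5` (the default, standard in the
#' gradient literature) approximates Fokker-Planck diffusion and `alpha = 1`
#' the Laplace-Beltrami operator.
#'
#' @param a symmetric non-negative affinity matrix (connected graph).
#' @param m number of gradients.
#' @param alpha anisotropic diffusion parameter in `[0, 1]`.
#' @param t diffusion time; `t = 0` selects the automatic multiscale
#'   scaling `lambda / (1 - lambda)`.
#' @return a `gradient_result` with `lambdas` the operator eigenvalues in
#'   descending order (stationary eigenvalue excluded).
#' @export
diffusion_maps <- function(a, m = 2L, alpha = 0.5, t = 0) {
  a <- as_affinity_values(a)
  n <- nrow(a)
  m <- check_m(m, n)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_gradmap("bad_alpha", "alpha must lie in [0, 1]")
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop_gradmap("bad_alpha", "diffusion time t must be >= 0")
  }
  check_connected(a)
  d <- rowSums(a)
  w <- if (alpha == 0) a else {
    da <- d^(-alpha)
    (da * a) * rep(da, each = n)
  }
  dw <- rowSums(w)
  # symmetric conjugate S = D_a^{-1/2} W D_a^{-1/2}; eigenvectors of
  # P = D_a^{-1} W are phi = D_a^{-1/2} psi.
  dis <- 1 / sqrt(dw)
  s <- (dis * w) * rep(dis, each = n)
  s <- (s + t(s)) / 2
  eig <- eigen(s, symmetric = TRUE)
  vals <- eig$values          # descending
  phi <- dis * eig$vectors
  phi <- phi / rep(sqrt(colSums(phi^2)), each = n)  # unit-norm columns
  sel <- seq.int(2L, m + 1L)  # drop stationary eigenvector
  lambdas <- vals[sel]
  g <- canonicalize_signs(phi[, sel, drop = FALSE])
  scale_fac <- if (t == 0) lambdas / (1 - lambdas) else lambdas^t
  g <- g * rep(scale_fac, each = n)
  new_gradient_result(
    gradients = g,
    lambdas = lambdas,
    method = "dm",
    params = list(m = m, alpha = alpha, t = t)
  )
}

#' Fit gradients from a feature matrix
#'
#' The one-call workflow: row-wise sparsification, kernel affinity, and
#' embedding. The PCA branch operates on the (sparsified) feature matrix
#' itself; Laplacian eigenmaps and diffusion maps operate on the kernel
#' affinity.
#'
#' @param x numeric matrix (seeds x features), or a square symmetric
#'   matrix with `kernel = "precomputed"`.
#' @param approach `"dm"` (diffusion maps), `"le"` (Laplacian eigenmaps)
#'   or `"pca"`.
#' @param m number of gradients.
#' @param kernel kernel name or [kernel_spec()]; see [compute_affinity()].
#' @param sparsity,keep_fraction row-wise threshold passed to
#'   [sparsify_rows()]; the default keeps the top 10% of each row. Set
#'   `sparsity = 0` to disable.
#' @param gamma,clamp_negative kernel parameters, see [kernel_spec()].
#' @param alpha,t diffusion-map parameters, see [diffusion_maps()].
#' @param normalized Laplacian-eigenmaps flag, see [laplacian_eigenmaps()].
#' @return a `gradient_result`; `params` records the full recipe.
#' @export
#' @examples
#' sim <- planted_gradient_connectome(n_seeds = 60, seed = 7)
#' g <- fit_gradients(sim$x, approach = "dm", m = 2, kernel = "normalized_angle")
#' cor(g$gradients[, 1], sim$latent[, 1], method = "spearman")
fit_gradients <- function(x, approach = c("dm", "le", "pca"), m = 2L,
                          kernel = "cosine",
                          sparsity = NULL, keep_fraction = NULL,
                          gamma = NULL, clamp_negative = TRUE,
                          alpha = 0.5, t = 0, normalized = FALSE) {
  approach <- match.arg(approach)
  spec <- if (inherits(kernel, "kernel_spec")) kernel else
    kernel_spec(kernel, gamma = gamma, clamp_negative = clamp_negative)
  x <- as_feature_matrix(x)
  if (is.null(sparsity) && is.null(keep_fraction)) keep_fraction <- 0.1
  xs <- sparsify_rows(x, sparsity = sparsity, keep_fraction = keep_fraction)
  res <- if (approach == "pca") {
    pca_embedding(xs, m = m)
  } else {
    a <- compute_affinity(xs, spec)
    if (approach == "le") {
      laplacian_eigenmaps(a, m = m, normalized = normalized)
    } else {
      diffusion_maps(a, m = m, alpha = alpha, t = t)
    }
  }
  res$params <- c(res$params,
                  list(kernel = spec$kernel, gamma = spec$gamma,
                       clamp_negative = spec$clamp_negative,
                       sparsity = if (is.null(sparsity)) 1 - keep_fraction else sparsity))
  res
}
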