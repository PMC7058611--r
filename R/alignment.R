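# Alignment of gradient sets: pairwise orthogonal Procrustes, generalized
# (iterative) Procrustes, and joint spectral embedding of a block affinity.

#' Procrustes alignment of one gradient set to another
#'
#' Finds the orthogonal transform `psi` (reflections allowed: sign flips
#' are exactly the eigenvector ambiguity alignment is meant to fix)
#' minimizing the Frobenius distance between `psi(source)` and `target`.
#' Optional centering and isotropic scaling are applied before the
#' rotation is estimated.
#'
#' @param source,target `gradient_result` objects or `n x m` matrices of
#'   identical shape.
#' @param center subtract column means first.
#' @param scale normalize to unit Frobenius norm and estimate an optimal
#'   isotropic scale.
#' @return a list with `aligned` (same type as `source`), `transform`
#'   (list with `rotation`, and `scale`/`translation` when requested) and
#'   `residual` (Frobenius distance after alignment).
#' @export
procrustes_align <- function(source, target, center = FALSE, scale = FALSE) {
  gs <- gradient_values(source)
  gt <- gradient_values(target)
  if (!all(dim(gs) == dim(gt))) {
    stop_gradmap("shape_mismatch",
                 sprintf("source is %dx%d but target is %dx%d",
                         nrow(gs), ncol(gs), nrow(gt), ncol(gt)))
  }
  mu_s <- if (center) colMeans(gs) else rep(0, ncol(gs))
  mu_t <- if (center) colMeans(gt) else rep(0, ncol(gt))
  s0 <- sweep(gs, 2L, mu_s)
  t0 <- sweep(gt, 2L, mu_t)
  ns <- sqrt(sum(s0^2))
  nt <- sqrt(sum(t0^2))
  if (scale) {
    s0 <- s0 / ns
    t0 <- t0 / nt
  }
  m <- crossprod(s0, t0)
  sv <- svd(m)
  if (center && scale && min(sv$d) < 1e-12 * max(sv$d, 1e-300)) {
    warning("rank-deficient cross-covariance; Procrustes rotation is not unique")
  }
  rot <- sv$u %*% t(sv$v)
  aligned <- s0 %*% rot
  transform <- list(rotation = rot)
  if (scale) {
    sc <- sum(sv$d) / sum(s0^2)  # optimal isotropic scale for normalized s0
    aligned <- aligned * sc * nt
    transform$scale <- sc * nt / ns
  }
  if (center) {
    aligned <- sweep(aligned, 2L, mu_t, "+")
    transform$translation <- mu_t
  }
  residual <- sqrt(sum((aligned - gt)^2))
  out <- source
  if (inherits(source, "gradient_result")) {
    out$gradients <- aligned
  } else {
    out <- aligned
  }
  list(aligned = out, transform = transform, residual = residual)
}

#' Generalized Procrustes alignment
#'
#' Iteratively aligns every gradient set to a reference and updates the
#' reference as the mean of the aligned sets. When a `reference` is given
#' it seeds the first iteration (template mode, e.g. aligning individual
#' subjects to a group-level template). The total disparity
#' `sum_k ||psi(G_k) - G_R||_F^2` is non-increasing over iterations;
#' iteration stops at `n_iter` or when the relative disparity change drops
#' below `tol`.
#'
#' @param glist list of `gradient_result` objects or matrices, all of the
#'   same shape.
#' @param n_iter maximum number of iterations.
#' @param reference optional template seeding the first iteration.
#' @param tol relative disparity-change convergence threshold.
#' @param center,scale passed to [procrustes_align()].
#' @return a list with `aligned` (list, same types as input), `reference`
#'   (the final mean template) and `disparity` (per-iteration vector).
#' @export
generalized_procrustes <- function(glist, n_iter = 10L, reference = NULL,
                                   tol = 1e-10, center = FALSE, scale = FALSE) {
  if (!is.list(glist) || length(glist) == 0L) {
    stop_gradmap("empty_input", "glist must be a non-empty list")
  }
  mats <- lapply(glist, gradient_values)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_gradmap("shape_mismatch", "all gradient sets must share one shape")
  }
  ref <- if (is.null(reference)) mats[[1]] else gradient_values(reference)
  if (!all(dim(ref) == dim(mats[[1]]))) {
    stop_gradmap("shape_mismatch", "reference shape does not match inputs")
  }
  disparity <- numeric(0)
  aligned <- mats
  for (it in seq_len(n_iter)) {
    fits <- lapply(mats, procrustes_align, target = ref,
                   center = center, scale = scale)
    aligned <- lapply(fits, `[[`, "aligned")
    ref_new <- Reduce(`+`, aligned) / length(aligned)
    disp <- sum(vapply(aligned, function(g) sum((g - ref_new)^2), numeric(1)))
    disparity <- c(disparity, disp)
    ref <- ref_new
    scale_ref <- max(sum(ref^2), 1e-300)
    if (disp <= tol * scale_ref) break
    if (it > 1L &&
        abs(disparity[it - 1L] - disp) < tol * max(disparity[it - 1L], scale_ref)) {
      break
    }
  }
  out <- Map(function(orig, g) {
    if (inherits(orig, "gradient_result")) {
      orig$gradients <- g
      orig
    } else g
  }, glist, aligned)
  list(aligned = out, reference = ref, disparity = disparity)
}

#' Joint spectral embedding of multiple datasets
#'
#' Embeds several datasets simultaneously through the joint affinity
#' matrix: within-dataset blocks `A_k = kernel(X_k, X_k)` on the diagonal
#' and cross-dataset blocks `A_ij = kernel(X_i rows vs X_j rows)` off the
#' diagonal, all built with the same kernel (hence all inputs must share
#' the same features). The joint matrix is embedded with Laplacian
#' eigenmaps or diffusion maps and sliced back into per-dataset gradient
#' sets living in one shared coordinate system.
#'
#' @param xlist list of numeric matrices (`n_k x p`, common `p`).
#' @param approach `"dm"` or `"le"` (joint alignment is spectral-only).
#' @param m number of gradients.
#' @param kernel kernel name or [kernel_spec()] (not `"precomputed"`).
#' @param sparsity,keep_fraction row-wise threshold applied to each input;
#'   default keeps the top 10%.
#' @param gamma,clamp_negative,alpha,t,normalized see [fit_gradients()].
#' @return a list of `gradient_result` objects, one per dataset, sharing
#'   the joint spectrum in `lambdas`.
#' @export
joint_embedding <- function(xlist, approach = c("dm", "le"), m = 2L,
                            kernel = "cosine",
                            sparsity = NULL, keep_fraction = NULL,
                            gamma = NULL, clamp_negative = TRUE,
                            alpha = 0.5, t = 0, normalized = FALSE) {
  approach <- match.arg(approach)
  if (!is.list(xlist) || length(xlist) == 0L) {
    stop_gradmap("empty_input", "xlist must be a non-empty list")
  }
  spec <- if (inherits(kernel, "kernel_spec")) kernel else
    kernel_spec(kernel, gamma = gamma, clamp_negative = clamp_negative)
  if (spec$kernel == "precomputed") {
    stop_gradmap("bad_kernel", "joint embedding requires a pairwise kernel")
  }
  xlist <- lapply(xlist, as_feature_matrix)
  ps <- vapply(xlist, ncol, integer(1))
  if (any(ps != ps[1])) {
    stop_gradmap("shape_mismatch",
                 "joint embedding can only be used if the input matrices have the same features (equal p)")
  }
  if (is.null(sparsity) && is.null(keep_fraction)) keep_fraction <- 0.1
  xs <- lapply(xlist, sparsify_rows, sparsity = sparsity,
               keep_fraction = keep_fraction)
  if (spec$kernel == "gaussian" && is.null(spec$gamma)) {
    spec$gamma <- default_gamma(do.call(rbind, xs))
  }
  sizes <- vapply(xs, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes))
  j <- assemble_joint_affinity(xs, spec)
  if (min(j) < 0) {
    stop_gradmap("negative_affinity",
                 "joint affinity has negative entries; enable clamp_negative or use a non-negative kernel")
  }
  res <- if (approach == "le") {
    laplacian_eigenmaps(j, m = m, normalized = normalized)
  } else {
    diffusion_maps(j, m = m, alpha = alpha, t = t)
  }
  lapply(seq_along(xs), function(i) {
    ri <- offsets[i] + seq_len(sizes[i])
    new_gradient_result(
      gradients = res$gradients[ri, , drop = FALSE],
      lambdas = res$lambdas,
      method = res$method,
      params = c(res$params, list(joint = TRUE, dataset = i, sizes = sizes,
                                  kernel = spec$kernel))
    )
  })
}

# Block assembly of the joint affinity matrix: within-dataset kernels on
# the diagonal, cross-dataset kernel blocks off the diagonal. Inputs are
# assumed already sparsified; a Gaussian spec must carry a fixed gamma so
# every block shares one width.
assemble_joint_affinity <- function(xs, spec) {
  sizes <- vapply(xs, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes))
  n_tot <- sum(sizes)
  nsets <- length(xs)
  j <- matrix(0, n_tot, n_tot)
  for (i in seq_len(nsets)) {
    ri <- offsets[i] + seq_len(sizes[i])
    j[ri, ri] <- as_affinity_values(compute_affinity(xs[[i]], spec),
                                    require_nonnegative = FALSE)
    if (i < nsets) {
      for (k in seq.int(i + 1L, nsets)) {
        rk <- offsets[k] + seq_len(sizes[k])
        blk <- compute_affinity_cross(xs[[i]], xs[[k]], spec)
        j[ri, rk] <- blk
        j[rk, ri] <- t(blk)
      }
    }
  }
  j
}
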