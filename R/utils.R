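# Internal helpers: classed errors, RNG scoping, eigenvector sign
# canonicalization, union-find connectivity.

stop_gradmap <- function(subclass, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("gradmap_", subclass), "gradmap_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

usage_error <- function(message) {
  stop_gradmap("usage", message)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Flip eigenvector columns so that the entry of largest absolute value is
# positive; which.max() resolves ties at the lowest index.
canonicalize_signs <- function(v) {
  if (!is.matrix(v)) v <- as.matrix(v)
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  v
}

# Number of connected components of the undirected graph whose edges are the
# nonzero off-diagonal entries of `a` (dense or Matrix sparse).
count_components <- function(a) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (inherits(a, "sparseMatrix")) {
    idx <- Matrix::which(a != 0, arr.ind = TRUE)
  } else {
    idx <- which(a != 0, arr.ind = TRUE)
  }
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  for (e in seq_len(nrow(idx))) {
    ri <- find(idx[e, 1])
    rj <- find(idx[e, 2])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

check_square_symmetric <- function(a, what = "matrix", rtol = 1e-10) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop_gradmap("not_square", sprintf("%s must be square", what))
  }
  scale <- max(abs(a))
  if (scale == 0) scale <- 1
  if (max(abs(a - t(a))) > rtol * scale) {
    stop_gradmap("not_symmetric", sprintf("%s must be symmetric", what))
  }
  invisible(a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
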