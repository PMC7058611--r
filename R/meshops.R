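# Mesh-derived structures: 1-ring adjacency, inverse-distance spatial
# weights, nearest-neighbor queries on spheres, parcel reduce/expand.

# Unique undirected 1-ring edges of a mesh, as a 2-column matrix of
# 1-based vertex indices with row < col.
mesh_edges <- function(mesh) {
  f <- mesh$faces + 1L  # to R indexing
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Build a spatial weight matrix from a mesh
#'
#' Weights connect each vertex to its immediate (1-ring) neighborhood:
#' `w_ij = 1 / ||v_i - v_j||` for edge-connected pairs under the
#' `inverse_distance` scheme, or `w_ij = 1` under `binary`. The matrix is
#' symmetric with a zero diagonal by construction; it is the spatial
#' weight matrix consumed by Moran spectral randomization and
#' [morans_i()].
#'
#' @param mesh a [triangle_mesh()].
#' @param scheme `"inverse_distance"` or `"binary"`.
#' @return a sparse symmetric `dgCMatrix` (`Matrix` package) with
#'   attribute `scheme`.
#' @export
build_spatial_weights <- function(mesh, scheme = c("inverse_distance", "binary")) {
  scheme <- match.arg(scheme)
  if (!inherits(mesh, "triangle_mesh")) {
    stop_gradmap("bad_input", "mesh must be a triangle_mesh")
  }
  e <- mesh_edges(mesh)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  if (any(d < 1e-12)) {
    stop_gradmap("coincident_vertices",
                 "neighboring vertices coincide (zero edge length)")
  }
  w <- if (scheme == "inverse_distance") 1 / d else rep(1, length(d))
  l <- nrow(mesh$vertices)
  m <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(w, w), dims = c(l, l))
  attr(m, "scheme") <- scheme
  m
}

#' Nearest-neighbor map between two point sets
#'
#' For each query point, the index (1-based, R convention) of the
#' Euclidean-nearest reference point; ties resolve to the lowest index.
#' This is the resampling step of the spin permutation: rotated sphere
#' vertices are assigned the data of their nearest neighbor on the
#' original sphere.
#'
#' @param query,reference numeric matrices with 3 columns.
#' @return integer vector of length `nrow(query)`.
#' @export
nearest_neighbor_map <- function(query, reference) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0L) {
    stop_gradmap("empty_input", "reference point set is empty")
  }
  d2 <- outer(rowSums(query^2), rowSums(reference^2), "+") -
    2 * tcrossprod(query, reference)
  max.col(-d2, ties.method = "first")
}

#' Reduce vertex data to parcel level
#'
#' @param x numeric vector (length `l`) or matrix (`l x k`) of vertex data.
#' @param labels integer label vector of length `l`, or
#'   [parcellation_labels()].
#' @param stat `"mean"` or `"median"`.
#' @param background_label label excluded from every parcel.
#' @return a vector (or matrix) of per-parcel statistics, parcels ordered
#'   by ascending label and carried in `names`/`rownames`.
#' @export
reduce_by_labels <- function(x, labels, stat = c("mean", "median"),
                             background_label = 0L) {
  stat <- match.arg(stat)
  if (inherits(labels, "parcellation_labels")) {
    background_label <- labels$background_label
    labels <- labels$labels
  }
  vec <- !is.matrix(x)
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) {
    stop_gradmap("length_mismatch",
                 sprintf("data has %d rows but labels has length %d",
                         nrow(x), length(labels)))
  }
  parcels <- sort(setdiff(unique(labels), background_label))
  if (length(parcels) == 0L) {
    stop_gradmap("bad_input", "no non-background parcels")
  }
  fn <- if (stat == "mean") mean else stats::median
  out <- t(vapply(parcels, function(p) {
    apply(x[labels == p, , drop = FALSE], 2L, fn)
  }, numeric(ncol(x))))
  if (ncol(x) == 1L) out <- matrix(out, ncol = 1L)
  rownames(out) <- parcels
  if (vec) stats::setNames(out[, 1L], parcels) else out
}

#' Expand parcel-level values back to vertices
#'
#' Each vertex receives the value of its parcel; background vertices get
#' `NA` and are flagged in the returned [scalar_map()] mask.
#'
#' @param parcel_values named vector (names = parcel labels, as returned
#'   by [reduce_by_labels()]) or unnamed vector matching the ascending
#'   parcel labels.
#' @inheritParams reduce_by_labels
#' @return a [scalar_map()] of length `length(labels)` whose mask marks
#'   background vertices as excluded; masked values are 0 placeholders.
#' @export
expand_labels <- function(parcel_values, labels, background_label = 0L) {
  if (inherits(labels, "parcellation_labels")) {
    background_label <- labels$background_label
    labels <- labels$labels
  }
  parcels <- sort(setdiff(unique(labels), background_label))
  vals <- as.numeric(parcel_values)
  nms <- names(parcel_values)
  if (!is.null(nms)) {
    if (!all(as.character(parcels) %in% nms)) {
      stop_gradmap("unknown_parcel",
                   "parcel label present in `labels` but missing from parcel_values")
    }
    vals <- vals[match(as.character(parcels), nms)]
  } else if (length(vals) != length(parcels)) {
    stop_gradmap("unknown_parcel",
                 sprintf("%d parcel values for %d parcels",
                         length(vals), length(parcels)))
  }
  out <- numeric(length(labels))
  mask <- labels != background_label
  out[mask] <- vals[match(labels[mask], parcels)]
  scalar_map(out, mask = mask)
}
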