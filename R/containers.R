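# Core data containers. Design follows the lightweight S3 style of ape and
# vegan: matrices stay matrices, structured results are plain lists with a
# class attribute and a print method.

#' Validate a seed-by-feature matrix
#'
#' Coerces `x` to a numeric matrix and checks the contract shared by all
#' downstream operations: finite entries and at least two rows and columns.
#'
#' @param x numeric matrix or data frame, one row per seed region and one
#'   column per feature (e.g., connectivity with a target region).
#' @return the validated numeric matrix.
#' @export
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_gradmap("bad_input", "feature matrix must be a numeric matrix")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_gradmap("bad_input", "feature matrix needs at least 2 rows and 2 columns")
  }
  if (!all(is.finite(x))) {
    stop_gradmap("nonfinite", "feature matrix contains NA/NaN/Inf entries")
  }
  x
}

new_affinity <- function(values, kernel, params) {
  structure(values, kernel = kernel, params = params,
            class = c("affinity_matrix", "matrix", "array"))
}

# Accept an affinity_matrix or any symmetric numeric matrix.
as_affinity_values <- function(a, require_nonnegative = TRUE) {
  if (inherits(a, "affinity_matrix")) {
    attributes(a) <- list(dim = dim(a))
  }
  a <- unclass(a)
  if (!is.matrix(a)) a <- as.matrix(a)
  storage.mode(a) <- "double"
  check_square_symmetric(a, "affinity matrix")
  if (!all(is.finite(a))) {
    stop_gradmap("nonfinite", "affinity matrix contains non-finite entries")
  }
  if (require_nonnegative && min(a) < 0) {
    stop_gradmap("negative_affinity",
                 "affinity matrix has negative entries; use clamp_negative = TRUE or a non-negative kernel")
  }
  (a + t(a)) / 2
}

#' Triangle surface mesh
#'
#' @param vertices numeric matrix `l x 3` of vertex coordinates.
#' @param faces integer matrix `t x 3` of 0-based vertex indices (the
#'   package-wide convention; file readers and writers convert at the I/O
#'   boundary).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) {
    stop_gradmap("bad_mesh", "vertices must have 3 columns")
  }
  if (nrow(vertices) < 4L) {
    stop_gradmap("bad_mesh", "mesh needs at least 4 vertices")
  }
  if (ncol(faces) != 3L) {
    stop_gradmap("bad_mesh", "faces must have 3 columns")
  }
  if (!all(is.finite(vertices))) {
    stop_gradmap("nonfinite", "mesh vertices contain non-finite values")
  }
  l <- nrow(vertices)
  if (any(faces < 0L) || any(faces >= l)) {
    stop_gradmap("face_index",
                 sprintf("face index out of range [0, %d)", l))
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen)) {
    stop_gradmap("degenerate_face",
                 sprintf("degenerate face(s) with repeated vertex index: %s",
                         paste(utils::head(which(degen), 5), collapse = ", ")))
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' Spherical surface mesh
#'
#' A [triangle_mesh()] whose vertices all lie on a common sphere centred at
#' the origin, as required by spin permutations.
#'
#' @inheritParams triangle_mesh
#' @param rtol relative tolerance on the vertex-norm check.
#' @return an object of class `sphere_mesh` (inherits `triangle_mesh`).
#' @export
sphere_mesh <- function(vertices, faces, rtol = 1e-6) {
  mesh <- triangle_mesh(vertices, faces)
  norms <- sqrt(rowSums(mesh$vertices^2))
  radius <- stats::median(norms)
  if (radius <= 0 || any(abs(norms - radius) > rtol * radius)) {
    stop_gradmap("not_spherical",
                 "vertices do not lie on a common sphere centred at the origin")
  }
  mesh$radius <- radius
  class(mesh) <- c("sphere_mesh", "triangle_mesh")
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("%s: %d vertices, %d faces\n",
              if (inherits(x, "sphere_mesh")) {
                sprintf("sphere_mesh (radius %.4g)", x$radius)
              } else "triangle_mesh",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Vertex-wise scalar map
#'
#' One value per mesh vertex, with an optional logical mask of vertices to
#' exclude from analysis (e.g., the medial wall). `NA` in the values is an
#' error: masking must be explicit, silent NaN propagation would corrupt
#' eigendecompositions downstream.
#'
#' @param values numeric vector, one value per vertex.
#' @param mask optional logical vector; `FALSE` marks excluded vertices.
#' @return an object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_gradmap("empty_input", "scalar map is empty")
  }
  if (!all(is.finite(values))) {
    stop_gradmap("nonfinite",
                 "scalar map contains NA/NaN/Inf; use an explicit mask instead")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(values)) {
      stop_gradmap("length_mismatch", "mask length must match values length")
    }
    if (anyNA(mask)) stop_gradmap("bad_input", "mask contains NA")
  }
  structure(list(values = values, mask = mask), class = "scalar_map")
}

# Accept scalar_map or bare numeric vector; returns list(values, mask).
as_scalar_map <- function(x) {
  if (inherits(x, "scalar_map")) return(x)
  scalar_map(x)
}

#' Parcellation label vector
#'
#' @param labels integer vector, one label per vertex.
#' @param background_label label marking vertices outside every parcel.
#' @return an object of class `parcellation_labels`.
#' @export
parcellation_labels <- function(labels, background_label = 0L) {
  if (any(labels != round(labels), na.rm = TRUE) || anyNA(labels)) {
    stop_gradmap("non_integer_label", "parcellation labels must be integers")
  }
  labels <- as.integer(round(labels))
  parcels <- setdiff(unique(labels), as.integer(background_label))
  if (length(parcels) < 2L) {
    stop_gradmap("bad_input", "need at least 2 distinct non-background labels")
  }
  structure(list(labels = labels, background_label = as.integer(background_label)),
            class = "parcellation_labels")
}

new_gradient_result <- function(gradients, lambdas, method, params,
                                variance_explained = NULL) {
  structure(
    list(gradients = gradients, lambdas = lambdas, method = method,
         params = params, variance_explained = variance_explained),
    class = "gradient_result"
  )
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("gradient_result: %d seeds x %d gradients (method: %s)\n",
              nrow(x$gradients), ncol(x$gradients), x$method))
  cat("lambdas:", format(x$lambdas, digits = 4), "\n")
  if (!is.null(x$variance_explained)) {
    cat("variance explained:",
        format(x$variance_explained, digits = 4), "\n")
  }
  invisible(x)
}

# Accept gradient_result or bare matrix.
gradient_values <- function(g) {
  if (inherits(g, "gradient_result")) g$gradients else as.matrix(g)
}

new_surrogate_ensemble <- function(surrogates, method, seed) {
  structure(list(surrogates = surrogates, method = method, seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("surrogate_ensemble: %d surrogates of length %d (method: %s, seed: %s)\n",
              nrow(x$surrogates), ncol(x$surrogates), x$method,
              x$seed %||% "ambient"))
  invisible(x)
}
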