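# File I/O: delimited and MatrixMarket matrices, ASCII PLY and GIFTI
# surface meshes, scalar maps and parcellation label vectors.
#
# Conventions: face indices are 0-based internally; both PLY and GIFTI use
# 0-based indices on disk so no conversion is needed, but readers validate
# the range either way. Delimited numbers are written with 17 significant
# digits so doubles round-trip exactly.

split_delim_line <- function(line, delim) {
  strsplit(line, delim, fixed = TRUE)[[1]]
}

detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

parse_numeric_cells <- function(cells, path, what = "matrix") {
  x <- suppressWarnings(as.numeric(cells))
  bad <- is.na(x) & !(trimws(cells) %in% c("NA", "NaN", "nan", "NAN"))
  if (any(bad)) {
    stop_gradmap("non_numeric",
                 sprintf("non-numeric cell '%s' in %s '%s'",
                         cells[which(bad)[1]], what, path))
  }
  if (!all(is.finite(x))) {
    stop_gradmap("nonfinite",
                 sprintf("NA/NaN/Inf entry in %s '%s'", what, path))
  }
  x
}

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    stop_gradmap("missing_file", sprintf("file not found: '%s'", path))
  }
}

#' Read a seed-by-feature matrix
#'
#' Reads a dense numeric matrix from delimited text (comma or tab,
#' auto-detected) or a MatrixMarket file. A non-numeric first row in a
#' delimited file is treated as a header of column identifiers.
#'
#' @param path path to the file.
#' @param format `"delimited"` or `"matrix-market"`.
#' @return a numeric matrix (with `dimnames` when the file carries them).
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, format = c("delimited", "matrix-market")) {
  format <- match.arg(format)
  check_file_exists(path)
  if (format == "matrix-market") {
    m <- as.matrix(Matrix::readMM(path))
    if (!all(is.finite(m))) {
      stop_gradmap("nonfinite", sprintf("NA/NaN/Inf entry in matrix '%s'", path))
    }
    return(m)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_gradmap("empty_input", sprintf("empty file: '%s'", path))
  }
  delim <- detect_delim(lines[1])
  cells <- lapply(lines, split_delim_line, delim = delim)
  lens <- lengths(cells)
  header <- NULL
  first <- suppressWarnings(as.numeric(cells[[1]]))
  if (length(lines) > 1L && all(is.na(first)) &&
      !all(trimws(cells[[1]]) %in% c("NA", "NaN"))) {
    header <- cells[[1]]
    cells <- cells[-1]
    lens <- lens[-1]
  }
  if (length(unique(lens)) != 1L) {
    stop_gradmap("ragged_rows",
                 sprintf("ragged rows in '%s': row lengths %s", path,
                         paste(unique(lens), collapse = ", ")))
  }
  vals <- vapply(cells, parse_numeric_cells, numeric(lens[1]),
                 path = path)
  m <- t(matrix(vals, nrow = lens[1]))
  if (!is.null(header)) colnames(m) <- header
  m
}

#' Write a matrix to delimited text or MatrixMarket
#'
#' Delimited output uses 17 significant digits so that doubles survive a
#' write/read round trip bit-identically.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @param format `"delimited"` or `"matrix-market"`.
#' @param delim field delimiter for delimited output.
#' @param col_names write a header row of column names (delimited only).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("delimited", "matrix-market"),
                         delim = ",", col_names = !is.null(colnames(x))) {
  format <- match.arg(format)
  x <- as.matrix(x)
  if (format == "matrix-market") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x), "generalMatrix"),
                                "CsparseMatrix"), path)
    return(invisible(path))
  }
  lines <- apply(x, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = delim)
  })
  if (col_names && !is.null(colnames(x))) {
    lines <- c(paste(colnames(x), collapse = delim), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- PLY (ASCII) ----------------------------------------------------------

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop_gradmap("malformed_header", sprintf("'%s' is not a PLY file", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) {
    stop_gradmap("malformed_header", sprintf("no end_header in '%s'", path))
  }
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header))) {
    stop_gradmap("malformed_header",
                 sprintf("only ASCII PLY is supported ('%s')", path))
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", header, value = TRUE)))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", header, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L || is.na(nv) || is.na(nf)) {
    stop_gradmap("malformed_header",
                 sprintf("missing vertex/face element counts in '%s'", path))
  }
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    stop_gradmap("malformed_header",
                 sprintf("'%s' has fewer data lines than the header declares", path))
  }
  vtx <- t(vapply(body[seq_len(nv)], function(ln) {
    parse_numeric_cells(strsplit(trimws(ln), "\\s+")[[1]][1:3], path, "mesh")
  }, numeric(3), USE.NAMES = FALSE))
  faces <- t(vapply(body[nv + seq_len(nf)], function(ln) {
    f <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    if (is.na(f[1]) || f[1] != 3L || length(f) < 4L) {
      stop_gradmap("malformed_header",
                   sprintf("non-triangular or malformed face line in '%s'", path))
    }
    f[2:4]
  }, integer(3), USE.NAMES = FALSE))
  triangle_mesh(vtx, faces)
}

write_ply_ascii <- function(mesh, path) {
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vlines <- apply(mesh$vertices, 1L, function(v) {
    paste(sprintf("%.17g", v), collapse = " ")
  })
  flines <- apply(mesh$faces, 1L, function(f) {
    paste(c(3L, f), collapse = " ")
  })
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

## ---- GIFTI (XML, ASCII-encoded data) --------------------------------------

gifti_data_array <- function(doc, intent) {
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  for (a in arrays) {
    if (identical(xml2::xml_attr(a, "Intent"), intent)) return(a)
  }
  NULL
}

parse_gifti_array <- function(node, path) {
  enc <- xml2::xml_attr(node, "Encoding")
  if (!identical(enc, "ASCII")) {
    stop_gradmap("malformed_header",
                 sprintf("only ASCII-encoded GIFTI is supported ('%s')", path))
  }
  txt <- xml2::xml_text(xml2::xml_find_first(node, "./Data"))
  vals <- strsplit(trimws(txt), "\\s+")[[1]]
  dim0 <- as.integer(xml2::xml_attr(node, "Dim0"))
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dim1 <- if (!is.na(ndim) && ndim > 1L) {
    as.integer(xml2::xml_attr(node, "Dim1"))
  } else 1L
  x <- parse_numeric_cells(vals, path, "GIFTI array")
  if (length(x) != dim0 * dim1) {
    stop_gradmap("malformed_header",
                 sprintf("GIFTI array length does not match its declared dims in '%s'", path))
  }
  # row-major on disk
  matrix(x, nrow = dim0, ncol = dim1, byrow = TRUE)
}

read_gifti_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- gifti_data_array(doc, "NIFTI_INTENT_POINTSET")
  tri <- gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE")
  if (is.null(pts) || is.null(tri)) {
    stop_gradmap("malformed_header",
                 sprintf("GIFTI file '%s' lacks POINTSET/TRIANGLE arrays", path))
  }
  vtx <- parse_gifti_array(pts, path)
  faces <- parse_gifti_array(tri, path)
  storage.mode(faces) <- "integer"
  triangle_mesh(vtx, faces)
}

gifti_xml <- function(arrays) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  for (a in arrays) {
    dims <- a$dims
    attrs <- c(
      Intent = a$intent, DataType = a$datatype,
      ArrayIndexingOrder = "RowMajorOrder",
      Dimensionality = as.character(length(dims)),
      Encoding = "ASCII", Endian = "LittleEndian",
      ExternalFileName = "", ExternalFileOffset = ""
    )
    for (d in seq_along(dims)) {
      attrs[[sprintf("Dim%d", d - 1L)]] <- as.character(dims[d])
    }
    node <- xml2::xml_add_child(doc, "DataArray")
    for (nm in names(attrs)) xml2::xml_set_attr(node, nm, attrs[[nm]])
    xml2::xml_add_child(node, "Data", a$text)
  }
  doc
}

write_gifti_mesh <- function(mesh, path) {
  vtext <- paste(apply(mesh$vertices, 1L, function(v) {
    paste(sprintf("%.17g", v), collapse = " ")
  }), collapse = "\n")
  ftext <- paste(apply(mesh$faces, 1L, paste, collapse = " "), collapse = "\n")
  doc <- gifti_xml(list(
    list(intent = "NIFTI_INTENT_POINTSET", datatype = "NIFTI_TYPE_FLOAT64",
         dims = dim(mesh$vertices), text = vtext),
    list(intent = "NIFTI_INTENT_TRIANGLE", datatype = "NIFTI_TYPE_INT32",
         dims = dim(mesh$faces), text = ftext)
  ))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a triangle surface mesh
#'
#' Supports ASCII PLY and GIFTI (ASCII-encoded) surface files. Faces are
#' returned 0-based regardless of on-disk convention.
#'
#' @param path path to the mesh file.
#' @param format `"ply-ascii"` or `"gifti"`; default guesses from the file
#'   extension (`.gii` means GIFTI).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply-ascii", "gifti")) {
  format <- match.arg(format)
  check_file_exists(path)
  if (format == "auto") {
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "ply-ascii"
  }
  if (format == "gifti") read_gifti_mesh(path) else read_ply_ascii(path)
}

#' Write a triangle surface mesh
#'
#' @param mesh a [triangle_mesh()] or [sphere_mesh()].
#' @inheritParams read_mesh
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply-ascii", "gifti")) {
  format <- match.arg(format)
  if (!inherits(mesh, "triangle_mesh")) {
    stop_gradmap("bad_input", "mesh must be a triangle_mesh")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "ply-ascii"
  }
  if (format == "gifti") write_gifti_mesh(mesh, path) else write_ply_ascii(mesh, path)
}

#' Read a vertex-wise scalar map
#'
#' One value per line (or the first column of a delimited file). `NaN`
#' entries are rejected: vertices excluded from analysis must be declared
#' through an explicit mask instead.
#'
#' @param path path to the file.
#' @return a numeric vector.
#' @export
read_scalar_map <- function(path) {
  check_file_exists(path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_gradmap("empty_input", sprintf("empty file: '%s'", path))
  }
  cells <- vapply(lines, function(ln) split_delim_line(ln, detect_delim(ln))[1],
                  character(1), USE.NAMES = FALSE)
  parse_numeric_cells(cells, path, "scalar map")
}

#' Write a vertex-wise scalar map
#'
#' @param values numeric vector or [scalar_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(values, path) {
  if (inherits(values, "scalar_map")) values <- values$values
  writeLines(sprintf("%.17g", values), path)
  invisible(path)
}

#' Read a parcellation label vector
#'
#' One integer label per line; non-integer values are an error.
#'
#' @param path path to the file.
#' @return an integer vector.
#' @export
read_labels <- function(path) {
  check_file_exists(path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_gradmap("empty_input", sprintf("empty file: '%s'", path))
  }
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x) || any(x != round(x))) {
    stop_gradmap("non_integer_label",
                 sprintf("non-integer label in '%s'", path))
  }
  as.integer(round(x))
}

#' Write a parcellation label vector
#'
#' @param labels integer vector (or [parcellation_labels()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "parcellation_labels")) labels <- labels$labels
  writeLines(sprintf("%d", as.integer(labels)), path)
  invisible(path)
}
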