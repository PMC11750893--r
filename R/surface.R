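#' Anatomical surface point cloud
#'
#' A `surface` is the basic geometric container of the package: an ordered
#' set of 3D point coordinates in millimetres, optionally triangulated,
#' labelled as either aortic `"wall"` or `"calcification"` and tagged with a
#' patient identifier. All downstream stages (registration, shape modeling,
#' morphometrics) consume and produce this class.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), at least 4 rows.
#' @param faces optional integer matrix with 3 columns of 1-based vertex
#'   indices (triangles).
#' @param patient_id character scalar identifying the subject.
#' @param label one of `"wall"` or `"calcification"`.
#' @param source_path path the geometry was read from, if any.
#'
#' @return An object of class `surface`: a list with elements `points`,
#'   `faces`, `patient_id`, `label`, `source_path`.
#' @export
#' @examples
#' s <- surface(matrix(rnorm(30), ncol = 3), patient_id = "p1", label = "wall")
#' s
surface <- function(points, faces = NULL, patient_id = "unknown",
                    label = c("wall", "calcification"), source_path = NA_character_) {
  label <- match.arg(label)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (nrow(points) < 4L)
    stop("a surface needs at least 4 points, got ", nrow(points), call. = FALSE)
  if (!all(is.finite(points)))
    stop("all point coordinates must be finite", call. = FALSE)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L)
      stop("`faces` must have 3 columns (triangle vertex indices)", call. = FALSE)
    storage.mode(faces) <- "integer"
    dimnames(faces) <- NULL
    if (any(faces < 1L) || any(faces > nrow(points)))
      stop("face indices must lie in [1, number of points]", call. = FALSE)
  }
  structure(
    list(points = points, faces = faces, patient_id = as.character(patient_id),
         label = label, source_path = source_path),
    class = "surface"
  )
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface> %s [%s]: %d points, %s faces\n",
              x$patient_id, x$label, nrow(x$points),
              if (is.null(x$faces)) "no" else format(nrow(x$faces))))
  bb <- apply(x$points, 2, range)
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of points of a surface
#' @param x a [surface].
#' @return integer point count.
#' @export
n_points <- function(x) nrow(x$points)

# Merge duplicate vertices (exact coordinate match) and remap faces.
# STL is a triangle soup: every triangle carries its own copy of each vertex.
merge_vertices <- function(points, faces) {
  key <- paste(points[, 1], points[, 2], points[, 3], sep = "/")
  first <- !duplicated(key)
  # map old vertex row -> row in de-duplicated matrix
  remap <- match(key, unique(key))
  list(points = points[first, , drop = FALSE],
       faces = if (is.null(faces)) NULL else matrix(remap[faces], ncol = 3L))
}

bbox_diagonal <- function(points) {
  rg <- apply(points, 2, range)
  sqrt(sum((rg[2, ] - rg[1, ])^2))
}

centroid <- function(points) colMeans(points)
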