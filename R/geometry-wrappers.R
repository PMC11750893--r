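#' Convex hull volume of a 3D point set
#'
#' Incremental convex hull; degenerate (coplanar or near-empty) inputs return
#' a volume of 0 rather than an error.
#'
#' @param points n x 3 numeric matrix (mm).
#' @return hull volume in mm^3.
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) return(0)
  storage.mode(points) <- "double"
  convhull_volume_cpp(points)
}

# grid-accelerated pairwise triangle test; TRUE when any two non-adjacent
# faces intersect
mesh_self_intersects <- function(points, faces) {
  storage.mode(points) <- "double"
  storage.mode(faces) <- "integer"
  mesh_self_intersects_cpp(points, faces)
}
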