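#' Annulus diameter of an aortic wall surface
#'
#' The annulus is taken as the most proximal cross-section of the root: the
#' wall is projected onto its principal (long) axis, the proximal end is the
#' end with the smaller radial spread (the annulus ring is narrower than the
#' sinus region), all points within `band_mm` of that end are projected onto
#' the plane perpendicular to the axis, and the area-derived diameter
#' `2 * sqrt(A / pi)` of their 2D convex hull is returned. The area-derived
#' diameter is the TAVI-sizing convention.
#'
#' @param wall a wall [surface] with at least 100 points.
#' @param band_mm thickness of the annulus band along the axis (mm).
#' @return annulus diameter in mm.
#' @export
annulus_diameter <- function(wall, band_mm = 1.0) {
  pts <- if (inherits(wall, "surface")) wall$points else as.matrix(wall)
  if (nrow(pts) < 100L)
    stop("geometry error: need at least 100 wall points", call. = FALSE)
  ctr <- colMeans(pts)
  axis <- principal_axis(pts)
  t <- as.numeric(sweep(pts, 2, ctr) %*% axis)
  radial <- sqrt(rowSums((sweep(pts, 2, ctr) - outer(t, axis))^2))

  # proximal end = end slab with the smaller median radius (the annulus ring
  # is narrower than the sinus/ascending segment); robust quantile anchors
  # keep single outlying points from defining the end
  slab <- 3 * band_mm
  q <- stats::quantile(t, c(0.002, 0.998))
  med_r <- c(stats::median(radial[t <= q[1] + slab]),
             stats::median(radial[t >= q[2] - slab]))
  lower_end <- which.min(med_r) == 1L
  sel0 <- if (lower_end) t <= q[1] + slab else t >= q[2] - slab
  sl <- pts[sel0, , drop = FALSE]
  if (nrow(sl) < 10L)
    stop("geometry error: fewer than 10 points in the annulus band", call. = FALSE)

  # re-estimate the rim plane locally: for a thin tube slab the normal is the
  # minimum-variance direction; this removes the global-axis tilt caused by
  # vessel curvature
  normal <- eigen(stats::cov(sl), symmetric = TRUE)$vectors[, 3]
  if (sum(normal * axis) * ifelse(lower_end, 1, -1) < 0) normal <- -normal
  s <- as.numeric(sweep(sl, 2, colMeans(sl)) %*% normal)
  anchor <- stats::quantile(s, 0.01)
  band <- s <= anchor + band_mm
  if (sum(band) < 10L)
    stop("geometry error: fewer than 10 points in the annulus band", call. = FALSE)

  basis <- orthonormal_complement(normal)
  uv <- sweep(sl[band, , drop = FALSE], 2, colMeans(sl)) %*% basis
  h <- grDevices::chull(uv)
  area <- polygon_area(uv[h, 1], uv[h, 2])
  2 * sqrt(area / pi)
}

orthonormal_complement <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  seedv <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seedv - sum(seedv * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  cbind(u, v)
}

# shoelace formula
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Total calcification volume of a plaque point cloud
#'
#' Clusters the points by density (single linkage on the
#' `cluster_distance_mm` neighbourhood graph), discards clusters smaller than
#' `min_cluster_points`, and returns the sum of per-cluster convex hull
#' volumes. Per-plaque hulls (rather than one global hull) keep disjoint
#' plaques from inflating the estimate with the empty space between them.
#'
#' @param calc a calcification [surface] or point matrix.
#' @param cluster_distance_mm neighbour radius for clustering (mm).
#' @param min_cluster_points minimum cluster size retained.
#' @return total volume in mm^3 (0 for empty or fully filtered input).
#' @export
calcification_volume <- function(calc, cluster_distance_mm = 2.0,
                                 min_cluster_points = 20L) {
  pts <- if (inherits(calc, "surface")) calc$points else as.matrix(calc)
  n <- nrow(pts)
  if (is.null(n) || n == 0L) return(0)
  if (n < min_cluster_points) return(0)
  cl <- radius_clusters(pts, cluster_distance_mm)
  sizes <- tabulate(cl)
  keep <- which(sizes >= min_cluster_points)
  if (length(keep) == 0L) return(0)
  sum(vapply(keep, function(k) hull_volume(pts[cl == k, , drop = FALSE]),
             numeric(1)))
}

# single-linkage clustering on the fixed-radius neighbour graph (union-find)
radius_clusters <- function(pts, radius) {
  n <- nrow(pts)
  k <- min(n, 12L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # iterate k-NN expansion until the graph within `radius` is exhausted
  nn <- RANN::nn2(pts, pts, k = k, searchtype = "radius", radius = radius)
  for (i in seq_len(n)) {
    nb <- nn$nn.idx[i, ]
    nb <- nb[nb > 0L & nb != i]
    for (j in nb) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Compare real and synthetic cohort morphometrics
#'
#' Two-sided Mann-Whitney U tests (tie-corrected; exact for small untied
#' samples) on annulus diameter and calcification volume between the real and
#' synthetic groups, plus boxplot quartile summaries per group. A
#' non-significant p-value is the desired outcome: it means the synthetic
#' cohort is morphometrically indistinguishable from the training population.
#'
#' @param real,synthetic data frames with numeric columns `annulus_mm` and/or
#'   `calc_volume_mm3`; each at least 3 rows.
#' @return a `validation_report`: per-measurement U statistic, p-value, and
#'   quartile summaries.
#' @export
compare_cohorts <- function(real, synthetic) {
  real <- as.data.frame(real); synthetic <- as.data.frame(synthetic)
  if (nrow(real) < 3L || nrow(synthetic) < 3L)
    stop("each group needs at least 3 subjects", call. = FALSE)
  vars <- intersect(c("annulus_mm", "calc_volume_mm3"),
                    intersect(names(real), names(synthetic)))
  if (length(vars) == 0L)
    stop("no shared measurement columns (annulus_mm, calc_volume_mm3)",
         call. = FALSE)
  out <- lapply(vars, function(v) {
    x <- real[[v]]; y <- synthetic[[v]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value,
         real_quartiles = stats::quantile(x, c(0, .25, .5, .75, 1)),
         synthetic_quartiles = stats::quantile(y, c(0, .25, .5, .75, 1)))
  })
  names(out) <- vars
  structure(list(tests = out,
                 n_real = nrow(real), n_synthetic = nrow(synthetic)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> real n=%d vs synthetic n=%d\n",
              x$n_real, x$n_synthetic))
  for (v in names(x$tests))
    cat(sprintf("  %s: U = %.1f, p = %.3f\n", v, x$tests[[v]]$U, x$tests[[v]]$p))
  invisible(x)
}

#' Morphometric measurements of an anatomy set
#'
#' Convenience wrapper: annulus diameter per wall and calcification volume
#' per plaque cloud, as the data frame [compare_cohorts()] consumes.
#'
#' @param walls list of wall [surface]s (or `NULL`).
#' @param calcs list of calcification [surface]s (or `NULL`).
#' @param ids subject ids; default taken from the surfaces.
#' @param band_mm annulus band thickness passed to [annulus_diameter()].
#' @return data frame with `id`, `annulus_mm`, `calc_volume_mm3`.
#' @export
measure_anatomy <- function(walls = NULL, calcs = NULL, ids = NULL,
                            band_mm = 1.0) {
  n <- max(length(walls), length(calcs))
  if (is.null(ids)) {
    src <- if (length(walls)) walls else calcs
    ids <- vapply(src, `[[`, "", "patient_id")
  }
  data.frame(
    id = ids,
    annulus_mm = if (length(walls))
      vapply(walls, annulus_diameter, numeric(1), band_mm = band_mm)
      else NA_real_,
    calc_volume_mm3 = if (length(calcs))
      vapply(calcs, calcification_volume, numeric(1)) else NA_real_
  )
}
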