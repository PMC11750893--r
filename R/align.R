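#' Non-rigid registration of a template onto a target cloud
#'
#' Warps the template onto the target by iteratively moving every template
#' point toward its closest target point, with the raw displacement field
#' smoothed by a Gaussian kernel over the template's k-nearest-neighbour
#' graph. The output keeps exactly the template's point count and ordering,
#' which is what establishes dense correspondence across subjects: row `i` of
#' every registered cloud is "the same" anatomical location.
#'
#' The smoothing bandwidth trades off fidelity against rigidity: as
#' `smoothing_mm` grows the displacement field approaches its own mean and
#' the warp degenerates to a translation. Default is 5% of the template
#' bounding-box diagonal.
#'
#' @param template a [surface]; defines the output topology.
#' @param target a [surface] or point matrix, pre-aligned to the template
#'   (rigid + similarity ICP).
#' @param smoothing_mm Gaussian bandwidth of the displacement smoother (mm).
#' @param n_iter number of closest-point/smooth iterations.
#' @param step fraction of the smoothed displacement applied per iteration.
#' @param k_neighbors neighbourhood size of the smoothing graph.
#' @return a [surface] with the template's point count, lying on the target.
#' @export
nonrigid_register <- function(template, target, smoothing_mm = NULL,
                              n_iter = 10L, step = 0.7, k_neighbors = 30L) {
  tpts <- if (inherits(template, "surface")) template$points else as.matrix(template)
  qpts <- if (inherits(target, "surface")) target$points else as.matrix(target)
  if (is.null(smoothing_mm))
    smoothing_mm <- 0.05 * bbox_diagonal(tpts)
  if (smoothing_mm <= 0)
    stop("smoothing_mm must be positive", call. = FALSE)
  m <- nrow(tpts)
  k <- min(k_neighbors, m)
  nbr <- RANN::nn2(tpts, tpts, k = k)
  W <- exp(-nbr$nn.dists^2 / (2 * smoothing_mm^2))
  W <- W / rowSums(W)
  idx <- nbr$nn.idx

  cur <- tpts
  for (i in seq_len(n_iter)) {
    nn <- RANN::nn2(qpts, cur, k = 1)
    D <- qpts[nn$nn.idx[, 1], , drop = FALSE] - cur
    Ds <- vapply(1:3, function(j)
      rowSums(W * matrix(D[idx, j], m, k)), numeric(m))
    cur <- cur + step * Ds
  }
  out <- if (inherits(template, "surface")) template else
    surface(tpts, patient_id = "template", label = "wall")
  out$points <- cur
  out
}

# X-matrix layout: one row per subject, (x1,y1,z1,x2,y2,z2,...).
points_to_row <- function(points) as.vector(t(points))
row_to_points <- function(row) matrix(row, ncol = 3, byrow = TRUE)

#' Corresponded, aligned shape cohort
#'
#' Constructor for the container produced by [align_cohort()] and
#' [align_calcifications()]: a template surface plus one fixed-length
#' coordinate row per subject (concatenated x,y,z of the template's m
#' corresponded points), with the per-subject similarity transforms that took
#' each input into the common frame.
#'
#' @param template [surface] defining point count and ordering.
#' @param X numeric matrix, one row per subject, `3 * n_points(template)` columns.
#' @param ids character vector of subject ids (rownames of `X`).
#' @param transforms named list of [rigid_transform]s.
#' @param label `"wall"` or `"calcification"`.
#' @param mean_iterations outer mean-shape re-alignment iterations used.
#' @return object of class `aligned_cohort`.
#' @export
aligned_cohort <- function(template, X, ids, transforms, label,
                           mean_iterations = NA_integer_) {
  stopifnot(inherits(template, "surface"),
            ncol(X) == 3L * n_points(template),
            nrow(X) == length(ids))
  rownames(X) <- ids
  structure(list(template = template, X = X, ids = ids,
                 transforms = transforms, label = label,
                 mean_iterations = mean_iterations),
            class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf("<aligned_cohort> %s: %d subjects x %d corresponded points (%d mean-shape iterations)\n",
              x$label, nrow(x$X), n_points(x$template), x$mean_iterations))
  invisible(x)
}

# Similarity-align `pts` onto `ref`, then warp `template` onto the aligned
# cloud. Returns list(row, transform, aligned_points).
correspond_one <- function(pts, ref_template, tolerance_mm, max_iter,
                           smoothing_mm, nonrigid_iter, prior_tf = NULL) {
  if (!is.null(prior_tf)) pts0 <- apply_transform(pts, prior_tf) else pts0 <- pts
  tf_r <- rigid_icp(pts0, ref_template$points, tolerance_mm = tolerance_mm,
                    max_iter = max_iter, with_scale = FALSE)
  tf_s <- rigid_icp(apply_transform(pts0, tf_r), ref_template$points,
                    tolerance_mm = tolerance_mm, max_iter = max_iter,
                    with_scale = TRUE)
  tf <- compose_transform(tf_r, tf_s)
  if (!is.null(prior_tf)) tf <- compose_transform(prior_tf, tf)
  aligned <- apply_transform(pts, tf)
  warped <- nonrigid_register(ref_template, aligned, smoothing_mm = smoothing_mm,
                              n_iter = nonrigid_iter)
  # undo the similarity scale about the template centroid so the corresponded
  # row keeps the subject's true size (mode 1 of the PCA can then capture
  # overall size variation); pose alignment is retained
  ctr <- colMeans(ref_template$points)
  restored <- sweep(sweep(warped$points, 2, ctr) / tf$scale, 2, ctr, "+")
  list(row = points_to_row(restored), transform = tf, aligned = aligned)
}

#' Align a cohort of surfaces into dense correspondence
#'
#' Full correspondence pipeline for one shape label: every subject is aligned
#' to a reference by rigid then similarity (rigid + isotropic scale) ICP, the
#' reference template is warped onto each aligned subject by
#' [nonrigid_register()] to produce one fixed-length coordinate row per
#' subject, and the whole procedure is then repeated against the current mean
#' shape until the mean no longer moves (less than `mean_tol_mm` on average)
#' or `max_mean_iter` is reached. Iterating against the mean removes the bias
#' of the arbitrary initial reference choice.
#'
#' The similarity scale is kept in the rows (not undone), so the first shape
#' mode of a subsequent PCA can capture overall size variation.
#'
#' @param surfaces list of [surface]s sharing one label; at least 3.
#' @param reference_id id of the reference subject. Default `NULL` picks the
#'   subject whose annulus diameter (walls) or centroid size (calcifications)
#'   is closest to the cohort median.
#' @param tolerance_mm ICP convergence tolerance, default 0.01 mm.
#' @param max_iter ICP iteration cap, default 120.
#' @param smoothing_mm non-rigid smoothing bandwidth; default 5% of the
#'   template bounding-box diagonal.
#' @param nonrigid_iter non-rigid warp iterations per subject.
#' @param max_mean_iter cap on mean-shape re-alignment rounds.
#' @param mean_tol_mm stop when the mean shape moves less than this (mm).
#' @return an [aligned_cohort()].
#' @export
align_cohort <- function(surfaces, reference_id = NULL, tolerance_mm = 0.01,
                         max_iter = 120L, smoothing_mm = NULL,
                         nonrigid_iter = 10L, max_mean_iter = 10L,
                         mean_tol_mm = 0.05) {
  if (length(surfaces) < 3L)
    stop("need at least 3 surfaces to build a cohort", call. = FALSE)
  labels <- vapply(surfaces, `[[`, "", "label")
  if (length(unique(labels)) != 1L)
    stop("mixed labels in cohort: ", paste(unique(labels), collapse = ", "),
         call. = FALSE)
  ids <- vapply(surfaces, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient ids", call. = FALSE)

  if (is.null(reference_id)) {
    size <- if (labels[1] == "wall") {
      vapply(surfaces, function(s)
        tryCatch(annulus_diameter(s), error = function(e) centroid_size(s$points)),
        numeric(1))
    } else {
      vapply(surfaces, function(s) centroid_size(s$points), numeric(1))
    }
    reference_id <- ids[which.min(abs(size - stats::median(size)))]
  }
  ref_i <- match(reference_id, ids)
  if (is.na(ref_i))
    stop("reference_id '", reference_id, "' not in cohort", call. = FALSE)

  template <- surfaces[[ref_i]]
  template$patient_id <- "template"
  N <- length(surfaces)
  m <- n_points(template)
  X <- matrix(NA_real_, N, 3L * m)
  tfs <- vector("list", N)
  outer_it <- 0L
  mean_trace <- numeric(0)     # mean-shape displacement per outer iteration
  dist_trace <- numeric(0)     # average subject-to-mean distance
  repeat {
    outer_it <- outer_it + 1L
    for (i in seq_len(N)) {
      res <- suppressWarnings(correspond_one(
        surfaces[[i]]$points, template, tolerance_mm, max_iter,
        smoothing_mm, nonrigid_iter))
      X[i, ] <- res$row
      tfs[[i]] <- res$transform
    }
    new_mean <- row_to_points(colMeans(X))
    mean_move <- mean(sqrt(rowSums((new_mean - template$points)^2)))
    mean_trace <- c(mean_trace, mean_move)
    dist_trace <- c(dist_trace, mean(vapply(seq_len(N), function(i)
      mean(sqrt(rowSums((row_to_points(X[i, ]) - new_mean)^2))), numeric(1))))
    template$points <- new_mean
    if (mean_move < mean_tol_mm || outer_it >= max_mean_iter) break
  }
  names(tfs) <- ids
  out <- aligned_cohort(template, X, ids, tfs, labels[1],
                        mean_iterations = outer_it)
  out$mean_trace <- mean_trace
  out$subject_mean_distance <- dist_trace
  out
}

centroid_size <- function(points)
  sqrt(mean(rowSums(sweep(points, 2, colMeans(points))^2)))

# Principal axis (longest extent) of a point set; used as the aortic root
# axis for leaflet-symmetry rotation search.
principal_axis <- function(points) {
  ev <- eigen(stats::cov(points), symmetric = TRUE)
  ev$vectors[, 1]
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Align calcification clouds using their wall transforms
#'
#' Calcific plaques have no anatomy-wide correspondence of their own, so
#' alignment rides on the wall: each subject's wall similarity transform is
#' applied to its calcification, a search over the three 120-degree rotations
#' about the root axis picks the leaflet assignment minimizing the mean
#' plaque-to-template distance (the valve is three-fold symmetric, so plaque
#' patterns can land on the "wrong" leaflet), and a final plaque-only ICP at
#' a relaxed tolerance (default 0.2 mm, to avoid excessive rotation and
#' translation) plus template warping produces the corresponded rows.
#' Assumes plaques are present on all three leaflets in every subject.
#'
#' @param calc_surfaces list of calcification [surface]s, one per wall subject.
#' @param wall_cohort the [aligned_cohort()] of the corresponding walls.
#' @param tolerance_mm relaxed ICP tolerance for the plaque-only step (mm).
#' @param axis_rotations number of candidate rotations about the root axis.
#' @param reference_id calcification template subject; defaults to the
#'   subject with median centroid size.
#' @param smoothing_mm,nonrigid_iter non-rigid warp controls. The default
#'   bandwidth is 1.5 mm — the plaque scale — rather than the wall's
#'   bbox-relative default: plaques are small independent structures and a
#'   wall-scale kernel over-smooths them (shrinking corresponded plaque
#'   volumes).
#' @param max_iter ICP iteration cap.
#' @return an [aligned_cohort()] of label `"calcification"`.
#' @export
align_calcifications <- function(calc_surfaces, wall_cohort,
                                 tolerance_mm = 0.2, axis_rotations = 3L,
                                 reference_id = NULL, smoothing_mm = 1.5,
                                 nonrigid_iter = 15L, max_iter = 120L) {
  stopifnot(inherits(wall_cohort, "aligned_cohort"))
  ids <- vapply(calc_surfaces, `[[`, "", "patient_id")
  if (!setequal(ids, wall_cohort$ids) || length(ids) != length(wall_cohort$ids))
    stop("calcification subjects do not match the wall cohort", call. = FALSE)
  labels <- vapply(calc_surfaces, `[[`, "", "label")
  if (any(labels != "calcification"))
    stop("all surfaces must be labelled 'calcification'", call. = FALSE)
  calc_surfaces <- calc_surfaces[match(wall_cohort$ids, ids)]
  ids <- wall_cohort$ids
  N <- length(ids)

  # carry each calcification into the common frame with its wall transform
  carried <- lapply(seq_len(N), function(i)
    apply_transform(calc_surfaces[[i]]$points, wall_cohort$transforms[[ids[i]]]))

  if (is.null(reference_id)) {
    size <- vapply(carried, centroid_size, numeric(1))
    reference_id <- ids[which.min(abs(size - stats::median(size)))]
  }
  ref_i <- match(reference_id, ids)
  if (is.na(ref_i)) stop("reference_id not found", call. = FALSE)
  template <- calc_surfaces[[ref_i]]
  template$points <- carried[[ref_i]]
  template$patient_id <- "template"

  axis <- principal_axis(wall_cohort$template$points)
  pivot <- colMeans(wall_cohort$template$points)
  angles <- 2 * pi * (seq_len(axis_rotations) - 1L) / axis_rotations

  X <- matrix(NA_real_, N, 3L * n_points(template))
  tfs <- vector("list", N)
  for (i in seq_len(N)) {
    pts <- carried[[i]]
    # leaflet-consistency search: best of the 120-degree candidates
    cand_cost <- vapply(angles, function(a) {
      Rm <- rotation_about_axis(axis, a)
      rot <- sweep((sweep(pts, 2, pivot) %*% t(Rm)), 2, pivot, "+")
      mean(RANN::nn2(template$points, rot, k = 1)$nn.dists)
    }, numeric(1))
    a_best <- angles[which.min(cand_cost)]
    Rm <- rotation_about_axis(axis, a_best)
    tf_rot <- rigid_transform(rotation = Rm,
                              translation = pivot - as.numeric(Rm %*% pivot))
    res <- suppressWarnings(correspond_one(
      pts, template, tolerance_mm, max_iter, smoothing_mm, nonrigid_iter,
      prior_tf = tf_rot))
    X[i, ] <- res$row
    tfs[[i]] <- compose_transform(wall_cohort$transforms[[ids[i]]], res$transform)
  }
  template$points <- row_to_points(colMeans(X))
  names(tfs) <- ids
  aligned_cohort(template, X, ids, tfs, "calcification", mean_iterations = 1L)
}
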