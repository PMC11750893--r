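#' Sample bounded mode weights for a virtual shape
#'
#' Draws each of the first `n_modes` weights independently and uniformly from
#' the discrete grid `{-boundary, -boundary+step, ..., 0, ..., boundary}` (in
#' sigma units); remaining modes stay at zero. Defaults are a +-2 sigma
#' boundary in 0.5 sigma steps. Uniformity over the grid is the
#' least-informative choice for "random variation" on a stated grid.
#'
#' @param model a [ssm_fit()] shape model.
#' @param n_modes number of leading modes to vary (<= K).
#' @param boundary positive sampling bound b (sigma units).
#' @param step grid step (sigma units); must divide `boundary`.
#' @param seed integer seed.
#' @return an object of class `mode_weights`: list with `weights`, `boundary`,
#'   `step`, `seed`.
#' @export
sample_weights <- function(model, n_modes, boundary = 2.0, step = 0.5,
                           seed = 1L) {
  stopifnot(inherits(model, "shape_model"))
  if (n_modes > model$K)
    stop("n_modes (", n_modes, ") exceeds available modes (", model$K, ")",
         call. = FALSE)
  if (boundary <= 0) stop("boundary must be positive", call. = FALSE)
  if (step <= 0 || step > boundary)
    stop("step must be in (0, boundary]", call. = FALSE)
  if (abs(boundary / step - round(boundary / step)) > 1e-9)
    stop("step must divide boundary", call. = FALSE)
  levels <- seq(-boundary, boundary, by = step)
  w <- with_seed(seed, sample(levels, n_modes, replace = TRUE))
  structure(list(weights = w, boundary = boundary, step = step, seed = seed),
            class = "mode_weights")
}

#' @export
print.mode_weights <- function(x, ...) {
  cat(sprintf("<mode_weights> %d modes in [-%g, %g] sigma (step %g), seed %d\n",
              length(x$weights), x$boundary, x$boundary, x$step, x$seed))
  cat(" ", paste(sprintf("%+.1f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Occurrence probability of a shape deviation
#'
#' Upper-tail probability that a shape-mode deviation at least as extreme as
#' `deviation` (in sigma units) occurs, computed as the standardized
#' one-sided upper tail `1 - Phi(deviation)`. At the levels 0.5, 1, 1.5, 2,
#' 2.5 and 3 sigma this gives 30.85%, 15.87%, 6.68%, 2.28%, 0.62% and 0.13%.
#' A chi-square variant based on the squared Mahalanobis distance with 3
#' degrees of freedom is exposed separately as [shape_probability_chisq()].
#'
#' @param deviation non-negative shape deviation in sigma units.
#' @return occurrence probability in `[0, 0.5]`.
#' @export
#' @examples
#' shape_probability(c(0.5, 1, 1.5, 2, 2.5, 3))
shape_probability <- function(deviation) {
  if (any(deviation < 0)) stop("deviation must be non-negative", call. = FALSE)
  stats::pnorm(deviation, lower.tail = FALSE)
}

#' Chi-square occurrence probability of a shape deviation
#'
#' Upper tail of the squared Mahalanobis distance under a chi-square
#' distribution with `df = 3` degrees of freedom:
#' `P(chi2_3 > deviation^2)`. Provided as the distributional alternative to
#' [shape_probability()]; note the two do not agree numerically.
#'
#' @param deviation non-negative shape deviation in sigma units.
#' @param df chi-square degrees of freedom.
#' @return occurrence probability in `[0, 1]`.
#' @export
shape_probability_chisq <- function(deviation, df = 3) {
  if (any(deviation < 0)) stop("deviation must be non-negative", call. = FALSE)
  stats::pchisq(deviation^2, df = df, lower.tail = FALSE)
}

#' Virtual shape container
#'
#' @param surface deformed [surface].
#' @param weights the [sample_weights()] that produced it.
#' @param probability occurrence probability of its most extreme mode
#'   deviation.
#' @param plausible logical plausibility verdict.
#' @param rejection_reason reason string when not plausible.
#' @return object of class `virtual_shape`.
#' @export
virtual_shape <- function(surface, weights, probability = NA_real_,
                          plausible = NA, rejection_reason = NULL) {
  stopifnot(inherits(surface, "surface"))
  if (isTRUE(plausible) && !is.null(rejection_reason))
    stop("a plausible shape cannot carry a rejection reason", call. = FALSE)
  structure(list(surface = surface, weights = weights,
                 probability = probability, plausible = plausible,
                 rejection_reason = rejection_reason),
            class = "virtual_shape")
}

#' @export
print.virtual_shape <- function(x, ...) {
  cat(sprintf("<virtual_shape> %s, P(occurrence) = %.4f, %s\n",
              x$surface$label, x$probability,
              if (isTRUE(x$plausible)) "plausible"
              else if (isFALSE(x$plausible)) paste0("REJECTED: ", x$rejection_reason)
              else "unchecked"))
  invisible(x)
}

#' Check a virtual shape for folded or self-intersecting geometry
#'
#' Automated stand-in for visual inspection of synthetic anatomies. With a
#' triangulated surface the check is geometric: no pair of non-adjacent
#' triangles may intersect (grid-accelerated triangle-triangle test) and at
#' least `normal_agreement` of face normals must agree in direction with the
#' corresponding mean-shape normals (no normal flips). For faceless point
#' clouds the check falls back to neighbourhood preservation on the k-nearest
#' neighbour graph: the deformation must be locally injective, i.e. for at
#' least `normal_agreement` of points the nearest deformed neighbour was
#' already among the point's `k_ref` nearest neighbours on the mean shape. A
#' surface folded through the opposite wall violates both formulations.
#'
#' @param shape a [virtual_shape()] (or bare [surface]).
#' @param model the generating [ssm_fit()] model (supplies the mean shape).
#' @param normal_agreement minimum agreeing fraction, default 0.99.
#' @param k_ref reference neighbourhood size for the faceless check.
#' @return the [virtual_shape()] with `plausible` / `rejection_reason` set.
#' @export
plausibility_check <- function(shape, model, normal_agreement = 0.99,
                               k_ref = 20L) {
  if (inherits(shape, "surface"))
    shape <- virtual_shape(shape, weights = NULL)
  stopifnot(inherits(shape, "virtual_shape"), inherits(model, "shape_model"))
  surf <- shape$surface
  mean_pts <- row_to_points(model$mean)
  reason <- NULL

  if (!is.null(surf$faces)) {
    # normal-flip test against the mean shape
    flips <- face_normal_agreement(surf$points, mean_pts, surf$faces)
    if (flips < normal_agreement)
      reason <- sprintf("normal flip: only %.1f%% of face normals agree with the mean shape",
                        100 * flips)
    if (is.null(reason) &&
        self_intersects(surf$points, surf$faces))
      reason <- "self-intersection: non-adjacent triangles overlap"
  } else {
    if (n_points(surf) < 10L)
      stop("geometry error: faceless surface with fewer than 10 points",
           call. = FALSE)
    k <- min(k_ref, n_points(surf) - 1L)
    ref_nbr <- RANN::nn2(mean_pts, mean_pts, k = k + 1L)$nn.idx[, -1, drop = FALSE]
    def_nn <- RANN::nn2(surf$points, surf$points, k = 2L)$nn.idx[, 2]
    preserved <- mean(vapply(seq_len(nrow(ref_nbr)), function(i)
      def_nn[i] %in% ref_nbr[i, ], logical(1)))
    if (preserved < normal_agreement)
      reason <- sprintf("fold: neighbourhood preservation %.1f%% below %.0f%%",
                        100 * preserved, 100 * normal_agreement)
  }
  shape$plausible <- is.null(reason)
  shape$rejection_reason <- reason
  shape
}

# Fraction of faces whose normal agrees (positive dot product) with the
# normal of the same face on the reference point configuration.
face_normal_agreement <- function(points, ref_points, faces) {
  n1 <- face_normals(points, faces)
  n0 <- face_normals(ref_points, faces)
  mean(rowSums(n1 * n0) > 0)
}

face_normals <- function(points, faces) {
  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE]
  c_ <- points[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

self_intersects <- function(points, faces) {
  mesh_self_intersects(points, faces)  # Rcpp, grid-accelerated
}

#' Generate a virtual patient cohort
#'
#' Synthesizes `n` wall + calcification anatomy pairs from two fitted shape
#' models: mode weights are drawn with [sample_weights()] over the leading
#' modes retaining `variance_fraction` of each model's variability, the mean
#' shapes are deformed accordingly, each deformed shape is annotated with the
#' occurrence probability of its most extreme mode deviation, and implausible
#' (folded or self-intersecting) shapes are rejected and redrawn up to
#' `max_attempts_per_shape` times. Wall and calcification weights are drawn
#' independently; a single seed stream keeps pairs reproducible.
#'
#' @param wall_model,calc_model fitted [ssm_fit()] models.
#' @param n number of virtual patients.
#' @param variance_fraction cumulative variance retained when choosing how
#'   many modes to vary (default 0.90).
#' @param boundary,step sampling grid, see [sample_weights()].
#' @param seed integer master seed.
#' @param max_attempts_per_shape redraw budget per anatomy.
#' @return list of `n` elements, each `list(id, wall, calc)` of
#'   [virtual_shape()]s.
#' @export
generate_cohort <- function(wall_model, calc_model, n = 100L,
                            variance_fraction = 0.90, boundary = 2.0,
                            step = 0.5, seed = 1L,
                            max_attempts_per_shape = 50L) {
  stopifnot(inherits(wall_model, "shape_model"),
            inherits(calc_model, "shape_model"))
  if (n == 0L) return(list())
  n_wall <- modes_for_variance(wall_model, variance_fraction)
  n_calc <- modes_for_variance(calc_model, variance_fraction)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- list(
      id = sprintf("virtual_%03d", i),
      wall = draw_plausible(wall_model, n_wall, boundary, step,
                            seed + 2L * i, max_attempts_per_shape),
      calc = draw_plausible(calc_model, n_calc, boundary, step,
                            seed + 2L * i + 1L, max_attempts_per_shape)
    )
  }
  out
}

draw_plausible <- function(model, n_modes, boundary, step, seed, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    w <- sample_weights(model, n_modes, boundary, step,
                        seed = seed + 100000L * (attempt - 1L))
    surf <- ssm_deform(model, w)
    vs <- virtual_shape(surf, w,
                        probability = shape_probability(max(abs(w$weights), 0)))
    vs <- plausibility_check(vs, model)
    if (vs$plausible) return(vs)
  }
  stop("generation error: no plausible shape after ", max_attempts,
       " attempts; last weights: ", paste(w$weights, collapse = ", "),
       call. = FALSE)
}
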