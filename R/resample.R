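#' Randomly resample a surface to a target point count
#'
#' Uniform random subsampling of the original grid, without replacement and
#' seeded for reproducibility. Faces are dropped: a random vertex subset does
#' not inherit a valid triangulation. Defaults follow the pipeline's working
#' resolutions of 30,000 points for the aortic wall and 50,000 for the
#' calcifications.
#'
#' @param x a [surface].
#' @param target_n number of points to keep; must not exceed `n_points(x)`.
#'   Defaults to 30,000 for walls and 50,000 for calcifications.
#' @param seed integer seed for the random subset.
#' @return a faceless [surface] with `target_n` points.
#' @export
resample_surface <- function(x, target_n = NULL, seed = 1L) {
  stopifnot(inherits(x, "surface"))
  if (is.null(target_n))
    target_n <- if (x$label == "wall") 30000L else 50000L
  n <- n_points(x)
  if (target_n > n)
    stop("target_n (", target_n, ") exceeds point count (", n, ")", call. = FALSE)
  if (target_n < 4L)
    stop("target_n must be at least 4", call. = FALSE)
  keep <- with_seed(seed, sample.int(n, target_n))
  surface(x$points[keep, , drop = FALSE], NULL, patient_id = x$patient_id,
          label = x$label, source_path = x$source_path)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Grid-resolution convergence of the first shape mode
#'
#' Runs the full correspondence + PCA pipeline at a series of resampling
#' levels and tracks the explained-variance fraction of the first shape mode.
#' The working resolution is declared converged at the first level whose
#' relative change versus the previous level falls below `threshold`
#' (default 5%). The explained-variance fraction is used as the convergence
#' metric because it is dimensionless and insensitive to the absolute scale
#' of the geometry.
#'
#' @param surfaces list of [surface]s of one label, at full resolution.
#' @param levels strictly increasing integer vector of point counts to test.
#' @param threshold relative-change threshold (fraction), default 0.05.
#' @param seed integer seed; fans out to the resampling of each level.
#' @param ... further arguments passed to [align_cohort()].
#' @return a `resolution_report`: list with `levels`, `first_mode_fraction`,
#'   `relative_changes`, `converged_level` and `converged` flag.
#' @export
resolution_convergence <- function(surfaces, levels, threshold = 0.05,
                                   seed = 1L, ...) {
  if (length(surfaces) < 3L)
    stop("need at least 3 surfaces", call. = FALSE)
  levels <- as.integer(levels)
  if (length(levels) < 2L)
    stop("need at least 2 resolution levels", call. = FALSE)
  if (any(diff(levels) <= 0L))
    stop("levels must be strictly increasing", call. = FALSE)

  frac1 <- vapply(seq_along(levels), function(k) {
    lv <- levels[k]
    sub <- lapply(seq_along(surfaces), function(i)
      resample_surface(surfaces[[i]], lv, seed = seed + 1000L * k + i))
    cohort <- align_cohort(sub, ...)
    model <- ssm_fit(cohort)
    if (model$K == 0L) return(NA_real_)
    model$variance_fractions[1]
  }, numeric(1))

  rel <- c(NA_real_, abs(diff(frac1)) / pmax(frac1[-length(frac1)], .Machine$double.eps))
  hit <- which(rel < threshold)
  converged <- length(hit) > 0L
  structure(
    list(levels = levels,
         first_mode_fraction = frac1,
         relative_changes = rel,
         converged_level = if (converged) levels[hit[1]] else levels[length(levels)],
         converged = converged,
         threshold = threshold),
    class = "resolution_report"
  )
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("<resolution_report>\n")
  print(data.frame(level = x$levels,
                   mode1_fraction = round(x$first_mode_fraction, 4),
                   rel_change = round(x$relative_changes, 4)))
  cat(sprintf("converged at %d points (threshold %.0f%%)%s\n",
              x$converged_level, 100 * x$threshold,
              if (x$converged) "" else " [WARNING: no level met the threshold]"))
  invisible(x)
}
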