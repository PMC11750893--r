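#' Rigid transform container
#'
#' @param rotation 3x3 rotation matrix (det +1).
#' @param translation length-3 numeric vector (mm).
#' @param scale positive isotropic scale (1 for strictly rigid).
#' @param converged logical, did the ICP meet its tolerance.
#' @param iterations number of ICP iterations run.
#' @param rms final root-mean-square closest-point distance (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1, converged = TRUE, iterations = 0L,
                            rms = NA_real_) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must have determinant +1", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale, converged = converged,
                 iterations = as.integer(iterations), rms = rms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f) mm, scale %.4f\n",
              ang, x$translation[1], x$translation[2], x$translation[3], x$scale))
  cat(sprintf("  %d iterations, rms %.4g mm%s\n", x$iterations, x$rms,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Apply a rigid/similarity transform to points or a surface
#'
#' Points map as `scale * R %*% p + t`.
#'
#' @param x a [surface] or an n x 3 matrix.
#' @param tf a [rigid_transform].
#' @return same type as `x`, transformed.
#' @export
apply_transform <- function(x, tf) {
  if (inherits(x, "surface")) {
    x$points <- apply_transform(x$points, tf)
    return(x)
  }
  sweep(x %*% t(tf$rotation) * tf$scale, 2, tf$translation, "+")
}

#' Compose two transforms (first `a`, then `b`)
#' @param a,b [rigid_transform]s.
#' @return the composite [rigid_transform].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(rotation = b$rotation %*% a$rotation,
                  translation = b$scale * as.numeric(b$rotation %*% a$translation) + b$translation,
                  scale = a$scale * b$scale,
                  converged = a$converged && b$converged,
                  iterations = a$iterations + b$iterations,
                  rms = b$rms)
}

#' Invert a transform
#' @param tf a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(rotation = Rt,
                  translation = -as.numeric(Rt %*% tf$translation) / tf$scale,
                  scale = 1 / tf$scale,
                  converged = tf$converged, iterations = tf$iterations,
                  rms = tf$rms)
}

# Closed-form least-squares alignment of paired point sets (Kabsch/Umeyama).
# Returns the transform mapping `moving` onto `fixed`.
procrustes_fit <- function(moving, fixed, with_scale = FALSE) {
  mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
  A <- sweep(moving, 2, mu_m); B <- sweep(fixed, 2, mu_f)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (with_scale) sum(sv$d * diag(D)) / sum(A^2) else 1
  t <- mu_f - s * as.numeric(R %*% mu_m)
  rigid_transform(rotation = R, translation = t, scale = s)
}

# ICP is a local optimizer, so start it from the best of several coarse
# initial poses: plain centroid alignment plus the four proper-rotation
# matchings of the two clouds' principal axes (axis signs are ambiguous).
icp_initialize <- function(P, Q) {
  cand <- list(rigid_transform(translation = colMeans(Q) - colMeans(P)))
  Vp <- eigen(stats::cov(P), symmetric = TRUE)$vectors
  Vq <- eigen(stats::cov(Q), symmetric = TRUE)$vectors
  if (det(Vp) < 0) Vp[, 3] <- -Vp[, 3]
  if (det(Vq) < 0) Vq[, 3] <- -Vq[, 3]
  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  for (i in seq_len(nrow(signs))) {
    R <- Vq %*% diag(signs[i, ]) %*% t(Vp)
    tr <- colMeans(Q) - as.numeric(R %*% colMeans(P))
    cand <- c(cand, list(rigid_transform(rotation = R, translation = tr)))
  }
  # subsample for the candidate scoring; full clouds are not needed here
  idx <- if (nrow(P) > 500L) round(seq(1L, nrow(P), length.out = 500L)) else seq_len(nrow(P))
  cost <- vapply(cand, function(tf)
    mean(RANN::nn2(Q, apply_transform(P[idx, , drop = FALSE], tf), k = 1)$nn.dists),
    numeric(1))
  cand[[which.min(cost)]]
}

check_nondegenerate <- function(points, what = "point cloud") {
  if (nrow(points) < 4L)
    stop("geometry error: ", what, " has fewer than 4 points", call. = FALSE)
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-12 * max(ev[1], .Machine$double.eps))
    stop("geometry error: ", what, " is degenerate (coplanar or collinear)",
         call. = FALSE)
  invisible(TRUE)
}

#' Rigid / similarity iterative closest point registration
#'
#' Aligns `moving` onto `fixed` by alternating closest-point matching
#' (kd-tree) with a closed-form least-squares transform update. Iteration
#' stops when the mean displacement of the moving cloud induced by the three
#' most recent consecutive transform estimates drops below `tolerance_mm`
#' (default 0.01 mm), or after `max_iter` iterations (default 120), in which
#' case the result is returned with `converged = FALSE`.
#'
#' @param moving,fixed [surface]s or n x 3 point matrices with at least 4
#'   non-coplanar points each.
#' @param tolerance_mm convergence tolerance on the mean inter-iteration
#'   displacement (mm).
#' @param max_iter iteration cap.
#' @param with_scale also estimate an isotropic scale (similarity ICP).
#' @return a [rigid_transform] mapping `moving` onto `fixed`.
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
#' tf <- rigid_icp(cube, cube)
#' max(abs(tf$rotation - diag(3)))
rigid_icp <- function(moving, fixed, tolerance_mm = 0.01, max_iter = 120L,
                      with_scale = FALSE) {
  P <- if (inherits(moving, "surface")) moving$points else as.matrix(moving)
  Q <- if (inherits(fixed, "surface")) fixed$points else as.matrix(fixed)
  check_nondegenerate(P, "moving cloud")
  check_nondegenerate(Q, "fixed cloud")

  tf <- icp_initialize(P, Q)
  cur <- apply_transform(P, tf)
  disp_hist <- rep(Inf, 3)
  it <- 0L
  rms <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    nn <- RANN::nn2(Q, cur, k = 1)
    target <- Q[nn$nn.idx[, 1], , drop = FALSE]
    step <- procrustes_fit(cur, target, with_scale = with_scale)
    newpts <- apply_transform(cur, step)
    disp <- mean(sqrt(rowSums((newpts - cur)^2)))
    disp_hist <- c(disp_hist[-1], disp)
    tf <- compose_transform(tf, step)
    cur <- newpts
    rms <- sqrt(mean(nn$nn.dists[, 1]^2))
    if (mean(disp_hist) < tolerance_mm) {
      tf$converged <- TRUE; tf$iterations <- it; tf$rms <- rms
      return(tf)
    }
  }
  tf$converged <- FALSE
  tf$iterations <- it
  tf$rms <- rms
  warning("ICP did not meet tolerance ", tolerance_mm, " mm after ",
          max_iter, " iterations (rms ", signif(rms, 4), " mm)", call. = FALSE)
  tf
}
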