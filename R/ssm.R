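#' Fit a statistical shape model by PCA
#'
#' Computes the point-distribution model of an aligned, corresponded cohort:
#' the mean shape plus orthonormal deformation modes from an
#' eigendecomposition of the sample covariance of the mean-centred coordinate
#' rows (divisor N-1), obtained via SVD of the centred matrix for numerical
#' stability. Modes with eigenvalue below `1e-12 * lambda_1` are discarded as
#' numerically null. Each mode's sign is fixed so its largest-magnitude entry
#' is positive (PCA signs are arbitrary; pinning them makes results
#' deterministic).
#'
#' @param cohort an [aligned_cohort()] with at least 3 subjects.
#' @return an object of class `shape_model`: list with `mean` (3m vector,
#'   mm), `modes` (3m x K orthonormal), `variances` (eigenvalues, mm^2,
#'   non-increasing), `sigmas` (their square roots), `variance_fractions`,
#'   `K`, `n_training`, `label`, `template`.
#' @export
ssm_fit <- function(cohort) {
  stopifnot(inherits(cohort, "aligned_cohort"))
  X <- cohort$X
  N <- nrow(X)
  if (N < 3L) stop("need at least 3 subjects to fit a shape model", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (N - 1)
  keep <- lambda > 1e-12 * max(lambda[1], .Machine$double.eps) &
    seq_along(lambda) <= N - 1L
  K <- sum(keep)
  if (K == 0L)
    warning("rank-0 cohort: all subjects identical; model has no modes",
            call. = FALSE)
  modes <- sv$v[, which(keep), drop = FALSE]
  # sign convention: largest-|entry| of each mode positive
  if (K > 0L) {
    flip <- vapply(seq_len(K), function(j) {
      v <- modes[, j]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    modes <- sweep(modes, 2, flip, "*")
  }
  lambda <- lambda[which(keep)]
  structure(
    list(mean = mu, modes = modes, variances = lambda,
         sigmas = sqrt(lambda),
         variance_fractions = if (K > 0L) lambda / sum(lambda) else numeric(0),
         K = K, n_training = N, label = cohort$label,
         template = cohort$template),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %s: %d modes from %d subjects (%d points)\n",
              x$label, x$K, x$n_training, length(x$mean) / 3))
  if (x$K > 0L) {
    k <- min(x$K, 6L)
    cat("  variance fractions:",
        paste(sprintf("%.1f%%", 100 * x$variance_fractions[seq_len(k)]),
              collapse = " "), if (x$K > k) "...", "\n")
  }
  invisible(x)
}

#' Deform the mean shape along model modes
#'
#' Builds the surface `mean + sum_j w_j * sigma_j * phi_j` for weights given
#' in standard-deviation units. Weights beyond `length(weights)` are zero.
#'
#' @param model a [ssm_fit()] shape model.
#' @param weights numeric vector of mode weights in sigma units (length <= K),
#'   or a `mode_weights` object from [sample_weights()].
#' @return a [surface]; template faces are reused when available.
#' @export
ssm_deform <- function(model, weights) {
  stopifnot(inherits(model, "shape_model"))
  if (inherits(weights, "mode_weights")) weights <- weights$weights
  w <- as.numeric(weights)
  if (length(w) > model$K)
    stop("weight vector longer than the number of modes (", model$K, ")",
         call. = FALSE)
  coords <- model$mean
  if (length(w) > 0L) {
    j <- seq_along(w)
    coords <- coords + as.numeric(model$modes[, j, drop = FALSE] %*%
                                    (w * model$sigmas[j]))
  }
  out <- model$template
  out$points <- row_to_points(coords)
  out$patient_id <- "synthetic"
  out
}

#' Number of modes needed to reach a variance fraction
#'
#' @param model a shape model.
#' @param fraction target cumulative explained-variance fraction in (0, 1].
#' @return the smallest mode count whose cumulative variance fraction reaches
#'   `fraction`.
#' @export
modes_for_variance <- function(model, fraction = 0.90) {
  stopifnot(inherits(model, "shape_model"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (model$K == 0L) return(0L)
  cv <- cumsum(model$variance_fractions)
  as.integer(which(cv >= fraction - 1e-12)[1])
}

#' Project corresponded shapes onto model modes
#'
#' Principal-component scores of each row: `(x - mean) %*% modes`, in mm.
#' The training-score covariance is diagonal with the model eigenvalues.
#'
#' @param model a shape model.
#' @param cohort an [aligned_cohort()] corresponded to the model's template,
#'   or a numeric matrix/vector of coordinate rows.
#' @return numeric matrix, subjects x K.
#' @export
mode_scores <- function(model, cohort) {
  stopifnot(inherits(model, "shape_model"))
  X <- if (inherits(cohort, "aligned_cohort")) cohort$X else
    if (is.matrix(cohort)) cohort else matrix(cohort, nrow = 1)
  if (ncol(X) != length(model$mean))
    stop("dimension mismatch: rows have ", ncol(X), " coordinates, model has ",
         length(model$mean), call. = FALSE)
  sweep(X, 2, model$mean) %*% model$modes
}

#' Generalization and compactness of a shape model
#'
#' Leave-one-out generalization: for each subject, a model is fitted on the
#' remaining subjects and the left-out shape is reconstructed from its
#' projection onto the first M modes. The generalization error GE(M) is the
#' cohort mean of the per-point RMS reconstruction distance (mm), a
#' resolution-independent norm. Folds reuse the cohort's existing
#' correspondence (no re-registration per fold).
#'
#' @param cohort an [aligned_cohort()] with at least 4 subjects.
#' @param M_values mode counts to evaluate; values above N-2 are skipped with
#'   a warning. Default `1:(N-2)`.
#' @return a `quality_report`: list with `M_values`, `generalization` (mm),
#'   `cumulative_variance`, `modes_for_fraction` (at 0.90 and 0.95).
#' @export
ssm_generalization <- function(cohort, M_values = NULL) {
  stopifnot(inherits(cohort, "aligned_cohort"))
  X <- cohort$X
  N <- nrow(X)
  if (N < 4L) stop("need at least 4 subjects for leave-one-out", call. = FALSE)
  if (is.null(M_values)) M_values <- seq_len(N - 2L)
  M_values <- as.integer(M_values)
  if (any(M_values > N - 2L)) {
    warning("dropping M values above N-2 = ", N - 2L, call. = FALSE)
    M_values <- M_values[M_values <= N - 2L]
  }
  m <- ncol(X) / 3
  err <- matrix(NA_real_, N, length(M_values))
  for (i in seq_len(N)) {
    Xi <- X[-i, , drop = FALSE]
    mu <- colMeans(Xi)
    sv <- svd(sweep(Xi, 2, mu), nu = 0)
    phi <- sv$v
    centred <- X[i, ] - mu
    scores <- as.numeric(centred %*% phi)
    for (k in seq_along(M_values)) {
      M <- min(M_values[k], ncol(phi))
      recon <- mu + as.numeric(phi[, seq_len(M), drop = FALSE] %*% scores[seq_len(M)])
      d2 <- rowSums((row_to_points(X[i, ]) - row_to_points(recon))^2)
      err[i, k] <- sqrt(mean(d2))
    }
  }
  model <- ssm_fit(cohort)
  cv <- cumsum(model$variance_fractions)
  structure(
    list(M_values = M_values,
         generalization = colMeans(err),
         per_subject_error = err,
         cumulative_variance = cv,
         modes_for_fraction = c(
           "0.9" = if (model$K) modes_for_variance(model, 0.90) else 0L,
           "0.95" = if (model$K) modes_for_variance(model, 0.95) else 0L)),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n  GE(M) [mm]:",
      paste(sprintf("M=%d: %.3f", utils::head(x$M_values, 8),
                    utils::head(x$generalization, 8)), collapse = "  "),
      if (length(x$M_values) > 8) "...", "\n")
  cat(sprintf("  modes for 90%%/95%% variance: %d / %d\n",
              x$modes_for_fraction[["0.9"]], x$modes_for_fraction[["0.95"]]))
  invisible(x)
}
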