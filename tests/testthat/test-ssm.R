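test_that("a one-factor cohort yields a single mode parallel to the factor", {
  set.seed(1)
  mu <- rnorm(12)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  t <- seq(-2, 2, length.out = 5)
  X <- t(vapply(t, function(ti) mu + ti * v, numeric(12)))
  m <- ssm_fit(cohort_from_rows(X))
  expect_equal(m$K, 1L)
  expect_equal(abs(sum(m$modes[, 1] * v)), 1, tolerance = 1e-10)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-10)
})

test_that("the fitted spectrum matches a dense eigendecomposition of the covariance", {
  set.seed(7)
  X <- matrix(rnorm(45), 5, 9)
  m <- ssm_fit(cohort_from_rows(X))
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(m$variances, ev[seq_len(m$K)], tolerance = 1e-8)
  # orthonormal modes
  expect_lt(max(abs(crossprod(m$modes) - diag(m$K))), 1e-8)
  expect_true(all(diff(m$variances) <= 1e-12))
  expect_lte(m$K, nrow(X) - 1L)
})

test_that("the fit is invariant to subject order", {
  set.seed(8)
  X <- matrix(rnorm(8 * 15), 8, 15)
  m1 <- ssm_fit(cohort_from_rows(X))
  m2 <- ssm_fit(cohort_from_rows(X[sample(8), ]))
  expect_equal(m1$variances, m2$variances, tolerance = 1e-10)
})

test_that("an all-identical cohort yields a modeless atlas with a warning", {
  X <- matrix(rep(rnorm(9), each = 4), 4, 9)
  expect_warning(m <- ssm_fit(cohort_from_rows(X)), "rank-0")
  expect_equal(m$K, 0L)
})

test_that("deformation reproduces the mean, single-mode offsets, and full reconstruction", {
  set.seed(9)
  X <- matrix(rnorm(6 * 12, sd = 3), 6, 12)
  cohort <- cohort_from_rows(X)
  m <- ssm_fit(cohort)

  expect_equal(as.vector(t(ssm_deform(m, numeric(0))$points)), m$mean)

  d3 <- ssm_deform(m, c(3))
  expect_equal(as.vector(t(d3$points)),
               m$mean + 3 * m$sigmas[1] * m$modes[, 1], tolerance = 1e-12)

  # PCA completeness: project a training row on all modes and rebuild it
  w_sigma <- mode_scores(m, X[4, , drop = FALSE])
  w <- as.numeric(w_sigma) / m$sigmas
  rebuilt <- as.vector(t(ssm_deform(m, w)$points))
  expect_lt(sqrt(sum((rebuilt - X[4, ])^2)) / sqrt(sum(X[4, ]^2)), 1e-6)

  expect_error(ssm_deform(m, rep(0, m$K + 1L)), "longer than")
})

test_that("modes_for_variance follows the cumulative spectrum", {
  fake <- function(lambda) {
    K <- length(lambda)
    structure(list(variances = lambda, variance_fractions = lambda / sum(lambda),
                   K = K), class = "shape_model")
  }
  expect_equal(modes_for_variance(fake(c(9, 0.5, 0.5)), 0.9), 1L)
  expect_equal(modes_for_variance(fake(rep(1, 4)), 0.5), 2L)
  expect_equal(modes_for_variance(fake(c(4, 3, 2, 1)), 0.9), 3L)
  expect_error(modes_for_variance(fake(c(1)), 0), "fraction")
  expect_error(modes_for_variance(fake(c(1)), 1.2), "fraction")
})

test_that("mode scores satisfy the PCA identities", {
  set.seed(10)
  X <- matrix(rnorm(20 * 30, sd = 2), 20, 30)
  cohort <- cohort_from_rows(X)
  m <- ssm_fit(cohort)
  # the mean row scores to zero
  expect_lt(max(abs(mode_scores(m, matrix(m$mean, 1)))), 1e-10)
  # deform-then-score returns w * sigma
  w <- c(1.5, -2, 0.5)
  sc <- mode_scores(m, matrix(as.vector(t(ssm_deform(m, w)$points)), 1))
  expect_equal(as.numeric(sc)[1:3], w * m$sigmas[1:3], tolerance = 1e-8)
  expect_lt(max(abs(sc[-(1:3)])), 1e-8)
  # training-score covariance is diagonal with the eigenvalues
  S <- mode_scores(m, cohort)
  CS <- cov(S)
  expect_equal(diag(CS), m$variances, tolerance = 1e-6 * m$variances[1])
  expect_lt(max(abs(CS - diag(diag(CS)))), 1e-6 * m$variances[1])
  expect_error(mode_scores(m, matrix(0, 1, 7)), "dimension mismatch")
})

test_that("leave-one-out generalization matches an independently coded loop", {
  set.seed(11)
  X <- matrix(rnorm(6 * 12, sd = 2), 6, 12)
  cohort <- cohort_from_rows(X)
  M_values <- 1:4
  qr_ <- ssm_generalization(cohort, M_values)

  # independent oracle: plain prcomp per fold, explicit reconstruction
  N <- nrow(X)
  ge <- sapply(M_values, function(M) {
    errs <- sapply(seq_len(N), function(i) {
      pc <- stats::prcomp(X[-i, ], center = TRUE, scale. = FALSE)
      ctr <- pc$center
      phi <- pc$rotation[, seq_len(M), drop = FALSE]
      sc <- as.numeric((X[i, ] - ctr) %*% phi)
      rec <- ctr + as.numeric(phi %*% sc)
      sqrt(mean(rowSums((matrix(X[i, ], ncol = 3, byrow = TRUE) -
                           matrix(rec, ncol = 3, byrow = TRUE))^2)))
    })
    mean(errs)
  })
  expect_equal(qr_$generalization, ge, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("generalization is zero for identical shapes and non-increasing in M", {
  Xsame <- matrix(rep(rnorm(9), each = 5), 5, 9)
  qr0 <- suppressWarnings(ssm_generalization(cohort_from_rows(Xsame), 1:2))
  expect_equal(qr0$generalization, c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)

  # one factor + isotropic noise: more modes never hurt the reconstruction
  set.seed(12)
  v <- rnorm(18); v <- v / sqrt(sum(v^2))
  X <- outer(rnorm(10, sd = 4), v) + matrix(rnorm(180, sd = 0.3), 10, 18)
  ge <- ssm_generalization(cohort_from_rows(X), 1:8)$generalization
  expect_true(all(diff(ge) <= 1e-9))

  expect_warning(ssm_generalization(cohort_from_rows(X), c(2, 9)), "N-2")
})

test_that("a known low-rank generative subspace is recovered at N = 50", {
  set.seed(13)
  m3 <- 30
  B <- qr.Q(qr(matrix(rnorm(m3 * 2), m3, 2)))   # generative subspace
  scores <- cbind(rnorm(50, sd = 6), rnorm(50, sd = 3))
  X <- scores %*% t(B) + matrix(rnorm(50 * m3, sd = 0.3), 50, m3)
  m <- ssm_fit(cohort_from_rows(X))
  # principal angle between fitted and generative 2D subspaces
  sv <- svd(crossprod(B, m$modes[, 1:2]))$d
  angle <- acos(min(sv)) * 180 / pi
  expect_lt(angle, 5)
})
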