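make_sphere_model <- function(n_sub = 5, with_faces = TRUE, seed = 1) {
  sm <- sphere_mesh(n = 10, r = 20)
  set.seed(seed)
  X <- t(vapply(seq_len(n_sub), function(i)
    as.vector(t(sm$points * (1 + 0.05 * rnorm(1)) +
                  matrix(rnorm(length(sm$points), sd = 0.05),
                         ncol = 3))), numeric(length(sm$points))))
  template <- surface(sm$points, if (with_faces) sm$faces,
                      patient_id = "template", label = "wall")
  cohort <- aligned_cohort(template, X, sprintf("s%d", seq_len(n_sub)),
                           replicate(n_sub, rigid_transform(), simplify = FALSE),
                           "wall")
  ssm_fit(cohort)
}

test_that("sampled weights live on the bounded sigma grid and are seeded", {
  m <- make_sphere_model()
  w <- sample_weights(m, n_modes = 4, boundary = 2, step = 0.5, seed = 3)
  expect_length(w$weights, 4L)
  expect_true(all(abs(w$weights) <= 2))
  expect_true(all(abs(w$weights / 0.5 - round(w$weights / 0.5)) < 1e-12))
  expect_identical(w$weights,
                   sample_weights(m, 4, 2, 0.5, seed = 3)$weights)

  expect_error(sample_weights(m, 4, boundary = 0), "positive")
  expect_error(sample_weights(m, 4, boundary = 2, step = 3), "step")
  expect_error(sample_weights(m, 4, boundary = 2, step = 0.3), "divide")
  expect_error(sample_weights(m, m$K + 1L), "exceeds")
})

test_that("single-mode draws are uniform over the nine grid levels", {
  m <- make_sphere_model()
  draws <- vapply(1:10000, function(i)
    sample_weights(m, 1, 2, 0.5, seed = i)$weights, numeric(1))
  freq <- table(factor(draws, levels = seq(-2, 2, 0.5))) / 10000
  se <- sqrt((1 / 9) * (8 / 9) / 10000)
  expect_true(all(abs(freq - 1 / 9) < 3 * se + 1e-12))
})

test_that("grid sampling reproduces the discrete-uniform score variance", {
  m <- make_sphere_model()
  W <- t(vapply(1:1000, function(i)
    sample_weights(m, 4, 2, 0.5, seed = 20000 + i)$weights, numeric(4)))
  theo <- mean(seq(-2, 2, 0.5)^2)          # uniform grid, zero mean
  expect_equal(mean(apply(W, 2, var)), theo, tolerance = 0.05)
  expect_true(all(abs(apply(W, 2, var) / theo - 1) < 0.2))
})

test_that("occurrence probability is the standardized upper tail and decreases strictly", {
  expect_equal(shape_probability(0), 0.5)
  d <- seq(0, 4, by = 0.1)
  expect_true(all(diff(shape_probability(d)) < 0))
  expect_error(shape_probability(-1), "non-negative")
  # chi-square variant: tail of the squared deviation with 3 df
  expect_equal(shape_probability_chisq(2), pchisq(4, 3, lower.tail = FALSE))
  expect_error(shape_probability_chisq(-0.5), "non-negative")
})

test_that("plausibility accepts the mean shape and rejects pierced geometry", {
  m <- make_sphere_model()
  mean_surf <- ssm_deform(m, numeric(0))
  ok <- plausibility_check(mean_surf, m)
  expect_true(ok$plausible)
  expect_null(ok$rejection_reason)

  # push one vertex out through the opposite wall: self-intersection
  bad <- mean_surf
  bad$points[50, ] <- -1.3 * bad$points[50, ]
  res <- plausibility_check(bad, m)
  expect_false(res$plausible)
  expect_match(res$rejection_reason, "self-intersection|normal flip")
})

test_that("faceless plausibility uses neighbourhood preservation", {
  m_nf <- make_sphere_model(with_faces = FALSE)
  mean_surf <- ssm_deform(m_nf, numeric(0))
  expect_true(plausibility_check(mean_surf, m_nf)$plausible)

  folded <- mean_surf
  idx <- 1:30
  folded$points[idx, ] <- -folded$points[idx, ]  # fold a patch to the far side
  res <- plausibility_check(folded, m_nf)
  expect_false(res$plausible)
  expect_match(res$rejection_reason, "fold")

  tiny <- surface(matrix(rnorm(15), ncol = 3) + 10, patient_id = "t",
                  label = "wall")
  expect_error(plausibility_check(tiny, m_nf), "fewer than 10")
})

test_that("virtual cohorts are plausible, bounded, probability-annotated and reproducible", {
  m <- make_sphere_model()
  expect_length(generate_cohort(m, m, n = 0, seed = 1), 0L)

  g1 <- generate_cohort(m, m, n = 6, seed = 5)
  g2 <- generate_cohort(m, m, n = 6, seed = 5)
  expect_equal(lapply(g1, function(v) v$wall$weights$weights),
               lapply(g2, function(v) v$wall$weights$weights))
  expect_equal(g1[[3]]$calc$surface$points, g2[[3]]$calc$surface$points)

  for (v in g1) {
    expect_true(v$wall$plausible && v$calc$plausible)
    expect_true(all(abs(v$wall$weights$weights) <= 2))
    # every emitted deviation is at least as probable as the 2-sigma bound
    expect_gte(v$wall$probability, shape_probability(2))
    expect_lte(v$wall$probability, 0.5)
  }
})

test_that("a plausible verdict cannot carry a rejection reason", {
  m <- make_sphere_model()
  s <- ssm_deform(m, numeric(0))
  expect_error(virtual_shape(s, NULL, plausible = TRUE,
                             rejection_reason = "nope"), "cannot carry")
})
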