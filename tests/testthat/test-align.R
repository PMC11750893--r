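test_that("identical shapes under random rigid motions align to identical rows", {
  P <- tube_cloud(500, seed = 1)
  surfaces <- lapply(1:3, function(i) {
    R <- random_rotation(i)
    moved <- sweep(P %*% t(R), 2, c(3 * i, -i, 2 * i), "+")
    surface(moved, patient_id = paste0("p", i), label = "wall")
  })
  ac <- align_cohort(surfaces)
  for (i in 2:3)
    expect_lt(max(abs(ac$X[i, ] - ac$X[1, ])), 0.01)
  expect_lte(ac$mean_iterations, 2L)
})

test_that("cohorts must have at least 3 surfaces and one label", {
  P <- tube_cloud(200, seed = 2)
  s1 <- surface(P, patient_id = "a", label = "wall")
  s2 <- surface(P + 1, patient_id = "b", label = "wall")
  expect_error(align_cohort(list(s1, s2)), "at least 3")
  s3 <- surface(P - 1, patient_id = "c", label = "calcification")
  expect_error(align_cohort(list(s1, s2, s3)), "mixed labels")
})

test_that("cohort alignment is equivariant under a common rigid motion", {
  coh <- tiny_cohort(n = 4, wall_points = 400, seed = 21)
  ac1 <- align_cohort(coh$walls, max_mean_iter = 2L)
  R <- random_rotation(99); shift <- c(10, -5, 3)
  common <- rigid_transform(rotation = R, translation = shift)
  moved <- lapply(coh$walls, apply_transform, tf = common)
  ac2 <- align_cohort(moved, max_mean_iter = 2L)
  # rows live in the template frame, which co-moves with the inputs: mapping
  # the second result back through the common motion must reproduce the first
  for (i in seq_along(moved)) {
    p2 <- apply_transform(matrix(ac2$X[i, ], ncol = 3, byrow = TRUE),
                          invert_transform(common))
    p1 <- matrix(ac1$X[i, ], ncol = 3, byrow = TRUE)
    expect_lt(mean(sqrt(rowSums((p1 - p2)^2))), 0.01)
  }
})

test_that("mean-shape re-alignment does not increase the subject-to-mean distance", {
  coh <- tiny_cohort(n = 5, wall_points = 500, seed = 31)
  ac <- align_cohort(coh$walls)
  d <- ac$subject_mean_distance
  if (length(d) > 1L)
    expect_true(all(diff(d) <= 0.01))
})

test_that("calcifications co-moved with their walls align without residual", {
  # all-zero latent SDs: every anatomy is identical up to its rigid motion,
  # so carrying each calcification with its wall transform must superpose them
  coh <- tiny_cohort(n = 4, wall_points = 500, calc_points = 350, seed = 41,
                     latent_sds = c(scale = 0, curvature = 0, annulus = 0,
                                    sinus_width = 0, plaque_volume = 0,
                                    plaque_gap = 0))
  ac <- align_cohort(coh$walls, max_mean_iter = 2L)
  cc <- align_calcifications(coh$calcs, ac)
  for (i in 2:4)
    expect_lt(mean(abs(cc$X[i, ] - cc$X[1, ])), 0.05)
  expect_equal(cc$ids, ac$ids)
})

test_that("the 120-degree leaflet search undoes a planted rotation", {
  coh <- tiny_cohort(n = 4, wall_points = 500, calc_points = 350, seed = 51,
                     latent_sds = c(scale = 0, curvature = 0, annulus = 0,
                                    sinus_width = 0, plaque_volume = 0,
                                    plaque_gap = 0),
                     rigid_motion = list(max_angle_deg = 0, max_shift_mm = 0))
  ac <- align_cohort(coh$walls, max_mean_iter = 2L)
  # rotate one subject's plaques 120 degrees about the root axis: the plaque
  # pattern lands on the neighbouring leaflet
  axis <- vcohort:::principal_axis(ac$template$points)
  pivot <- colMeans(ac$template$points)
  R120 <- vcohort:::rotation_about_axis(axis, 2 * pi / 3)
  calcs <- coh$calcs
  p <- sweep(sweep(calcs[[2]]$points, 2, pivot) %*% t(R120), 2, pivot, "+")
  calcs[[2]]$points <- p
  cc <- align_calcifications(calcs, ac)
  expect_lt(mean(abs(cc$X[2, ] - cc$X[1, ])), 0.5)
})

test_that("subject mismatch between calcifications and walls is rejected", {
  coh <- tiny_cohort(n = 4, wall_points = 400, calc_points = 300, seed = 61)
  ac <- align_cohort(coh$walls, max_mean_iter = 1L)
  bad <- coh$calcs[1:3]
  expect_error(align_calcifications(bad, ac), "do not match")
  wrong_label <- coh$walls
  expect_error(align_calcifications(wrong_label, ac), "calcification")
})
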