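test_that("annulus diameter matches analytic cylinders and scales linearly", {
  cyl <- cylinder_cloud(n = 6000, rx = 10, L = 40, seed = 1)
  d <- annulus_diameter(cyl)
  expect_equal(d, 20, tolerance = 0.02 * 20)
  expect_equal(annulus_diameter(cyl * 1.3), 26, tolerance = 0.02 * 26)
  # exact linearity under isotropic scaling (the band scales with the shape)
  expect_equal(annulus_diameter(cyl * 1.3, band_mm = 1.3) /
                 annulus_diameter(cyl, band_mm = 1), 1.3, tolerance = 1e-6)
})

test_that("annulus diameter of an elliptic section is the area-derived 2*sqrt(a*b)", {
  ell <- cylinder_cloud(n = 8000, rx = 10, ry = 12.5, L = 40, seed = 2)
  expect_equal(annulus_diameter(ell), 2 * sqrt(10 * 12.5),
               tolerance = 0.02 * 2 * sqrt(10 * 12.5))
})

test_that("annulus measurement rejects inadequate inputs", {
  expect_error(annulus_diameter(matrix(rnorm(30), ncol = 3)), "at least 100")
})

test_that("calcification volume recovers analytic ball volumes and is additive", {
  b1 <- ball_cloud(5000, r = 5, seed = 3)
  v_ball <- 4 / 3 * pi * 125
  expect_equal(calcification_volume(b1), v_ball, tolerance = 0.10 * v_ball)

  b2 <- ball_cloud(5000, r = 4, center = c(30, 0, 0), seed = 4)
  v2 <- 4 / 3 * pi * 64
  both <- rbind(b1, b2)
  expect_equal(calcification_volume(both), v_ball + v2,
               tolerance = 0.10 * (v_ball + v2))

  expect_equal(calcification_volume(matrix(numeric(0), ncol = 3)), 0)
  # sparse scatter is filtered out entirely
  expect_equal(calcification_volume(matrix(runif(30, 0, 100), ncol = 3)), 0)
})

test_that("calcification volume is invariant under rigid motion", {
  b <- ball_cloud(2000, r = 5, seed = 5)
  v0 <- calcification_volume(b)
  moved <- sweep(b %*% t(random_rotation(6)), 2, c(12, -7, 3), "+")
  expect_equal(calcification_volume(moved), v0, tolerance = 1e-6 * v0)
})

test_that("convex hull volume handles exact and degenerate bodies", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  expect_equal(hull_volume(cube), 27, tolerance = 1e-10)
  inside <- rbind(cube, matrix(runif(90, 0.1, 2.9), ncol = 3))
  expect_equal(hull_volume(inside), 27, tolerance = 1e-10)
  flat <- cbind(runif(50), runif(50), 1)
  expect_equal(hull_volume(flat), 0)
  expect_equal(hull_volume(cube[1:3, ]), 0)
})

test_that("cohort comparison reproduces exact Mann-Whitney enumeration", {
  # canonical extreme case: complete separation of two triples
  r1 <- compare_cohorts(data.frame(annulus_mm = c(1, 2, 3)),
                        data.frame(annulus_mm = c(4, 5, 6)))
  expect_equal(unname(r1$tests$annulus_mm$U), 0)
  expect_equal(r1$tests$annulus_mm$p, 0.1)
  expect_equal(r1$tests$annulus_mm$p, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  # identical groups are maximally non-significant
  same <- data.frame(annulus_mm = c(1, 2, 3, 4))
  expect_equal(compare_cohorts(same, same)$tests$annulus_mm$p, 1,
               tolerance = 0.05)

  # full-enumeration agreement across group sizes up to 8 (untied samples)
  set.seed(7)
  for (nx in c(3, 5, 8)) for (ny in c(3, 6, 8)) {
    x <- rnorm(nx); y <- rnorm(ny, mean = 0.5)
    got <- compare_cohorts(data.frame(annulus_mm = x),
                           data.frame(annulus_mm = y))$tests$annulus_mm$p
    expect_equal(got, mw_enum_p(x, y), tolerance = 1e-12,
                 label = sprintf("p for sizes %d vs %d", nx, ny))
  }

  expect_error(compare_cohorts(data.frame(annulus_mm = 1:2),
                               data.frame(annulus_mm = 1:5)), "at least 3")
  expect_error(compare_cohorts(data.frame(z = 1:5), data.frame(z = 1:5)),
               "no shared measurement")
})

test_that("quartile summaries are ordered and attached per group", {
  r <- compare_cohorts(data.frame(annulus_mm = rnorm(20, 23)),
                       data.frame(annulus_mm = rnorm(30, 23.5)))
  q <- r$tests$annulus_mm$real_quartiles
  expect_true(all(diff(q) >= 0))
  expect_length(r$tests$annulus_mm$synthetic_quartiles, 5L)
})
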