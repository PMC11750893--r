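test_that("the generator is bit-reproducible from its config", {
  cfg <- synth_config(n_patients = 4, wall_points = 300, calc_points = 200,
                      seed = 7)
  c1 <- synth_cohort(cfg)
  c2 <- synth_cohort(cfg)
  expect_identical(c1$walls[[2]]$points, c2$walls[[2]]$points)
  expect_identical(c1$calcs[[4]]$points, c2$calcs[[4]]$points)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth$latents, c2$truth$latents)
})

test_that("zero latent variability yields identical anatomies up to rigid motion", {
  cfg <- synth_config(n_patients = 4, wall_points = 400, calc_points = 300,
                      seed = 2,
                      latent_sds = c(scale = 0, curvature = 0, annulus = 0,
                                     sinus_width = 0, plaque_volume = 0,
                                     plaque_gap = 0))
  coh <- synth_cohort(cfg)
  tf <- rigid_icp(coh$walls[[1]], coh$walls[[2]])
  expect_lt(tf$rms, 1e-8)
  # after alignment the cohort carries no real shape variance
  ac <- align_cohort(coh$walls, max_mean_iter = 2L)
  m <- ssm_fit(ac)
  expect_lt(sum(m$variances), 1e-6)
})

test_that("the clinical table reproduces the target peak-gradient moments", {
  coh <- synth_cohort(synth_config(seed = 123))   # n = 68 default
  pg <- coh$clinical$peak_gradient
  n <- length(pg)
  expect_equal(n, 68L)
  se_mean <- 14.59 / sqrt(n)
  se_sd <- 14.59 / sqrt(2 * n)
  expect_lt(abs(mean(pg) - 79.11), 2 * se_mean)
  expect_lt(abs(sd(pg) - 14.59), 2 * se_sd)
  expect_true(all(coh$clinical$device_size %in% c(23L, 26L)))
  expect_true(all(coh$clinical$ava > 0))
  # derived quantities stay internally consistent
  expect_equal(coh$clinical$bmi,
               coh$clinical$mass / (coh$clinical$height / 100)^2)
  expect_equal(coh$clinical$jet_velocity, sqrt(pg / 4))
})

test_that("latent sample moments match the configuration within Monte-Carlo error", {
  cfg <- synth_config(n_patients = 68, wall_points = 300, calc_points = 200,
                      seed = 31)
  Z <- synth_cohort(cfg)$truth$latents
  for (j in colnames(Z)) {
    expect_lt(abs(mean(Z[, j])), 3 / sqrt(68))
    expect_lt(abs(sd(Z[, j]) - 1), 3 / sqrt(2 * 68))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_patients = 0), "positive")
  expect_error(synth_config(wall_points = 2), "at least 4")
  expect_error(synth_config(latent_sds = c(scale = -1, curvature = 1,
                                           annulus = 1, sinus_width = 1,
                                           plaque_volume = 1, plaque_gap = 1)),
               "non-negative")
  expect_error(synth_config(device_rule = list(annulus_threshold_mm = 23,
                                               label_noise = 0.6)),
               "label_noise")
})

test_that("the end-to-end benchmark recovers the generative latents", {
  cfg <- synth_config(n_patients = 30, wall_points = 800, calc_points = 400,
                      seed = 5)
  rb <- recovery_benchmark(cfg, max_mean_iter = 3L)
  # scale and annulus latents must surface among the leading modes
  expect_gte(rb$best_r[["annulus"]], 0.8)
  expect_gte(rb$best_r[["scale"]], 0.85)
  expect_true(all(rb$best_mode[c("scale", "annulus")] <= 10))
})
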