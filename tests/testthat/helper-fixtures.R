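# Geometric fixtures built in code; all deterministic given their seeds.

# unit tetrahedron as points + faces
tetrahedron <- function() {
  list(points = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# structured triangulated sphere (no poles, so all faces are proper)
sphere_mesh <- function(n = 14, r = 20) {
  u <- seq(0.1, pi - 0.1, length.out = n)
  v <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  idx <- function(iu, iv) (iu - 1L) * (2L * n) + ((iv - 1L) %% (2L * n)) + 1L
  pts <- matrix(NA_real_, n * 2 * n, 3)
  for (iu in 1:n) for (iv in 1:(2 * n))
    pts[idx(iu, iv), ] <- r * c(sin(u[iu]) * cos(v[iv]),
                                sin(u[iu]) * sin(v[iv]), cos(u[iu]))
  f <- matrix(NA_integer_, 2 * (n - 1) * 2 * n, 3)
  k <- 0L
  for (iu in 1:(n - 1)) for (iv in 1:(2 * n)) {
    a <- idx(iu, iv); b <- idx(iu + 1, iv)
    cc <- idx(iu + 1, iv + 1); d <- idx(iu, iv + 1)
    f[k + 1L, ] <- c(a, b, cc); f[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  list(points = pts, faces = f)
}

# lateral surface of a cylinder (optionally elliptic), axis = z
cylinder_cloud <- function(n = 5000, rx = 10, ry = rx, L = 40, seed = 1) {
  set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  cbind(rx * cos(th), ry * sin(th), stats::runif(n, 0, L))
}

# uniform points inside a ball
ball_cloud <- function(n = 3000, r = 5, center = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * r * stats::runif(n)^(1 / 3)
  sweep(u, 2, center, "+")
}

# anisotropic structured cloud with enough features for ICP to lock onto
tube_cloud <- function(n = 800, seed = 1) {
  set.seed(seed)
  v <- stats::runif(n); th <- stats::runif(n, 0, 2 * pi)
  r <- 8 + 3 * exp(-((v - 0.3) / 0.1)^2) * (0.6 + 0.4 * cos(3 * th))
  cbind(r * cos(th), r * sin(th), 50 * v)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi / 6)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# wrap a raw coordinate-row matrix as an aligned cohort (for SSM unit tests
# that need no registration); built directly so toy matrices with fewer than
# 4 "points" per row are allowed
cohort_from_rows <- function(X, label = "wall") {
  m <- ncol(X) / 3
  template <- structure(
    list(points = matrix(X[1, ], ncol = 3, byrow = TRUE), faces = NULL,
         patient_id = "template", label = label, source_path = NA_character_),
    class = "surface")
  aligned_cohort(template, X, sprintf("s%02d", seq_len(nrow(X))),
                 transforms = replicate(nrow(X), rigid_transform(),
                                        simplify = FALSE),
                 label = label)
}

# small synthetic anatomy cohort for integration-style tests
tiny_cohort <- function(n = 6, wall_points = 600, calc_points = 450, seed = 11,
                        ...) {
  synth_cohort(synth_config(n_patients = n, wall_points = wall_points,
                            calc_points = calc_points, seed = seed, ...))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  mid <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

expect_no_error <- function(expr) expect_error(expr, NA)
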