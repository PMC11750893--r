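# Minimal Bayesian optimization: Gaussian-process surrogate
# (kernlab::gausspr with a predictive-variance model) + expected improvement
# over a box, used to tune SVM hyperparameters. Deterministic given the seed.
#
# f: function(numeric vector in box) -> scalar loss to MINIMIZE
# lower/upper: box bounds (search happens in these coordinates; callers put
# log10-scaled parameters here)
# n_init: initial space-filling evaluations; n_iter: EI-guided evaluations.
bayes_optimize <- function(f, lower, upper, n_init = 8L, n_iter = 12L,
                           seed = 1L, n_candidates = 512L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  X <- with_seed(seed, {
    # stratified (jittered-grid) initial design
    u <- matrix(stats::runif(n_init * d), n_init, d)
    strat <- (matrix(rep(sample.int(n_init) - 1L, d), n_init, d) + u) / n_init
    sweep(sweep(strat, 2, upper - lower, "*"), 2, lower, "+")
  })
  y <- apply(X, 1, f)

  for (it in seq_len(n_iter)) {
    Xs <- scale(X)
    ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    gp <- tryCatch(
      kernlab::gausspr(Xs, y, kernel = "rbfdot", variance.model = TRUE,
                       var = 1e-4, tol = 1e-6, scaled = FALSE),
      error = function(e) NULL)
    cand <- with_seed(seed + 7919L * it, {
      m <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      sweep(sweep(m, 2, upper - lower, "*"), 2, lower, "+")
    })
    if (is.null(gp)) {
      xnew <- cand[1, ]
    } else {
      cs <- sweep(sweep(cand, 2, ctr), 2, scl, "/")
      mu <- as.numeric(kernlab::predict(gp, cs))
      sd <- suppressWarnings(as.numeric(kernlab::predict(gp, cs, type = "sdeviation")))
      sd[!is.finite(sd) | sd < 1e-12] <- 1e-12
      best <- min(y)
      z <- (best - mu) / sd
      ei <- sd * (z * stats::pnorm(z) + stats::dnorm(z))
      xnew <- cand[which.max(ei), ]
    }
    X <- rbind(X, xnew)
    y <- c(y, f(xnew))
  }
  i <- which.min(y)
  list(par = X[i, ], value = y[i], X = X, y = y)
}
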