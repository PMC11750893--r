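make_scores <- function(n = 68, K = 20, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * K), n, K) %*% diag(seq(3, 0.5, length.out = K))
}

test_that("correlations with clinical variables match the textbook formula", {
  S <- make_scores(30, 5, seed = 2)
  clin <- data.frame(v = S[, 3])
  res <- correlate(S, clin, "v")
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_equal(res$mode[1], 3L)
  expect_lt(res$p[1], 1e-12)

  clin$neg <- -S[, 2]
  res2 <- correlate(S, clin, "neg")
  expect_equal(res2$r[1], -1, tolerance = 1e-12)

  # 6-point hand dataset against the direct formula
  x <- c(1, 2, 4, 5, 7, 9); y <- c(2.1, 2.6, 3.9, 6.0, 6.2, 8.8)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res3 <- correlate(matrix(x, ncol = 1), data.frame(v = y), "v")
  expect_equal(res3$r[1], r_direct, tolerance = 1e-12)

  expect_error(correlate(S, data.frame(v = rep(1, 30)), "v"), "zero variance")
  expect_error(correlate(S, data.frame(v = c(1, 2, NA, NA)), "w"), "not in")
})

test_that("results are sorted by absolute correlation with missing values dropped pairwise", {
  S <- make_scores(40, 6, seed = 3)
  y <- 2 * S[, 4] + rnorm(40, sd = 3)
  y[c(5, 9)] <- NA
  res <- correlate(S, data.frame(v = y), "v")
  expect_equal(res$mode[1], 4L)
  expect_true(all(diff(abs(res$r)) <= 1e-12))
})

test_that("F-score selection always finds a strongly planted mode", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 40
    lab <- rep(c(23, 26), each = n / 2)
    S <- matrix(rnorm(n * 8), n, 8)
    S[, 5] <- S[, 5] + ifelse(lab == 26, 5, 0)   # 5-SD class separation
    f_score_select(S, lab, n_select = 1)[1] == 5L
  }, logical(1))
  expect_true(all(hits))
})

test_that("the F statistic equals the one-way ANOVA oracle", {
  set.seed(4)
  x <- rnorm(30); g <- factor(rep(c("a", "b"), 15))
  f_pkg <- vcohort:::anova_f(x, g)
  f_aov <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(f_pkg, f_aov, tolerance = 1e-10)
  expect_error(f_score_select(matrix(rnorm(12), 6), c(1, 1, 1, 1, 1, 2)),
               "at least 2")
})

test_that("no mode is systematically favoured under label-independent noise", {
  top <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    S <- matrix(rnorm(40 * 10), 40, 10)
    lab <- sample(rep(c(23, 26), 20))
    f_score_select(S, lab, n_select = 1)[1]
  }, integer(1))
  # 60 draws over 10 modes: no index should dominate
  expect_lt(max(table(factor(top, levels = 1:10))), 20)
})

test_that("SVM regression is essentially exact on a noiseless realizable target", {
  S <- make_scores(60, 8, seed = 5)
  y <- 50 + 4 * S[, 1]
  rr <- svm_regress(S, y, folds = 10, tuning_iters = 12, seed = 2)
  expect_gt(rr$r_squared, 0.99)
  expect_equal(rr$selected_modes[1], 1L)
  expect_equal(nrow(rr$predictions), 60L)
  expect_error(svm_regress(S, rep(1, 60)), "constant target")
  expect_error(svm_regress(S[1:20, ], y[1:20], folds = 10), "per fold")
})

test_that("SVM regression is bitwise reproducible for a fixed seed", {
  S <- make_scores(40, 6, seed = 6)
  y <- 70 + 3 * S[, 2] + rnorm(40, sd = 4)
  r1 <- svm_regress(S, y, folds = 5, tuning_iters = 4, seed = 9)
  r2 <- svm_regress(S, y, folds = 5, tuning_iters = 4, seed = 9)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_identical(r1$cv_rmse, r2$cv_rmse)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("a permuted target carries no out-of-fold signal", {
  r2 <- vapply(1:8, function(s) {
    S <- make_scores(50, 8, seed = s)
    y0 <- 60 + 3 * S[, 1] + rnorm(50, 2)
    set.seed(s)
    svm_regress(S, sample(y0), folds = 10, tuning_iters = 3,
                seed = s)$r_squared
  }, numeric(1))
  expect_true(all(abs(r2) < 0.15))
})

test_that("classifiers separate separable classes and report coherent metrics", {
  set.seed(11)
  n <- 60
  lab <- rep(c(23, 26), each = n / 2)
  S <- matrix(rnorm(n * 8), n, 8)
  S[, 3] <- S[, 3] + ifelse(lab == 26, 6, 0)
  res <- classify_device_size(S, lab, seed = 1)
  for (fam in c("mlp", "logistic", "knn", "svm")) {
    expect_gte(res[[fam]]$auroc, 0.95)
    cm <- res[[fam]]$confusion_matrix
    expect_equal(sum(cm), length(res$test_index))
    # precision/recall recomputed from the matrix match the reported values
    expect_equal(unname(res[[fam]]$recall), unname(diag(cm) / rowSums(cm)))
    expect_equal(unname(res[[fam]]$precision), unname(diag(cm) / colSums(cm)))
    expect_equal(res[[fam]]$accuracy, sum(diag(cm)) / sum(cm))
  }
  # determinism
  res2 <- classify_device_size(S, lab, seed = 1)
  expect_identical(res$mlp$confusion_matrix, res2$mlp$confusion_matrix)
  expect_identical(res$svm$scores, res2$svm$scores)
})

test_that("random labels give chance-level AUROC", {
  aurocs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    S <- matrix(rnorm(60 * 8), 60, 8)
    lab <- sample(rep(c(23, 26), 30))
    classify_device_size(S, lab, seed = s)$logistic$auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.15)
})

test_that("classification rejects inadequate class sizes", {
  S <- matrix(rnorm(40 * 5), 40, 5)
  expect_error(classify_device_size(S, c(rep(23, 37), rep(26, 3))),
               "at least 5")
  expect_error(classify_device_size(S, rep(23, 40)), "two classes")
})
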