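#' Pearson correlation of shape-mode scores with a clinical variable
#'
#' One correlation per mode, with the two-sided t-based p-value; rows with a
#' missing clinical value are dropped pairwise. Modes are returned sorted by
#' decreasing `|r|`. Zero-variance inputs are flagged and excluded rather
#' than reported as NA correlations.
#'
#' @param scores subjects x modes score matrix ([mode_scores()]).
#' @param clinical data frame of clinical records, one row per subject, in
#'   the same order as `scores`.
#' @param variable name of the clinical column to correlate.
#' @return data frame with columns `mode`, `r`, `p`, sorted by `|r|`.
#' @export
correlate <- function(scores, clinical, variable) {
  scores <- as.matrix(scores)
  if (!variable %in% names(clinical))
    stop("variable '", variable, "' not in the clinical table", call. = FALSE)
  y <- clinical[[variable]]
  ok <- is.finite(y)
  if (sum(ok) < 4L)
    stop("need at least 4 complete pairs", call. = FALSE)
  y <- y[ok]
  S <- scores[ok, , drop = FALSE]
  if (stats::var(y) == 0)
    stop("variable '", variable, "' has zero variance; correlation undefined",
         call. = FALSE)
  res <- lapply(seq_len(ncol(S)), function(j) {
    if (stats::var(S[, j]) == 0) return(NULL)  # flat mode: excluded
    ct <- stats::cor.test(S[, j], y)
    data.frame(mode = j, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' SVM regression of a functional target on shape modes
#'
#' Predicts a clinical target (canonically the transvalvular peak pressure
#' gradient, mmHg) from shape-mode scores: the `n_select` modes with the
#' largest absolute Pearson correlation with the target are kept, and a
#' polynomial-kernel support-vector regression is tuned by Bayesian
#' optimization (Gaussian-process surrogate, expected improvement) over
#' `log10(C) in [-2, 3]`, `log10(gamma) in [-3, 1]` and `degree in {2, 3, 4}`,
#' minimizing the k-fold cross-validated RMSE. Reported R-squared comes in
#' two flavours: `r_squared` from the out-of-fold predictions (predictive)
#' and `r_squared_refit` from re-fitting on all data (in-sample).
#'
#' @param scores subjects x modes score matrix.
#' @param target numeric response vector.
#' @param n_select number of modes kept by |Pearson r| (default 6).
#' @param folds cross-validation folds (default 10).
#' @param tuning_iters EI-guided tuning evaluations after the initial design.
#' @param seed integer seed controlling folds and tuning.
#' @return a `regression_result`: list with `selected_modes`,
#'   `hyperparameters` (C, degree, gamma), `cv_rmse` (mmHg), `r_squared`,
#'   `r_squared_refit`, `predictions` (true, predicted out-of-fold).
#' @export
svm_regress <- function(scores, target, n_select = 6L, folds = 10L,
                        tuning_iters = 12L, seed = 1L) {
  scores <- as.matrix(scores)
  target <- as.numeric(target)
  n <- nrow(scores)
  stopifnot(length(target) == n)
  if (stats::var(target) == 0)
    stop("regression error: constant target", call. = FALSE)
  if (n < 3L * folds)
    stop("need at least 3 subjects per fold (n >= ", 3L * folds, ")",
         call. = FALSE)

  n_select <- min(n_select, ncol(scores))
  r <- abs(apply(scores, 2, function(s)
    if (stats::var(s) == 0) 0 else stats::cor(s, target)))
  selected <- order(-r)[seq_len(n_select)]
  Xs <- scores[, selected, drop = FALSE]

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_rmse <- function(C, gamma, degree) {
    pred <- numeric(n)
    for (k in seq_len(folds)) {
      te <- fold_id == k
      fit <- e1071::svm(Xs[!te, , drop = FALSE], target[!te],
                        type = "eps-regression", kernel = "polynomial",
                        cost = C, gamma = gamma, degree = degree, coef0 = 1,
                        scale = TRUE)
      pred[te] <- stats::predict(fit, Xs[te, , drop = FALSE])
    }
    list(rmse = sqrt(mean((pred - target)^2)), pred = pred)
  }

  opt <- bayes_optimize(
    function(par) cv_rmse(10^par[1], 10^par[2], round(par[3]))$rmse,
    lower = c(-2, -3, 1.51), upper = c(3, 1, 4.49),
    n_init = 8L, n_iter = tuning_iters, seed = seed)
  C <- 10^opt$par[1]; gamma <- 10^opt$par[2]; degree <- round(opt$par[3])

  best <- cv_rmse(C, gamma, degree)
  ssr <- sum((best$pred - target)^2)
  sst <- sum((target - mean(target))^2)
  refit <- e1071::svm(Xs, target, type = "eps-regression",
                      kernel = "polynomial", cost = C, gamma = gamma,
                      degree = degree, coef0 = 1, scale = TRUE)
  pred_in <- stats::predict(refit, Xs)
  structure(
    list(selected_modes = selected,
         hyperparameters = list(C = C, degree = degree, gamma = gamma),
         cv_rmse = best$rmse,
         r_squared = 1 - ssr / sst,
         r_squared_refit = 1 - sum((pred_in - target)^2) / sst,
         predictions = data.frame(true = target, predicted = best$pred),
         model = refit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> modes {%s}; C = %.3f, degree = %d, gamma = %.3f\n",
              paste(x$selected_modes, collapse = ", "),
              x$hyperparameters$C, x$hyperparameters$degree,
              x$hyperparameters$gamma))
  cat(sprintf("  CV RMSE = %.2f, out-of-fold R^2 = %.3f (refit-on-all R^2 = %.3f)\n",
              x$cv_rmse, x$r_squared, x$r_squared_refit))
  invisible(x)
}

#' F-score feature selection for a binary label
#'
#' One-way ANOVA F statistic (between-class over within-class variance) per
#' mode; the `n_select` modes with the largest F are returned in descending
#' order.
#'
#' @param scores subjects x modes score matrix.
#' @param labels binary label vector (factor or 2-valued).
#' @param n_select number of modes to return (default 6).
#' @return integer vector of mode indices, descending F.
#' @export
f_score_select <- function(scores, labels, n_select = 6L) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 members", call. = FALSE)
  Fs <- apply(scores, 2, function(s) anova_f(s, labels))
  n_select <- min(n_select, ncol(scores))
  order(-Fs)[seq_len(n_select)]
}

# one-way ANOVA F, vector form
anova_f <- function(x, g) {
  gm <- tapply(x, g, mean)
  ng <- tapply(x, g, length)
  grand <- mean(x)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((x - gm[g])^2)
  dfb <- nlevels(g) - 1L
  dfw <- length(x) - nlevels(g)
  if (ssw <= 0) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}

#' Device-size classification from shape modes
#'
#' Trains the four classifier families (multilayer perceptron, logistic
#' regression, k-nearest neighbours, support vector machine) to predict a
#' binary device-size label from F-score-selected mode scores, on a
#' stratified 70/30 train/test split. Each family reports accuracy, per-class
#' recall and precision, AUROC from its test-set scores, the confusion
#' matrix, and ROC points. The MLP is a single-hidden-layer network with
#' twice as many hidden units as features.
#'
#' @param scores subjects x modes score matrix.
#' @param labels binary label vector (e.g. device size 23 vs 26 mm); each
#'   class needs at least 5 members.
#' @param n_select modes kept by F-score (default 6).
#' @param test_fraction held-out fraction (default 0.30).
#' @param seed integer seed for the split and the MLP initialisation.
#' @return a `classification_result`: named list (`mlp`, `logistic`, `knn`,
#'   `svm`) of per-model metric lists, plus `selected_modes` and `test_index`.
#' @export
classify_device_size <- function(scores, labels, n_select = 6L,
                                 test_fraction = 0.30, seed = 1L) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) < 5L))
    stop("each class needs at least 5 members", call. = FALSE)
  lv <- levels(labels)

  selected <- f_score_select(scores, labels, n_select)
  Xs <- scale(scores[, selected, drop = FALSE])
  n <- nrow(Xs)

  # stratified split; re-split with incremented seed if a class is missing
  # from the test set (can only happen at extreme fractions)
  split_seed <- seed
  repeat {
    te <- with_seed(split_seed, {
      idx <- unlist(lapply(lv, function(l) {
        cls <- which(labels == l)
        sample(cls, max(1L, round(test_fraction * length(cls))))
      }))
      sort(idx)
    })
    if (length(unique(labels[te])) == 2L && length(te) < n) break
    split_seed <- split_seed + 1L
  }
  tr <- setdiff(seq_len(n), te)
  xtr <- Xs[tr, , drop = FALSE]; xte <- Xs[te, , drop = FALSE]
  ytr <- labels[tr]; yte <- labels[te]

  # each family returns P(class = lv[2]) on the test set
  fams <- list(
    mlp = function() {
      fit <- with_seed(seed, nnet::nnet(
        xtr, class.ind01(ytr), size = 2L * ncol(xtr), decay = 0.01,
        maxit = 500, entropy = TRUE, trace = FALSE))
      as.numeric(stats::predict(fit, xte))
    },
    logistic = function() {
      df <- data.frame(y = as.integer(ytr == lv[2]), xtr)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      as.numeric(stats::predict(fit, data.frame(xte), type = "response"))
    },
    knn = function() {
      k <- min(5L, length(tr))
      pr <- class::knn(xtr, xte, ytr, k = k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == lv[2], p_win, 1 - p_win)
    },
    svm = function() {
      fit <- with_seed(seed, e1071::svm(xtr, ytr, kernel = "radial",
                                        probability = TRUE, scale = FALSE))
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, lv[2]]
    }
  )

  results <- lapply(fams, function(fam) {
    p2 <- fam()
    pred <- factor(ifelse(p2 >= 0.5, lv[2], lv[1]), levels = lv)
    cm <- table(truth = yte, predicted = pred)
    roc <- suppressMessages(pROC::roc(response = yte, predictor = p2,
                                      levels = lv, direction = "<"))
    list(
      accuracy = mean(pred == yte),
      recall = stats::setNames(diag(cm) / pmax(rowSums(cm), 1L), lv),
      precision = stats::setNames(diag(cm) / pmax(colSums(cm), 1L), lv),
      auroc = as.numeric(pROC::auc(roc)),
      confusion_matrix = cm,
      roc_points = data.frame(fpr = 1 - roc$specificities,
                              tpr = roc$sensitivities),
      scores = p2
    )
  })
  structure(c(results,
              list(selected_modes = selected, test_index = te,
                   classes = lv)),
            class = "classification_result")
}

class.ind01 <- function(y) as.integer(y == levels(y)[2])

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> test n =", length(x$test_index),
      " classes:", paste(x$classes, collapse = " vs "), "\n")
  for (m in c("mlp", "logistic", "knn", "svm"))
    cat(sprintf("  %-8s accuracy %.3f  AUROC %.3f\n",
                m, x[[m]]$accuracy, x[[m]]$auroc))
  invisible(x)
}
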