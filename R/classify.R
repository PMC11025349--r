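#' Stratified train/test split of a feature table
#'
#' @param table data frame with a `label` column in
#'   \{"benign", "malignant"\}.
#' @param ratio train fraction (default 0.8).
#' @param seed integer seed.
#' @return list(train, test) preserving class proportions.
#' @export
split_table <- function(table, ratio = 0.8, seed = 1L) {
  if (nrow(table) < 5) stop("split_table: need at least 5 rows")
  if (length(unique(table$label)) < 2)
    stop("split_table: both classes must be present")
  with_seed(seed, {
    tr_idx <- unlist(lapply(unique(table$label), function(l) {
      idx <- which(table$label == l)
      idx[sample.int(length(idx), round(ratio * length(idx)))]
    }))
    tr_idx <- sort(tr_idx)
    list(train = table[tr_idx, , drop = FALSE],
         test = table[-tr_idx, , drop = FALSE])
  })
}

feature_matrix <- function(table) {
  drop <- intersect(c("label", "id", "empty_flag"), names(table))
  as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
}

CLASSIFIER_NAMES <- c("DT", "LR", "SVM", "KNN", "RF", "XGB", "AdaBoost")

#' Train the seven benign/malignant classifiers
#'
#' Decision tree (rpart), logistic regression (glm), SVM with RBF kernel
#' (e1071), k-nearest neighbours (class), random forest (randomForest),
#' gradient-boosted trees (xgboost) and AdaBoost (discrete AdaBoost.M1 with
#' depth-1 rpart stumps, implemented here). Features are standardized (fit
#' on the training set only) for the scale-sensitive models (LR, SVM, KNN);
#' tree ensembles consume raw features. Zero-variance features are dropped
#' with a warning. Hyperparameters are common defaults with fixed seeds.
#'
#' @param train training feature table with a binary `label` column.
#' @param seed integer seed controlling every stochastic fit.
#' @return a `classifier_bank`.
#' @export
train_classifiers <- function(train, seed = 1L) {
  stopifnot(length(unique(train$label)) == 2)
  y <- factor(train$label, levels = c("benign", "malignant"))
  X <- feature_matrix(train)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  if (any(!keep))
    warning("train_classifiers: dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  Xs <- scale(X, center, scale_)
  df <- data.frame(X, check.names = FALSE)
  df$label <- y
  dfs <- data.frame(Xs, check.names = FALSE)
  dfs$label <- y

  models <- list()
  with_seed(seed, {
    models$DT <- rpart::rpart(label ~ ., data = df, method = "class")
    models$LR <- suppressWarnings(
      glm(label ~ ., data = dfs, family = binomial()))
    models$SVM <- e1071::svm(label ~ ., data = dfs, probability = TRUE,
                             kernel = "radial")
    models$KNN <- list(train = Xs, labels = y, k = 5L)  # lazy learner
    models$RF <- randomForest::randomForest(label ~ ., data = df,
                                            ntree = 200)
    models$XGB <- xgboost::xgboost(x = X, y = y, nrounds = 50,
                                   max_depth = 3, nthreads = 1)
    models$AdaBoost <- adaboost_fit(X, y, n_rounds = 50)
  })
  structure(list(models = models, center = center, scale = scale_,
                 features = colnames(X), classes = levels(y),
                 seed = as.integer(seed)),
            class = "classifier_bank")
}

#' Malignancy scores of every classifier on new data
#'
#' @param bank a `classifier_bank`.
#' @param table feature table.
#' @return matrix (rows x classifiers) of malignant-class probabilities.
#' @export
predict_scores <- function(bank, table) {
  X <- feature_matrix(table)[, bank$features, drop = FALSE]
  Xs <- scale(X, bank$center, bank$scale)
  df <- data.frame(X, check.names = FALSE)
  dfs <- data.frame(Xs, check.names = FALSE)
  m <- bank$models
  knn_pred <- class::knn(m$KNN$train, Xs, m$KNN$labels, k = m$KNN$k,
                         prob = TRUE)
  knn_p <- attr(knn_pred, "prob")
  scores <- cbind(
    DT = predict(m$DT, df, type = "prob")[, "malignant"],
    LR = suppressWarnings(predict(m$LR, dfs, type = "response")),
    SVM = attr(predict(m$SVM, dfs, probability = TRUE),
               "probabilities")[, "malignant"],
    KNN = ifelse(knn_pred == "malignant", knn_p, 1 - knn_p),
    RF = predict(m$RF, df, type = "prob")[, "malignant"],
    XGB = predict(m$XGB, X),
    AdaBoost = adaboost_score(m$AdaBoost, X))
  rownames(scores) <- NULL
  scores
}

#' ROC curve by score-threshold sweep
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels binary truth (1/TRUE = positive class).
#' @return data frame of (fpr, tpr) points from (0,0) to (1,1),
#'   non-decreasing in both coordinates.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels %in% c(1, TRUE, "malignant"))
  if (all(y == 1) || all(y == 0)) stop("roc_curve: need both classes")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # collapse tied scores
  data.frame(fpr = c(0, fp[last] / sum(y == 0)),
             tpr = c(0, tp[last] / sum(y == 1)))
}

#' Area under the ROC curve (trapezoid rule)
#' @inheritParams roc_curve
#' @return AUC in \[0,1\].
#' @export
auc_trapezoid <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Evaluate the classifier bank on a test table
#'
#' ROC by threshold sweep, AUC by trapezoid rule, 95% CI by stratified
#' percentile bootstrap over test rows, and accuracy at the 0.5 threshold.
#'
#' @param bank a `classifier_bank`.
#' @param test test feature table (both classes present).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap.
#' @return a `classifier_report`: list per algorithm with `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `accuracy`, `roc`; plus
#'   `feature_importance` (AdaBoost) and `n_test`.
#' @export
evaluate_classifiers <- function(bank, test, n_boot = 2000, seed = 1L) {
  y <- factor(test$label, levels = bank$classes)
  if (length(unique(y)) < 2)
    stop("evaluate_classifiers: test set must contain both classes")
  scores <- predict_scores(bank, test)
  ybin <- as.integer(y == "malignant")
  pos <- which(ybin == 1)
  neg <- which(ybin == 0)
  per_algo <- lapply(colnames(scores), function(a) {
    s <- scores[, a]
    auc <- auc_trapezoid(s, ybin)
    cis <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
        auc_trapezoid(s[idx], ybin[idx])
      }, numeric(1))
    })
    ci <- unname(quantile(cis, c(0.025, 0.975)))
    list(name = a, auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
         accuracy = mean((s > 0.5) == (ybin == 1)),
         roc = roc_curve(s, ybin))
  })
  names(per_algo) <- colnames(scores)
  structure(list(algorithms = per_algo,
                 feature_importance =
                   feature_importance(bank$models$AdaBoost),
                 n_test = nrow(test)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report on", x$n_test, "test samples\n")
  for (a in x$algorithms)
    cat(sprintf("  %-8s AUC %.3f (95%% CI %.3f-%.3f)  accuracy %.2f\n",
                a$name, a$auc, a$auc_ci_low, a$auc_ci_high, a$accuracy))
  top <- head(x$feature_importance, 3)
  cat("  top AdaBoost features:",
      paste(sprintf("%s (%.2f)", top$feature, top$weight), collapse = ", "),
      "\n")
  invisible(x)
}

# ---- discrete AdaBoost.M1 with rpart stumps -------------------------------

adaboost_fit <- function(X, y, n_rounds = 50) {
  n <- nrow(X)
  stopifnot(n >= 2, nlevels(y) == 2)
  w <- rep(1 / n, n)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- y
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, minsplit = 2, cp = -1, xval = 0))
    pred <- predict(fit, df, type = "class")
    mis <- as.numeric(pred != y)
    err <- sum(w * mis)
    if (err >= 0.5) break               # stump no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
    if (err <= 1e-10) break             # perfect stump
  }
  if (!length(stumps))
    stop("adaboost_fit: no stump beat chance; degenerate training data")
  list(stumps = stumps, alphas = alphas, classes = levels(y),
       features = colnames(X))
}

# score in [0,1]: weighted vote margin mapped linearly, 0.5 = decision line
adaboost_score <- function(model, X) {
  df <- data.frame(X, check.names = FALSE)
  votes <- vapply(seq_along(model$stumps), function(m) {
    p <- predict(model$stumps[[m]], df, type = "class")
    ifelse(p == model$classes[2], 1, -1) * model$alphas[m]
  }, numeric(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  f <- rowSums(votes) / sum(model$alphas)
  (f + 1) / 2
}

#' AdaBoost feature importances
#'
#' Alpha-weighted sum of each stump's rpart variable importance,
#' normalized to sum to 1 and sorted in descending order.
#'
#' @param model the fitted AdaBoost component of a `classifier_bank`
#'   (`bank$models$AdaBoost`).
#' @return data frame (feature, weight), weights summing to 1.
#' @export
feature_importance <- function(model) {
  if (is.null(model$stumps)) stop("feature_importance: unfitted model")
  imp <- setNames(numeric(length(model$features)), model$features)
  for (m in seq_along(model$stumps)) {
    vi <- model$stumps[[m]]$variable.importance
    if (is.null(vi)) next
    vi <- vi / sum(vi)
    imp[names(vi)] <- imp[names(vi)] + model$alphas[m] * vi
  }
  imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  data.frame(feature = names(imp), weight = unname(imp),
             row.names = NULL)
}
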