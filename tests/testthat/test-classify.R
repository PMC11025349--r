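# separable synthetic feature table mimicking the quantified cohort layout
toy_table <- function(n_each = 40, seed = 1, noise = 0.3) {
  set.seed(seed)
  lab <- rep(c("benign", "malignant"), each = n_each)
  shift <- ifelse(lab == "malignant", 1.5, 0)
  data.frame(
    label = lab,
    calc_num = round(10 + 8 * shift + rnorm(2 * n_each, sd = 2)),
    clu_num = pmax(0, round(shift * 2 + rnorm(2 * n_each, sd = noise))),
    density = 0.5 + 0.05 * shift + rnorm(2 * n_each, sd = 0.03),
    size_10 = round(4 + 5 * shift + rnorm(2 * n_each, sd = 1.5)))
}

test_that("stratified split preserves class proportions", {
  tab <- toy_table(50)
  sp <- split_table(tab, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$test$label == "benign"), 10)
  expect_identical(sp, split_table(tab, 0.8, seed = 3))
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(tab)))
  one <- tab[tab$label == "benign", ]
  expect_error(split_table(one), "both classes")
})

test_that("ROC starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5)
  s <- runif(40)
  r <- roc_curve(s, y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("AUC equals the Mann-Whitney pairwise oracle, with ties", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(auc_trapezoid(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  y <- c(0, 0, 1, 1)
  expect_equal(auc_trapezoid(c(0.1, 0.2, 0.8, 0.9), y), 1)
  # invariant under strictly monotone score transforms
  s <- runif(20); yy <- rbinom(20, 1, 0.5); yy[1:2] <- c(0, 1)
  expect_equal(auc_trapezoid(s, yy), auc_trapezoid(qlogis(s), yy))
})

test_that("all seven classifiers separate an easy cohort", {
  tab <- toy_table(40, seed = 6)
  bank <- train_classifiers(tab, seed = 1)
  expect_named(bank$models, c("DT", "LR", "SVM", "KNN", "RF", "XGB",
                              "AdaBoost"))
  scores <- predict_scores(bank, tab)
  for (a in colnames(scores)) {
    acc <- mean((scores[, a] > 0.5) == (tab$label == "malignant"))
    expect_gte(acc, 0.9)
  }
})

test_that("zero-variance features are dropped with a warning", {
  tab <- toy_table(20, seed = 7)
  tab$flat <- 1
  expect_warning(bank <- train_classifiers(tab, seed = 1), "zero-variance")
  expect_false("flat" %in% bank$features)
})

test_that("training and scoring are deterministic per seed", {
  tab <- toy_table(25, seed = 8)
  sp <- split_table(tab, 0.8, seed = 1)
  b1 <- train_classifiers(sp$train, seed = 5)
  b2 <- train_classifiers(sp$train, seed = 5)
  expect_equal(predict_scores(b1, sp$test), predict_scores(b2, sp$test))
})

test_that("evaluation reports AUC with CI and accuracy per algorithm", {
  tab <- toy_table(40, seed = 9)
  sp <- split_table(tab, 0.8, seed = 2)
  bank <- train_classifiers(sp$train, seed = 1)
  rep <- evaluate_classifiers(bank, sp$test, n_boot = 200, seed = 1)
  for (a in rep$algorithms) {
    expect_true(a$auc >= 0 && a$auc <= 1)
    expect_lte(a$auc_ci_low, a$auc + 1e-12)
    expect_gte(a$auc_ci_high, a$auc - 1e-12)
    expect_equal(a$roc$fpr[1], 0)
    expect_equal(tail(a$roc$tpr, 1), 1)
  }
  single <- sp$test[sp$test$label == "benign", ]
  expect_error(evaluate_classifiers(bank, single, n_boot = 10),
               "both classes")
})

test_that("AUC agrees with pROC on a shared score vector", {
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(60)
  ours <- auc_trapezoid(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<",
                                           levels = c(0, 1))))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("AdaBoost importances are a normalized ranking", {
  tab <- toy_table(30, seed = 11)
  bank <- train_classifiers(tab, seed = 2)
  fi <- feature_importance(bank$models$AdaBoost)
  expect_equal(sum(fi$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(fi$weight) <= 0))
  expect_true(all(fi$weight >= 0))
  expect_error(feature_importance(list()), "unfitted")
})

test_that("cluster-only signal puts a cluster feature on top", {
  set.seed(12)
  n <- 60
  lab <- rep(c("benign", "malignant"), each = n)
  tab <- data.frame(
    label = lab,
    calc_num = round(rnorm(2 * n, 15, 2)),          # uninformative
    density = rnorm(2 * n, 0.5, 0.05),              # uninformative
    clu_num = ifelse(lab == "malignant", 3, 0) +
      round(rnorm(2 * n, sd = 0.4)),                # the only real signal
    long_l = round(rnorm(2 * n, 4, 1)))             # uninformative
  bank <- train_classifiers(tab, seed = 3)
  fi <- feature_importance(bank$models$AdaBoost)
  expect_equal(fi$feature[1], "clu_num")
})

test_that("a single-feature table gives that feature weight one", {
  set.seed(13)
  lab <- rep(c("benign", "malignant"), each = 20)
  tab <- data.frame(label = lab,
                    clu_num = ifelse(lab == "malignant", 3, 0) +
                      rnorm(40, sd = 0.5))
  bank <- train_classifiers(tab, seed = 1)
  fi <- feature_importance(bank$models$AdaBoost)
  expect_equal(fi$weight[fi$feature == "clu_num"], 1, tolerance = 1e-9)
})
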