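make_feature_table <- function(n = 40, p = 4, seed = 1, sep = 3) {
  # two well-separated gaussian classes
  with_seed(seed, {
    half <- n %/% 2
    x <- rbind(matrix(rnorm(half * p), half, p),
               matrix(rnorm((n - half) * p, mean = sep), n - half, p))
    colnames(x) <- sprintf("f%02d", seq_len(p))
    df <- cbind(data.frame(id = sprintf("s%03d", seq_len(n)),
                           label = rep(c("neg_class", "pos_class"),
                                       c(half, n - half)),
                           stringsAsFactors = FALSE),
                as.data.frame(x))
    df
  })
}

test_that("zscore normalization is fit on training rows only", {
  df <- make_feature_table(30)
  df$partition <- rep(c("train", "test"), c(20, 10))
  zs <- zscore_fit(df, 1:20)
  out <- zscore_apply(df, zs)
  x <- as.matrix(out[1:20, zs$features])
  expect_equal(unname(colMeans(x)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(sqrt(colMeans(sweep(x, 2, colMeans(x))^2))),
               rep(1, 4), tolerance = 1e-10)
  # leakage guard: test rows in the fit set are a hard error
  expect_error(zscore_fit(df, 1:30), "leakage")
  expect_error(zscore_fit(df, integer(0)), "empty")
})

test_that("constant features map to 0 instead of NaN", {
  df <- make_feature_table(10)
  df$f01 <- 5
  zs <- zscore_fit(df)
  out <- zscore_apply(df, zs)
  expect_equal(out$f01, rep(0, 10))
  expect_true(all(is.finite(as.matrix(out[, zs$features]))))
})

test_that("fuse concatenates blocks radiomic-first and checks alignment", {
  rad <- data.frame(id = c("a", "b"), label = c("x", "y"), r1 = c(1, 2))
  deep <- data.frame(id = c("a", "b"), d1 = c(3, 4), d2 = c(5, 6))
  fused <- fuse(rad, deep)
  expect_equal(names(fused), c("id", "label", "r1", "d1", "d2"))
  expect_equal(feature_columns(fused), c("r1", "d1", "d2"))
  deep_bad <- deep; deep_bad$id <- c("b", "a")
  expect_error(fuse(rad, deep_bad), "alignment")
})

test_that("softmax is stable, positive and sums to one", {
  p <- softmax(c(1000, 1001, 1002))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  expect_equal(p, softmax(c(0, 1, 2)))  # shift invariance
  m <- softmax(matrix(c(0, 0, 10, 0), 2, 2))
  expect_equal(rowSums(m), c(1, 1))
  expect_error(softmax(c(1, NA)), "non-finite")
  expect_error(softmax(c(1, Inf)), "non-finite")
})

test_that("cross_entropy matches hand-computed values", {
  probs <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  colnames(probs) <- c("a", "b")
  expect_equal(cross_entropy(probs, c("a", "b")),
               -(log(0.8) + log(0.6)) / 2)
  onehot <- rbind(c(1, 0)); colnames(onehot) <- c("a", "b")
  expect_equal(cross_entropy(onehot, "a"), 0)
  uni <- rbind(c(0.5, 0.5)); colnames(uni) <- c("a", "b")
  expect_equal(cross_entropy(uni, "a"), log(2))
})

test_that("classifier_config applies the RF profiles", {
  expect_equal(classifier_config("rf", profile = "radiomic")$n_trees, 55L)
  expect_equal(classifier_config("rf", profile = "radiomic")$max_depth, 10L)
  expect_equal(classifier_config("rf", profile = "hybrid")$n_trees, 100L)
  expect_equal(classifier_config("rf", profile = "hybrid")$max_depth, 15L)
  expect_equal(classifier_config("rf", n_trees = 7, max_depth = 2)$n_trees, 7)
})

test_that("all three classifier kinds separate easy data and are deterministic", {
  df <- make_feature_table(60, seed = 5)
  zs <- zscore_fit(df)
  dfn <- zscore_apply(df, zs)
  for (kind in c("rf", "svm", "ann")) {
    cfg <- classifier_config(kind, epochs = 80, hidden = c(16, 8))
    m <- train_classifier(dfn, dfn$label, cfg, seed = 3)
    pr <- predict_proba(m, dfn)
    expect_equal(dim(pr), c(60, 2))
    expect_equal(unname(rowSums(pr)), rep(1, 60), tolerance = 1e-9)
    expect_equal(colnames(pr), c("neg_class", "pos_class"))
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    expect_gte(mean(pred == dfn$label), 0.95)
    m2 <- train_classifier(dfn, dfn$label, cfg, seed = 3)
    expect_equal(predict_proba(m2, dfn), pr)
  }
  expect_error(train_classifier(dfn, rep("one", 60)), "at least 2 classes")
})

test_that("SVM probabilities rank the true class highest on 3-class data", {
  with_seed(44, {
    x <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 5), 15, 2),
               cbind(rnorm(15, 0), rnorm(15, 5)))
  })
  colnames(x) <- c("f1", "f2")
  df <- cbind(data.frame(label = rep(c("a", "b", "c"), each = 15)),
              as.data.frame(x))
  m <- train_classifier(df, df$label, classifier_config("svm"), seed = 2)
  pr <- predict_proba(m, df)
  pred <- colnames(pr)[max.col(pr, ties.method = "first")]
  expect_gte(mean(pred == df$label), 0.9)
})

test_that("hyperparameter grid search returns the best configuration", {
  df <- make_feature_table(40, seed = 9)
  grid <- list(classifier_config("rf", n_trees = 25, max_depth = 6),
               classifier_config("rf", n_trees = 50, max_depth = 8))
  res <- select_hyperparams(df, df$label, grid, k = 4, seed = 2)
  expect_length(res$scores, 2)
  expect_true(res$best_score == max(res$scores))
  expect_s3_class(res$best, "classifier_config")
  acc <- crossval_accuracy(df, df$label, grid[[1]], k = 4, seed = 2)
  expect_equal(acc, res$scores[1])
  expect_error(select_hyperparams(df, df$label, list()), "empty configuration")
})
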