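test_that("confusion builds counts[truth, predicted] and validates labels", {
  cm <- confusion(c("a", "a", "b", "b", "b"), c("a", "b", "b", "b", "a"),
                  c("a", "b"))
  expect_equal(cm, matrix(c(1L, 1L, 1L, 2L), 2, 2,
                          dimnames = list(truth = c("a", "b"),
                                          predicted = c("a", "b"))))
  expect_error(confusion("a", "c", class_names = c("a", "b")), "outside")
  expect_error(confusion(c("a", "b"), "a"), "equal length")
})

test_that("per_class_metrics matches a hand-computed one-vs-rest table", {
  # cm: truth a -> (8 a, 2 b); truth b -> (1 a, 9 b)
  cm <- matrix(c(8L, 1L, 2L, 9L), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  pc <- per_class_metrics(cm)
  a <- pc[pc$class == "a", ]
  expect_equal(a$precision, 100 * 8 / 9)
  expect_equal(a$sensitivity, 100 * 8 / 10)
  expect_equal(a$specificity, 100 * 9 / 10)
  expect_equal(a$accuracy, 100 * 17 / 20)
  expect_equal(a$n, 10)
  expect_false(a$undefined)
})

test_that("0/0 metric ratios yield 0 with the undefined flag", {
  cm <- matrix(c(5L, 0L, 0L, 0L), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  pc <- per_class_metrics(cm)
  b <- pc[pc$class == "b", ]
  expect_equal(b$precision, 0)     # TP + FP = 0
  expect_equal(b$sensitivity, 0)   # TP + FN = 0
  expect_true(b$undefined)
})

test_that("roc_points sweeps thresholds into the expected staircase", {
  scores <- c(0.9, 0.4, 0.5, 0.1)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  curve <- roc_points(scores, truth)
  expect_equal(curve$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 0.5, 1, 1))
  # all-equal scores collapse to the diagonal
  flat <- roc_points(rep(0.5, 4), truth)
  expect_equal(flat$fpr, c(0, 1))
  expect_equal(flat$tpr, c(0, 1))
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("both AUC estimators match hand-computed values", {
  scores <- c(0.9, 0.4, 0.5, 0.1)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_trapezoid(roc_points(scores, truth)), 0.75)
  expect_equal(auc_rank(scores, truth), 0.75)
  # perfect and inverted separations
  expect_equal(auc_rank(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # ties get midrank treatment: one tied pair contributes 1/2
  expect_equal(auc_rank(c(1, 1), c(TRUE, FALSE)), 0.5)
})

test_that("trapezoid and rank AUC agree to 1e-12 including tied scores", {
  for (s in 1:25) {
    with_seed(5000 + s, {
      n <- sample(10:60, 1)
      scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
      truth <- runif(n) < 0.5
      if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
      expect_equal(auc_trapezoid(roc_points(scores, truth)),
                   auc_rank(scores, truth), tolerance = 1e-12)
    })
  }
})

test_that("aggregate_overall macro-averages and prints half-up rounded values", {
  pc <- data.frame(class = c("a", "b"),
                   auc = c(80, 90.175), precision = c(70, 80),
                   sensitivity = c(60, 62.465), specificity = c(98, 99))
  cm <- matrix(c(8L, 1L, 2L, 9L), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  rep <- aggregate_overall(pc, cm)
  expect_equal(rep$overall$auc, 85.0875)
  expect_equal(rep$overall_rounded$auc, 85.09)
  expect_equal(rep$overall$accuracy, 100 * 17 / 20)
  expect_equal(rep$overall_rounded$sensitivity, 61.23)  # mean 61.2325
  out <- capture.output(print(rep))
  expect_true(any(grepl("85.09", out)))
})

test_that("evaluate_run composes metrics and rejects training rows", {
  set.seed(77)
  df <- data.frame(f1 = c(rnorm(20, 0), rnorm(20, 4)),
                   f2 = c(rnorm(20, 0), rnorm(20, 4)),
                   label = rep(c("a", "b"), each = 20))
  m <- train_classifier(df, df$label, classifier_config("rf", n_trees = 20),
                        seed = 1)
  rep <- evaluate_run(m, df[, c("f1", "f2")], df$label)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$per_class$class, c("a", "b"))
  expect_true(all(rep$per_class$auc >= 0 & rep$per_class$auc <= 100))
  expect_equal(names(rep$per_class),
               c("class", "n", "auc", "precision", "accuracy",
                 "sensitivity", "specificity", "undefined"))
  bad <- df; bad$partition <- "train"
  expect_error(evaluate_run(m, bad, df$label), "leakage")
})

test_that("write_metrics_json emits valid JSON with numeric values", {
  pc <- data.frame(class = "a", n = 5L, auc = 91.5, precision = 80,
                   accuracy = 85, sensitivity = 75, specificity = 95,
                   undefined = FALSE)
  rep <- aggregate_overall(pc, NULL)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_metrics_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$overall$auc, 91.5)
  expect_equal(parsed$per_class[[1]]$class, "a")
})
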