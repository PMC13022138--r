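test_that("round_half_up rounds .5 away from zero at every digit", {
  rhu <- lesionlab:::round_half_up
  expect_equal(rhu(0.5), 1)
  expect_equal(rhu(1.5), 2)
  expect_equal(rhu(2.5), 3)  # base R banker's rounding would give 2
  expect_equal(rhu(84.525, 2), 84.53)
  expect_equal(rhu(85.0875, 2), 85.09)
  expect_equal(rhu(99.2375, 2), 99.24)
  expect_equal(rhu(173.4), 173)
})

test_that("make_split partitions each class with the stated arithmetic", {
  labels <- rep(c("a", "b"), c(50, 23))
  df <- data.frame(label = labels, stringsAsFactors = FALSE)
  sp <- make_split(df, seed = 4)
  expect_setequal(unique(sp$assignment), c("train", "val", "test"))
  pl <- sp$plan
  # class a: test = round(10) = 10, val = round(8) = 8, train = 32
  expect_equal(pl[pl$class == "a", c("train_n", "val_n", "test_n")],
               data.frame(train_n = 32, val_n = 8, test_n = 10),
               ignore_attr = TRUE)
  # class b: test = round(4.6) = 5, val = round(3.68) = 4, train = 14
  expect_equal(pl[pl$class == "b", c("train_n", "val_n", "test_n")],
               data.frame(train_n = 14, val_n = 4, test_n = 5),
               ignore_attr = TRUE)
  # every record lands in exactly one partition; counts agree with the plan
  for (cl in c("a", "b")) {
    tab <- table(sp$assignment[labels == cl])
    expect_equal(as.integer(tab[c("train", "val", "test")]),
                 as.integer(pl[pl$class == cl, c("train_n", "val_n", "test_n")]))
  }
  # deterministic given the seed, different under another seed
  expect_identical(sp$assignment, make_split(df, seed = 4)$assignment)
  expect_false(identical(sp$assignment, make_split(df, seed = 5)$assignment))
})

test_that("make_split routes tiny classes to training with a warning", {
  df <- data.frame(label = c(rep("big", 20), "rare", "rare"))
  expect_warning(sp <- make_split(df, seed = 1), "rare")
  expect_true(all(sp$assignment[df$label == "rare"] == "train"))
})

test_that("make_cv_folds stratifies and covers every record exactly once", {
  labels <- rep(c("x", "y", "z"), c(11, 7, 5))
  folds <- make_cv_folds(labels, k = 5, seed = 9)
  expect_length(folds, 5)
  val_all <- sort(unlist(lapply(folds, `[[`, "val_idx")))
  expect_equal(val_all, seq_along(labels))
  for (f in folds) {
    expect_equal(sort(c(f$fit_idx, f$val_idx)), seq_along(labels))
    # within each class the fold sizes differ by at most one
    for (cl in c("x", "y", "z")) {
      n_val <- sum(labels[f$val_idx] == cl)
      n_cl <- sum(labels == cl)
      expect_true(n_val %in% c(floor(n_cl / 5), ceiling(n_cl / 5)))
    }
  }
  expect_error(make_cv_folds(labels, k = 6), "smallest class")
})

test_that("plan_augmentation applies final = original * (k + 1)", {
  counts <- c(a = 10L, b = 7L, c = 3L)
  plan <- plan_augmentation(counts, c(a = 2L, b = 0L, c = 5L))
  expect_equal(plan$final, c(30L, 7L, 18L))
  expect_error(plan_augmentation(counts, c(a = -1L)), ">= 0")
  expect_error(plan_augmentation(unname(counts)), "named")
})

test_that("augment ops are deterministic, label-preserving transforms", {
  ops <- sample_augment_ops(seed = 21)
  expect_identical(ops, sample_augment_ops(seed = 21))
  expect_true(abs(ops$rotate) <= 15)
  expect_true(ops$zoom >= 0.9 && ops$zoom <= 1.1)
  img <- disc_image(32, 32, radius = 8)
  out <- apply_augment_ops(img, ops)
  expect_equal(dim(out), dim(img))
  expect_gte(min(out), 0); expect_lte(max(out), 255)
  # pure hflip is an exact mirror
  flip <- apply_augment_ops(img, list(hflip = TRUE))
  expect_equal(flip[, 1, ], img[, 32, ])
  expect_equal(apply_augment_ops(flip, list(hflip = TRUE)), img)
})

test_that("apply_augmentation materializes k variants per original", {
  spec <- synthetic_spec(n_classes = 2, per_class_counts = 3,
                         image_size = c(32, 32), seed = 6)
  ds <- generate_dataset(spec)
  ds$records$partition <- "train"
  plan <- plan_augmentation(c(class1 = 3L, class2 = 3L),
                            c(class1 = 2L, class2 = 0L))
  aug <- apply_augmentation(ds, plan, seed = 6)
  expect_equal(nrow(aug$records), 3 * 3 + 3)  # class1 tripled, class2 kept
  expect_equal(sum(aug$records$label == "class1"), 9)
  expect_length(aug$images, nrow(aug$records))
  expect_false(any(vapply(aug$images, is.null, logical(1))))
  # variants differ from their originals but share the label
  expect_false(identical(aug$images[[1]], aug$images[[2]]))
  # deterministic
  aug2 <- apply_augmentation(ds, plan, seed = 6)
  expect_identical(aug$images, aug2$images)
})

test_that("apply_augmentation hard-fails on non-training records", {
  spec <- synthetic_spec(n_classes = 2, per_class_counts = 2,
                         image_size = c(32, 32))
  ds <- generate_dataset(spec)
  ds$records$partition <- c("train", "test", "train", "train")
  plan <- plan_augmentation(c(class1 = 2L, class2 = 2L), c(class1 = 1L))
  expect_error(apply_augmentation(ds, plan), "leakage")
  ds$records$partition <- NULL
  expect_error(apply_augmentation(ds, plan), "partition")
})
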