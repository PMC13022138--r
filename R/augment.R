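# Leakage-safe stratified splitting (64/16/20 and stratified k-fold CV) and
# class-specific augmentation planning/application for imbalanced lesion
# datasets.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Default per-class augmentation multipliers
#'
#' The class-specific multipliers used to rebalance the eight ISIC-2019
#' lesion classes toward the majority (nevus) class: each original training
#' image of class `c` gains `k[c]` synthetic variants, so the final count is
#' `original * (k + 1)`.
#'
#' @return named integer vector of multipliers.
#' @export
default_multipliers <- function() {
  c(SCC = 19L, AKIEC = 13L, BCC = 3L, BKL = 4L, DF = 51L, MEL = 2L,
    NV = 0L, VASC = 51L)
}

#' Stratified train/validation/test split
#'
#' Splits each class independently: `test = round(0.20 n)`,
#' `val = round(0.16 n)` (half-up rounding), `train = n - test - val`.
#' Assignment within a class is a seeded permutation, so no record appears in
#' two partitions. Classes with fewer than 3 records go entirely to training
#' with a warning.
#'
#' @param ds a `labeled_dataset` (or a data.frame with a `label` column).
#' @param fractions named fractions `c(train, val, test)` summing to 1.
#' @param seed RNG seed for the within-class permutation.
#' @return list with `plan` (per-class data.frame `class,total,train_n,val_n,
#'   test_n`) and `assignment` (character vector, one of
#'   `"train"/"val"/"test"` per record).
#' @export
make_split <- function(ds, fractions = c(train = 0.64, val = 0.16, test = 0.20),
                       seed = 1) {
  records <- if (inherits(ds, "labeled_dataset")) ds$records else ds
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  class_names <- if (inherits(ds, "labeled_dataset")) ds$class_names
  else sort(unique(records$label))
  assignment <- character(nrow(records))
  plan <- list()
  with_seed(seed, {
    for (cl in class_names) {
      idx <- which(records$label == cl)
      n <- length(idx)
      if (n == 0) {
        plan[[cl]] <- data.frame(class = cl, total = 0L, train_n = 0L,
                                 val_n = 0L, test_n = 0L)
        next
      }
      if (n < 3) {
        warning(sprintf("class '%s' has %d record(s); all assigned to train", cl, n))
        assignment[idx] <- "train"
        plan[[cl]] <- data.frame(class = cl, total = n, train_n = n,
                                 val_n = 0L, test_n = 0L)
        next
      }
      test_n <- round_half_up(fractions[["test"]] * n)
      val_n <- round_half_up(fractions[["val"]] * n)
      train_n <- n - test_n - val_n
      perm <- sample(idx)
      assignment[perm[seq_len(train_n)]] <- "train"
      assignment[perm[train_n + seq_len(val_n)]] <- "val"
      assignment[perm[train_n + val_n + seq_len(test_n)]] <- "test"
      plan[[cl]] <- data.frame(class = cl, total = n, train_n = train_n,
                               val_n = val_n, test_n = test_n)
    }
  })
  list(plan = do.call(rbind, c(plan, list(make.row.names = FALSE))),
       assignment = assignment, fractions = fractions, seed = seed)
}

#' Stratified k-fold cross-validation folds
#'
#' Partitions records into `k` folds stratified by class: each record
#' validates exactly once, and within each class fold sizes differ by at most
#' one.
#'
#' @param labels class label per record (character or factor).
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of `k` elements, each `list(fit_idx, val_idx)`.
#' @export
make_cv_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  if (k < 2) stop("k must be >= 2")
  counts <- table(labels)
  if (k > min(counts))
    stop(sprintf("k = %d exceeds the smallest class size (%d)", k, min(counts)))
  n <- length(labels)
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(fit_idx = which(fold_of != f), val_idx = which(fold_of == f)))
}

#' Plan class-specific augmentation
#'
#' For each class, the final training count is `original * (k + 1)` where `k`
#' synthetic variants are generated per original image.
#'
#' @param train_counts named integer vector of per-class training counts.
#' @param multipliers named integer vector of per-class multipliers `k`;
#'   defaults to [default_multipliers()] for classes present there, else 0.
#' @return data.frame `class, original, k, final`.
#' @export
plan_augmentation <- function(train_counts, multipliers = default_multipliers()) {
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  cls <- names(train_counts)
  if (is.null(cls)) stop("train_counts must be named by class")
  k <- vapply(cls, function(cl)
    if (cl %in% names(multipliers)) as.integer(multipliers[[cl]]) else 0L,
    integer(1))
  data.frame(class = cls, original = as.integer(train_counts), k = k,
             final = as.integer(train_counts) * (k + 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample a random augmentation operation chain
#'
#' Draws one composition of label-preserving transforms: horizontal/vertical
#' flips (each with probability 1/2), rotation uniform in +/- 15 degrees,
#' zoom in `[0.9, 1.1]`, and brightness/contrast/saturation factors in
#' `[0.8, 1.2]`.
#'
#' @param seed RNG seed.
#' @return named list of operation parameters.
#' @export
sample_augment_ops <- function(seed = 1) {
  with_seed(seed, list(
    hflip = runif(1) < 0.5,
    vflip = runif(1) < 0.5,
    rotate = runif(1, -15, 15),
    zoom = runif(1, 0.9, 1.1),
    brightness = runif(1, 0.8, 1.2),
    contrast = runif(1, 0.8, 1.2),
    saturation = runif(1, 0.8, 1.2)
  ))
}

#' Apply an augmentation operation chain to an image
#'
#' Geometric transforms use bilinear resampling with replicate padding (no
#' black wedges at rotated corners); photometric transforms are clipped to
#' `[0, 255]`.
#'
#' @param img RGB array on 0..255.
#' @param ops a list from [sample_augment_ops()].
#' @return transformed RGB array.
#' @export
apply_augment_ops <- function(img, ops) {
  if (isTRUE(ops$hflip)) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (isTRUE(ops$vflip)) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (!is.null(ops$rotate) || !is.null(ops$zoom))
    img <- affine_sample(img, angle = ops$rotate %||% 0, zoom = ops$zoom %||% 1)
  if (!is.null(ops$brightness)) img <- img * ops$brightness
  if (!is.null(ops$contrast)) img <- (img - 128) * ops$contrast + 128
  if (!is.null(ops$saturation)) {
    gray <- rgb_to_gray(clip255(img))
    for (k in 1:3) img[, , k] <- gray + ops$saturation * (img[, , k] - gray)
  }
  clip255(img)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fetch one image of a labeled dataset
#'
#' Returns record `i` as an RGB array on 0..255, reading from disk when the
#' dataset was materialized with an `out_dir` and from memory otherwise.
#'
#' @param ds a `labeled_dataset` from [generate_dataset()].
#' @param i record index.
#' @return `h x w x 3` numeric array.
#' @export
dataset_image <- function(ds, i) {
  if (!is.null(ds$images)) return(ds$images[[i]])
  read_image(file.path(ds$dir, ds$records$filename[i]))
}

#' Apply augmentation to training records
#'
#' Generates `k` synthetic variants per original according to `plan`.
#' Only records tagged as training may be passed in: the function hard-fails
#' on any record whose `partition` is not `"train"` (the leakage guard).
#' Originals are retained; variants keep their originals' labels.
#'
#' @param ds a `labeled_dataset` whose `records` carry a `partition` column
#'   (all `"train"`), or one accompanied by `partition`.
#' @param plan data.frame from [plan_augmentation()].
#' @param seed RNG seed; each variant is seeded from `(seed, record, copy)`.
#' @param partition optional partition tags if not already a records column.
#' @return augmented `labeled_dataset` (in-memory images when the input is
#'   in-memory).
#' @export
apply_augmentation <- function(ds, plan, seed = 1, partition = NULL) {
  records <- ds$records
  part <- partition %||% records$partition
  if (is.null(part)) stop("training records must carry a partition tag")
  if (any(part != "train"))
    stop("leakage error: augmentation received non-training records")
  k_of <- setNames(plan$k, plan$class)
  out_recs <- list(); out_imgs <- list()
  n_out <- 0L
  for (i in seq_len(nrow(records))) {
    img <- dataset_image(ds, i)
    n_out <- n_out + 1L
    out_recs[[n_out]] <- data.frame(filename = records$filename[i],
                                    label = records$label[i],
                                    partition = "train",
                                    stringsAsFactors = FALSE)
    out_imgs[[n_out]] <- img
    k <- k_of[[records$label[i]]] %||% 0L
    if (k > 0) {
      for (j in seq_len(k)) {
        ops <- sample_augment_ops(seed = per_image_seed(seed, i * 1000L + j))
        n_out <- n_out + 1L
        out_recs[[n_out]] <- data.frame(
          filename = sub("\\.png$", sprintf("_aug%02d.png", j),
                         records$filename[i]),
          label = records$label[i], partition = "train",
          stringsAsFactors = FALSE)
        out_imgs[[n_out]] <- apply_augment_ops(img, ops)
      }
    }
  }
  res <- structure(list(records = do.call(rbind, out_recs),
                        class_names = ds$class_names,
                        manifest_path = NA_character_, dir = ds$dir),
                   class = "labeled_dataset")
  res$images <- out_imgs
  res
}
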