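# End-to-end orchestration over the synthetic benchmark: simulate ->
# preprocess -> split (-> augment) -> segment -> radiomic + deep features ->
# z-score fusion -> train -> evaluate, with a switch that replaces the
# watershed ROI by the full image (the segmentation ablation).

#' Pipeline configuration
#'
#' @param spec a [synthetic_spec()] describing the dataset to simulate.
#' @param hair_removal run DullRazor-style hair removal after enhancement.
#' @param segmentation use the watershed ROI; `FALSE` computes features on
#'   the full image (ablation mode).
#' @param feature_set `"hybrid"`, `"radiomic"` or `"deep"`.
#' @param backbone deep-feature backbone name.
#' @param classifier a [classifier_config()]; the default picks the random
#'   forest profile matching `feature_set`.
#' @param multipliers per-class augmentation multipliers (default: none).
#' @param enhancement an [enhancement_params()] list.
#' @param hair a [hair_removal_params()] list.
#' @param watershed a [watershed_params()] list.
#' @param radiomics a [radiomics_config()] list.
#' @param seed global run seed (split, augmentation, classifier).
#' @param out_dir optional directory for artifacts (metrics JSON, masks).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = synthetic_spec(n_classes = 3,
                                                  per_class_counts = 12,
                                                  image_size = c(64, 64)),
                            hair_removal = FALSE,
                            segmentation = TRUE,
                            feature_set = c("hybrid", "radiomic", "deep"),
                            backbone = "tiny_test",
                            classifier = NULL,
                            multipliers = NULL,
                            enhancement = enhancement_params(),
                            hair = hair_removal_params(),
                            watershed = watershed_params(),
                            radiomics = radiomics_config(),
                            seed = 1,
                            out_dir = NULL) {
  feature_set <- match.arg(feature_set)
  if (is.null(classifier))
    classifier <- classifier_config("rf", profile = if (feature_set == "radiomic")
      "radiomic" else "hybrid")
  structure(list(spec = spec, hair_removal = hair_removal,
                 segmentation = segmentation, feature_set = feature_set,
                 backbone = backbone, classifier = classifier,
                 multipliers = multipliers, enhancement = enhancement,
                 hair = hair, watershed = watershed, radiomics = radiomics,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

# preprocess + segment one image; returns mask (possibly full-image), roi
prepare_image <- function(img, config) {
  pre <- enhance(img, config$enhancement)
  if (isTRUE(config$hair_removal)) pre <- remove_hair(pre, config$hair)$cleaned
  full_mask <- matrix(1, dim(pre)[1], dim(pre)[2])
  if (!isTRUE(config$segmentation))
    return(list(image = pre, mask = full_mask, roi = pre, seg_failed = NA))
  seg <- segment_lesion(pre, config$watershed)
  if (isTRUE(seg$failure))
    return(list(image = pre, mask = full_mask, roi = pre, seg_failed = TRUE))
  list(image = pre, mask = seg$lesion_mask, roi = seg$roi_image,
       seg_failed = FALSE, dice = NA)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a freshly simulated dataset and
#' returns a run record with the test-set metrics report. Fully reproducible
#' from `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @return a `run_record`: config echo, per-stage timings, feature tables,
#'   the trained model and the `metrics_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  lap <- function(nm, since) {
    timings[[nm]] <<- round(tic() - since, 3)
    tic()
  }

  t <- tic()
  ds <- generate_dataset(config$spec)
  n <- nrow(ds$records)
  if (n == 0) stop("stage simulate: empty dataset")
  t <- lap("simulate", t)

  split <- make_split(ds, seed = config$seed)
  ds$records$partition <- split$assignment
  t <- lap("split", t)

  prepared <- lapply(seq_len(n), function(i)
    prepare_image(dataset_image(ds, i), config))
  t <- lap("preprocess_segment", t)

  # augmentation: train partition only, after the split (leakage-safe)
  aug_prepared <- list(); aug_labels <- character(0)
  if (!is.null(config$multipliers)) {
    tr_idx <- which(ds$records$partition == "train")
    tr <- structure(list(records = ds$records[tr_idx, , drop = FALSE],
                         class_names = ds$class_names,
                         images = lapply(tr_idx, function(i) dataset_image(ds, i))),
                    class = "labeled_dataset")
    counts <- table(factor(tr$records$label, levels = ds$class_names))
    plan <- plan_augmentation(setNames(as.integer(counts), names(counts)),
                              config$multipliers)
    aug <- apply_augmentation(tr, plan, seed = config$seed)
    new_idx <- which(!aug$records$filename %in% tr$records$filename)
    aug_prepared <- lapply(new_idx, function(i)
      prepare_image(aug$images[[i]], config))
    aug_labels <- aug$records$label[new_idx]
  }
  t <- lap("augment", t)

  all_prepared <- c(prepared, aug_prepared)
  labels <- c(ds$records$label, aug_labels)
  partition <- c(ds$records$partition, rep("train", length(aug_prepared)))
  ids <- sprintf("img%04d", seq_along(all_prepared))

  rad <- t(vapply(all_prepared, function(p)
    extract_radiomics(p$image, p$mask, config$radiomics), numeric(96)))
  rad_table <- cbind(data.frame(id = ids, label = labels, partition = partition,
                                stringsAsFactors = FALSE),
                     as.data.frame(rad))
  t <- lap("radiomics", t)

  deep_table <- extract_deep_features(lapply(all_prepared, `[[`, "roi"),
                                      spec = config$backbone, ids = ids)
  deep_table <- cbind(data.frame(id = ids, label = labels, partition = partition,
                                 stringsAsFactors = FALSE),
                      deep_table[, feature_columns(deep_table), drop = FALSE])
  t <- lap("deep_features", t)

  train_rows <- which(partition == "train")
  test_rows <- which(partition == "test")
  zs_rad <- zscore_fit(rad_table, train_rows)
  zs_deep <- zscore_fit(deep_table, train_rows)
  rad_n <- zscore_apply(rad_table, zs_rad)
  deep_n <- zscore_apply(deep_table, zs_deep)
  features <- switch(config$feature_set,
                     radiomic = rad_n, deep = deep_n,
                     hybrid = fuse(rad_n, deep_n))
  t <- lap("fuse_normalize", t)

  model <- train_classifier(features[train_rows, , drop = FALSE],
                            labels[train_rows], config$classifier,
                            seed = config$seed)
  t <- lap("train", t)

  report <- evaluate_run(model, features[test_rows, , drop = FALSE],
                         labels[test_rows])
  t <- lap("evaluate", t)

  seg_failed <- vapply(all_prepared, function(p) isTRUE(p$seg_failed), logical(1))
  rec <- structure(list(
    config = config, timings = timings, n_images = length(all_prepared),
    n_train = length(train_rows), n_test = length(test_rows),
    segmentation_failures = sum(seg_failed),
    features = features, labels = labels, partition = partition,
    model = model, metrics = report,
    elapsed = round(tic() - t0, 3)), class = "run_record")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_json(report, file.path(config$out_dir, "metrics.json"))
  }
  rec
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run_record: %d images (%d train / %d test), %s features, %s\n",
              x$n_images, x$n_train, x$n_test, x$config$feature_set,
              x$config$classifier$kind))
  cat(sprintf("segmentation: %s (%d failures)\n",
              if (isTRUE(x$config$segmentation)) "watershed ROI" else "full image",
              x$segmentation_failures))
  ov <- x$metrics$overall_rounded
  cat(sprintf("overall: AUC %.2f | accuracy %.2f | sensitivity %.2f | specificity %.2f\n",
              ov$auc, ov$accuracy, ov$sensitivity, ov$specificity))
  invisible(x)
}

#' Paired segmentation ablation
#'
#' Runs the pipeline twice with identical configuration except for the
#' segmentation toggle and reports both metric sets plus their deltas
#' (with-watershed minus without).
#'
#' @param config a [pipeline_config()]; its `segmentation` flag is ignored.
#' @return list with `with_watershed`, `without_watershed` (run records) and
#'   `delta` (named overall metric differences).
#' @export
compare_ablation <- function(config = pipeline_config()) {
  cfg_on <- config; cfg_on$segmentation <- TRUE
  cfg_off <- config; cfg_off$segmentation <- FALSE
  on <- run_pipeline(cfg_on)
  off <- run_pipeline(cfg_off)
  delta <- mapply(function(a, b) a - b, on$metrics$overall, off$metrics$overall)
  list(with_watershed = on, without_watershed = off, delta = delta)
}
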