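# Confusion matrices, per-class one-vs-rest metrics, ROC curves with two AUC
# estimators (empirical trapezoid and Mann-Whitney rank), and the macro
# "overall" aggregation used in the report tables.

#' Confusion matrix
#'
#' `counts[t, p]` = number of samples of true class `t` predicted as `p`.
#'
#' @param truth,predicted equal-length label vectors.
#' @param class_names ordered class labels; every observed label must belong.
#' @return C x C integer matrix with class dimnames.
#' @export
confusion <- function(truth, predicted, class_names = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(bad)) stop("label outside class set: ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = class_names),
               factor(predicted, levels = class_names))
  m <- matrix(as.integer(tab), length(class_names), length(class_names),
              dimnames = list(truth = class_names, predicted = class_names))
  m
}

#' Per-class one-vs-rest metrics
#'
#' For each class `c`: `TP = cm[c, c]`, `FN = rowsum - TP`,
#' `FP = colsum - TP`, `TN = rest`; then precision `TP/(TP+FP)`, accuracy
#' `(TN+TP)/total`, sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`,
#' each as a percentage. 0/0 yields 0 with `undefined = TRUE`.
#'
#' @param cm confusion matrix from [confusion()].
#' @return data.frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  cls <- rownames(cm)
  rows <- lapply(seq_along(cls), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
    pr <- ratio(tp, tp + fp); se <- ratio(tp, tp + fn); sp <- ratio(tn, tn + fp)
    data.frame(class = cls[k], n = tp + fn,
               precision = 100 * pr[1], accuracy = 100 * (tn + tp) / total,
               sensitivity = 100 * se[1], specificity = 100 * sp[1],
               undefined = pr[2] | se[2] | sp[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique scores in descending order
#' (plus sentinels), yielding the `(FPR, TPR)` staircase from `(0, 0)` to
#' `(1, 1)`; duplicated points are removed.
#'
#' @param scores positive-class score per sample.
#' @param truth binary truth (logical, or 0/1).
#' @return data.frame with columns `fpr`, `tpr` (class `roc_curve`).
#' @export
roc_points <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # keep one point per distinct threshold (last index of each tied block)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  pts <- rbind(c(0, 0), cbind(fp[keep] / nn, tp[keep] / np))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  structure(data.frame(fpr = pts[, 1], tpr = pts[, 2]), class = c("roc_curve", "data.frame"))
}

#' Trapezoidal AUC
#'
#' `sum_k (FPR_{k+1} - FPR_k) (TPR_{k+1} + TPR_k) / 2` over the ROC points
#' sorted by FPR (and TPR within ties).
#'
#' @param curve a [roc_points()] data.frame.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  if (nrow(curve) < 2) stop("need at least 2 ROC points")
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' `(R+ - n+ (n+ + 1) / 2) / (n+ n-)` where `R+` is the rank sum of the
#' positive scores; ties use midranks. Numerically identical to
#' [auc_trapezoid()] over the full empirical ROC.
#'
#' @param scores positive-class scores.
#' @param truth binary truth.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Aggregate per-class metrics into an overall report
#'
#' Overall AUC / precision / sensitivity / specificity are unweighted macro
#' means of the per-class values; overall accuracy is the plain multiclass
#' accuracy `trace(cm) / total`. Values are carried at full precision with a
#' half-up 2-decimal rounding used for display.
#'
#' @param per_class data.frame with columns `auc`, `precision`,
#'   `sensitivity`, `specificity` (percent scale).
#' @param cm confusion matrix (for the accuracy trace), or `NULL` to omit.
#' @return object of class `metrics_report`.
#' @export
aggregate_overall <- function(per_class, cm = NULL) {
  overall <- list(
    auc = mean(per_class$auc),
    precision = mean(per_class$precision),
    sensitivity = mean(per_class$sensitivity),
    specificity = mean(per_class$specificity),
    accuracy = if (!is.null(cm)) 100 * sum(diag(cm)) / sum(cm) else NA_real_
  )
  structure(list(per_class = per_class, confusion = cm, overall = overall,
                 overall_rounded = lapply(overall, round_half_up, digits = 2)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report\n")
  if (!is.null(x$confusion)) {
    cat("confusion matrix (rows = truth):\n"); print(x$confusion)
  }
  pc <- x$per_class
  num <- vapply(pc, is.numeric, logical(1))
  pc[num] <- lapply(pc[num], round_half_up, digits = 2)
  print(pc, row.names = FALSE)
  ov <- x$overall_rounded
  cat(sprintf("overall: AUC %.2f | precision %.2f | accuracy %.2f | sensitivity %.2f | specificity %.2f\n",
              ov$auc, ov$precision, ov$accuracy, ov$sensitivity, ov$specificity))
  invisible(x)
}

#' Evaluate a trained model on held-out data
#'
#' Computes predicted probabilities, the confusion matrix, per-class
#' one-vs-rest metrics, per-class ROC AUCs by both estimators (their
#' agreement is asserted to 1e-9) and the overall aggregates. Rows tagged
#' with a training partition are rejected (leakage guard).
#'
#' @param model a `trained_model`.
#' @param test_table feature data.frame of held-out rows.
#' @param truth true labels of the held-out rows.
#' @return a `metrics_report` with a per-class `auc` column.
#' @export
evaluate_run <- function(model, test_table, truth) {
  if (!is.null(test_table$partition) && any(test_table$partition == "train"))
    stop("leakage error: evaluation received training rows")
  truth <- as.character(truth)
  probs <- predict_proba(model, test_table)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  cm <- confusion(truth, pred, model$class_names)
  pc <- per_class_metrics(cm)
  aucs <- vapply(model$class_names, function(cl) {
    y <- truth == cl
    if (all(y) || !any(y)) return(NA_real_)
    a1 <- auc_trapezoid(roc_points(probs[, cl], y))
    a2 <- auc_rank(probs[, cl], y)
    if (abs(a1 - a2) > 1e-9)
      stop("AUC estimator disagreement: ", a1, " vs ", a2)
    a1
  }, numeric(1))
  pc$auc <- 100 * aucs[pc$class]
  pc <- pc[, c("class", "n", "auc", "precision", "accuracy",
               "sensitivity", "specificity", "undefined")]
  rep <- aggregate_overall(pc[!is.na(pc$auc), ], cm)
  rep$per_class <- pc
  rep
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- list(
    overall = report$overall,
    per_class = report$per_class,
    confusion = if (!is.null(report$confusion)) {
      list(classes = rownames(report$confusion),
           counts = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)))
    }
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
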