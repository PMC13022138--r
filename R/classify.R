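# Z-score normalization fitted on training rows only, radiomic/deep feature
# fusion by concatenation, and three classifier families: a two-hidden-layer
# ReLU network with a softmax head trained on cross-entropy, one-vs-rest
# SVMs, and gini random forests with the (55, 10) / (100, 15) profiles.

feature_columns <- function(table) {
  setdiff(names(table), c("id", "label", "partition"))
}

#' Fit z-score normalization parameters on training rows
#'
#' Computes the per-feature mean and (population) standard deviation from the
#' training rows only. If the table carries a `partition` column, handing in
#' a row that is not tagged `"train"` is a hard error — the leakage guard.
#' Features with zero standard deviation are flagged to map to 0.
#'
#' @param table feature data.frame (numeric feature columns; optional `id`,
#'   `label`, `partition`).
#' @param train_rows integer indices of the training rows.
#' @return list with `mu`, `sigma` and `features`.
#' @export
zscore_fit <- function(table, train_rows = seq_len(nrow(table))) {
  if (length(train_rows) == 0) stop("empty training set")
  if (!is.null(table$partition) && any(table$partition[train_rows] != "train"))
    stop("leakage error: zscore_fit received non-training rows")
  feats <- feature_columns(table)
  x <- as.matrix(table[train_rows, feats, drop = FALSE])
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  list(mu = mu, sigma = sigma, features = feats)
}

#' Apply fitted z-score normalization
#'
#' Transforms every row with the fitted mean/sd; zero-sd features map to 0.
#'
#' @param table feature data.frame.
#' @param params output of [zscore_fit()].
#' @return the table with normalized feature columns.
#' @export
zscore_apply <- function(table, params) {
  x <- as.matrix(table[, params$features, drop = FALSE])
  sigma <- params$sigma
  zero <- sigma == 0
  sigma[zero] <- 1
  z <- sweep(sweep(x, 2, params$mu), 2, sigma, "/")
  z[, zero] <- 0
  table[, params$features] <- z
  table
}

#' Fuse radiomic and deep feature tables
#'
#' Row-wise concatenation with the radiomic block first; rows are aligned by
#' the `id` column and must match exactly. Output width is
#' `96 + d` feature columns for the default radiomic block.
#'
#' @param radiomic,deep feature data.frames sharing an `id` column (and
#'   optionally `label`/`partition`, taken from `radiomic`).
#' @return fused data.frame.
#' @export
fuse <- function(radiomic, deep) {
  if (!identical(radiomic$id, deep$id))
    stop("alignment error: radiomic and deep tables have different row ids")
  meta <- intersect(c("id", "label", "partition"), names(radiomic))
  cbind(radiomic[, c(meta, feature_columns(radiomic)), drop = FALSE],
        deep[, feature_columns(deep), drop = FALSE])
}

#' Numerically stable softmax
#'
#' Converts scores to positive probabilities summing to 1 (max-shifted
#' before exponentiation). Matrix inputs are transformed row-wise.
#'
#' @param scores numeric vector, or matrix with one score row per sample.
#' @return probabilities of the same shape.
#' @export
softmax <- function(scores) {
  if (is.matrix(scores)) {
    if (any(!is.finite(scores))) stop("non-finite scores")
    e <- exp(scores - apply(scores, 1, max))
    return(e / rowSums(e))
  }
  if (any(!is.finite(scores))) stop("non-finite scores")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Mean cross-entropy loss
#'
#' `-(1/N) sum_i log p_i[true class of i]` (natural log); 0 for perfect
#' one-hot predictions, `log(C)` per sample for uniform predictions over `C`
#' classes.
#'
#' @param probs N x C probability matrix with class-named columns.
#' @param truth true labels (character/factor matching the columns).
#' @param eps floor applied to probabilities before the log.
#' @return mean loss (scalar).
#' @export
cross_entropy <- function(probs, truth, eps = 1e-12) {
  truth <- as.character(truth)
  if (is.null(colnames(probs))) stop("probs must have class-named columns")
  p <- probs[cbind(seq_len(nrow(probs)), match(truth, colnames(probs)))]
  -mean(log(pmax(p, eps)))
}

#' Classifier configuration
#'
#' * `ann`: fully connected network with two ReLU hidden layers (default
#'   256 and 128 units) and a softmax output, trained by minibatch gradient
#'   descent (Adam) on cross-entropy with early stopping patience.
#' * `svm`: one-vs-rest support vector machines; kernels `linear`, `rbf` or
#'   `poly3` with cost `C` and RBF/poly coefficient `gamma`.
#' * `rf`: gini random forest; profile `"radiomic"` = 55 trees, depth 10;
#'   profile `"hybrid"` = 100 trees, depth 15.
#'
#' @param kind `"ann"`, `"svm"` or `"rf"`.
#' @param hidden ANN hidden layer sizes.
#' @param epochs,learning_rate,batch_size ANN optimizer settings.
#' @param kernel SVM kernel.
#' @param C,gamma SVM regularization and kernel coefficient (`gamma = NULL`
#'   means `1 / n_features`).
#' @param profile RF profile, or `NULL` to set `n_trees`/`max_depth` directly.
#' @param n_trees,max_depth explicit RF shape (overridden by `profile`).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(kind = c("rf", "ann", "svm"),
                              hidden = c(256, 128), epochs = 200,
                              learning_rate = 1e-3, batch_size = 32,
                              kernel = c("rbf", "linear", "poly3"),
                              C = 1, gamma = NULL,
                              profile = c("radiomic", "hybrid"),
                              n_trees = NULL, max_depth = NULL) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  profile <- match.arg(profile)
  if (kind == "rf") {
    if (is.null(n_trees))
      n_trees <- if (profile == "hybrid") 100L else 55L
    if (is.null(max_depth))
      max_depth <- if (profile == "hybrid") 15L else 10L
  }
  structure(list(kind = kind, hidden = as.integer(hidden), epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 kernel = kernel, C = C, gamma = gamma, profile = profile,
                 n_trees = n_trees, max_depth = max_depth),
            class = "classifier_config")
}

# ---- ANN: 2 hidden ReLU layers + softmax, Adam on cross-entropy ------------

ann_train <- function(x, y_idx, n_class, config, seed) {
  n <- nrow(x); p <- ncol(x)
  sizes <- c(p, config$hidden, n_class)
  with_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(length(sizes) - 1), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; epsi <- 1e-8; t <- 0
    lr <- config$learning_rate
    Y <- matrix(0, n, n_class); Y[cbind(seq_len(n), y_idx)] <- 1
    best <- list(loss = Inf, W = W, b = b); stall <- 0
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
        # forward
        a <- list(xb)
        for (l in 1:2) a[[l + 1]] <- pmax(sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+"), 0)
        logits <- sweep(a[[3]] %*% W[[3]], 2, b[[3]], "+")
        pr <- softmax(logits)
        # backward
        d <- (pr - yb) / nrow(xb)
        gW <- vector("list", 3); gb <- vector("list", 3)
        for (l in 3:1) {
          gW[[l]] <- t(a[[l]]) %*% d
          gb[[l]] <- colSums(d)
          if (l > 1) d <- (d %*% t(W[[l]])) * (a[[l]] > 0)
        }
        t <- t + 1
        for (l in 1:3) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
          W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
            (sqrt(vW[[l]] / (1 - b2^t)) + epsi)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
            (sqrt(vb[[l]] / (1 - b2^t)) + epsi)
        }
      }
      pr <- ann_forward(x, W, b)
      loss <- -mean(log(pmax(pr[cbind(seq_len(n), y_idx)], 1e-12)))
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, W = W, b = b); stall <- 0
      } else stall <- stall + 1
      if (stall >= 20) break
    }
    list(W = best$W, b = best$b)
  })
}

ann_forward <- function(x, W, b) {
  a <- x
  for (l in 1:2) a <- pmax(sweep(a %*% W[[l]], 2, b[[l]], "+"), 0)
  softmax(sweep(a %*% W[[3]], 2, b[[3]], "+"))
}

#' Train a classifier
#'
#' Deterministic given `seed`. The table's feature columns are used as-is
#' (normalize first with [zscore_fit()]/[zscore_apply()]).
#'
#' @param table feature data.frame.
#' @param labels class label per row.
#' @param config a [classifier_config()].
#' @param seed RNG seed.
#' @return a `trained_model`.
#' @export
train_classifier <- function(table, labels, config = classifier_config("rf"),
                             seed = 1) {
  labels <- as.character(labels)
  class_names <- sort(unique(labels))
  if (length(class_names) < 2) stop("need at least 2 classes to train")
  feats <- feature_columns(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  fit <- switch(config$kind,
    ann = ann_train(x, match(labels, class_names), length(class_names),
                    config, seed),
    svm = {
      gamma <- config$gamma %||% (1 / ncol(x))
      kern <- switch(config$kernel, linear = "linear", rbf = "radial",
                     poly3 = "polynomial")
      with_seed(seed, lapply(class_names, function(cl) {
        y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("neg", "pos"))
        e1071::svm(x, y, kernel = kern, cost = config$C, gamma = gamma,
                   degree = 3, scale = FALSE)
      }))
    },
    rf = ranger::ranger(
      x = x, y = factor(labels, levels = class_names),
      num.trees = config$n_trees, max.depth = config$max_depth,
      splitrule = "gini", probability = TRUE, seed = seed,
      num.threads = 1)
  )
  structure(list(config = config, fit = fit, class_names = class_names,
                 features = feats, seed = seed),
            class = "trained_model")
}

#' Predict class probabilities
#'
#' Rows sum to 1 for every classifier kind (one-vs-rest SVM decision values
#' are mapped through a softmax).
#'
#' @param model a `trained_model`.
#' @param table feature data.frame with the model's feature columns.
#' @return N x C probability matrix with class-named columns.
#' @export
predict_proba <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  probs <- switch(model$config$kind,
    ann = ann_forward(x, model$fit$W, model$fit$b),
    svm = {
      dec <- vapply(model$fit, function(m) {
        as.numeric(attr(predict(m, x, decision.values = TRUE),
                        "decision.values"))
      }, numeric(nrow(x)))
      dec <- matrix(dec, nrow = nrow(x))
      # orient decision values so larger = more 'pos' for every binary machine
      for (j in seq_along(model$fit)) {
        lv <- colnames(attr(predict(model$fit[[j]], x[1, , drop = FALSE],
                                    decision.values = TRUE),
                            "decision.values"))
        if (!is.null(lv) && grepl("^neg", lv)) dec[, j] <- -dec[, j]
      }
      softmax(dec)
    },
    rf = predict(model$fit, data = x, num.threads = 1)$predictions
  )
  colnames(probs) <- model$class_names
  rownames(probs) <- NULL
  probs
}

#' Grid search for hyperparameters by stratified CV accuracy
#'
#' Evaluates every configuration with [make_cv_folds()] stratified k-fold
#' cross-validation and returns the one with the highest mean validation
#' accuracy (ties: first in grid order).
#'
#' @param table feature data.frame.
#' @param labels class labels.
#' @param grid list of [classifier_config()] objects.
#' @param k folds.
#' @param seed RNG seed (folds and classifier training).
#' @return list with `best` config, `best_score` and per-config `scores`.
#' @export
select_hyperparams <- function(table, labels, grid, k = 5, seed = 1) {
  if (length(grid) == 0) stop("empty configuration grid")
  folds <- make_cv_folds(labels, k = k, seed = seed)
  scores <- vapply(grid, function(cfg) {
    accs <- vapply(folds, function(f) {
      zs <- zscore_fit(table[f$fit_idx, , drop = FALSE])
      tr <- zscore_apply(table[f$fit_idx, , drop = FALSE], zs)
      va <- zscore_apply(table[f$val_idx, , drop = FALSE], zs)
      m <- train_classifier(tr, labels[f$fit_idx], cfg, seed = seed)
      pr <- predict_proba(m, va)
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      mean(pred == labels[f$val_idx])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(scores)
  list(best = grid[[best]], best_score = scores[best], scores = scores)
}

#' Stratified cross-validated accuracy of one configuration
#'
#' Convenience wrapper: k-fold CV with per-fold z-score normalization fitted
#' on the fit partition only.
#'
#' @inheritParams select_hyperparams
#' @param config a [classifier_config()].
#' @return mean validation accuracy across folds.
#' @export
crossval_accuracy <- function(table, labels, config, k = 5, seed = 1) {
  select_hyperparams(table, labels, list(config), k = k, seed = seed)$best_score
}
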