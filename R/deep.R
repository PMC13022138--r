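# Pluggable deep-feature extraction: a backbone registry (name, expected
# input size, GAP output dimension, weight loader) plus a tiny deterministic
# convolutional backbone used for testing. Pretrained backbones are opaque
# feature extractors loaded from externally supplied weights; they are never
# downloaded at run time.

.backbone_registry <- new.env(parent = emptyenv())

#' Describe a deep-feature backbone
#'
#' @param name unique backbone name.
#' @param input_size `c(height, width)` the backbone expects.
#' @param output_dim length of the pooled feature vector.
#' @param loader `"builtin-test"` (the deterministic test backbone) or
#'   `"external-pretrained"` (weights must be supplied offline).
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(name, input_size, output_dim,
                          loader = c("external-pretrained", "builtin-test")) {
  loader <- match.arg(loader)
  stopifnot(output_dim > 0, length(input_size) == 2)
  structure(list(name = name, input_size = as.integer(input_size),
                 output_dim = as.integer(output_dim), loader = loader),
            class = "backbone_spec")
}

#' Register a backbone
#'
#' @param spec a [backbone_spec()].
#' @param overwrite allow replacing an existing entry.
#' @return the spec, invisibly.
#' @export
register_backbone <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (!overwrite && !is.null(.backbone_registry[[spec$name]]))
    stop("backbone already registered: ", spec$name)
  assign(spec$name, spec, envir = .backbone_registry)
  invisible(spec)
}

#' Look up a registered backbone
#'
#' @param name backbone name.
#' @return the registered `backbone_spec`.
#' @export
get_backbone <- function(name) {
  sp <- .backbone_registry[[name]]
  if (is.null(sp))
    stop("unknown backbone '", name, "'; known: ",
         paste(sort(ls(.backbone_registry)), collapse = ", "))
  sp
}

#' List registered backbone names
#' @return character vector of names.
#' @export
list_backbones <- function() sort(ls(.backbone_registry))

register_default_backbones <- function() {
  for (nm in ls(.backbone_registry)) rm(list = nm, envir = .backbone_registry)
  register_backbone(backbone_spec("mobilenet_v2", c(224, 224), 1280,
                                  "external-pretrained"))
  register_backbone(backbone_spec("efficientnet_b4", c(380, 380), 1792,
                                  "external-pretrained"))
  register_backbone(backbone_spec("tiny_test", c(64, 64), 32, "builtin-test"))
}

.onLoad <- function(libname, pkgname) {
  register_default_backbones()
}

#' Global average pooling
#'
#' Reduces a `w x h x d` feature-map stack to the `d`-vector of channel
#' means: `v_i = (1 / (w h)) sum_jk F[j, k, i]`.
#'
#' @param f numeric 3-d array of feature maps.
#' @return numeric vector of length `dim(f)[3]`.
#' @export
global_average_pool <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3) stop("expected a w x h x d array")
  if (any(dim(f) < 1)) stop("empty feature-map stack")
  apply(f, 3, mean)
}

# Resize an RGB image to (h, w): proportional bilinear scale so the shorter
# relative side fits, then center crop.
resize_center_crop <- function(img, size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  f <- max(size[1] / h, size[2] / w)
  nh <- max(size[1], ceiling(h * f)); nw <- max(size[2], ceiling(w * f))
  rows <- seq(1, h, length.out = nh)
  cols <- seq(1, w, length.out = nw)
  g <- expand.grid(r = rows, c = cols)
  out <- array(0, c(nh, nw, 3))
  for (k in 1:3)
    out[, , k] <- matrix(bilinear_sample(img[, , k], g$r, g$c), nh, nw)
  r0 <- floor((nh - size[1]) / 2); c0 <- floor((nw - size[2]) / 2)
  out[r0 + seq_len(size[1]), c0 + seq_len(size[2]), , drop = FALSE]
}

# Deterministic tiny convolutional backbone: three stages of 3x3 convolution
# (replicate padding) + ReLU + 2x2 average pooling, with fixed-seed random
# weights (He-scaled). 64 x 64 x 3 input -> 8 x 8 x 32 maps.
tiny_test_weights <- function() {
  cached <- .backbone_registry[[".tiny_test_weights"]]
  if (!is.null(cached)) return(cached)
  chans <- c(3L, 8L, 16L, 32L)
  w <- with_seed(424242L, lapply(1:3, function(s) {
    cin <- chans[s]; cout <- chans[s + 1]
    array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
  }))
  assign(".tiny_test_weights", w, envir = .backbone_registry)
  w
}

conv3x3 <- function(x, w) {
  # x: h x w x cin on arbitrary scale; w: 3 x 3 x cin x cout
  cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  out <- array(0, c(h, wd, cout))
  for (q in seq_len(cout)) {
    acc <- matrix(0, h, wd)
    for (c in seq_len(cin))
      for (a in 1:3) for (b in 1:3)
        acc <- acc + w[a, b, c, q] * shift_pad(x[, , c], a - 2L, b - 2L)
    out[, , q] <- acc
  }
  out
}

avgpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L
  out <- array(0, c(h, w, dim(x)[3]))
  ri <- 2 * seq_len(h); ci <- 2 * seq_len(w)
  for (q in seq_len(dim(x)[3])) {
    m <- x[, , q]
    out[, , q] <- (m[ri - 1, ci - 1] + m[ri - 1, ci] + m[ri, ci - 1] + m[ri, ci]) / 4
  }
  out
}

tiny_test_forward <- function(img) {
  x <- img / 255
  w <- tiny_test_weights()
  for (s in 1:3) {
    x <- conv3x3(x, w[[s]])
    x <- pmax(x, 0)
    x <- avgpool2(x)
  }
  x
}

#' Extract deep features for a list of images
#'
#' Each image is resized to the backbone's expected input (bilinear
#' proportional scale + center crop), passed through the backbone and reduced
#' by global average pooling to one `d`-dimensional vector. The built-in
#' `tiny_test` backbone is fully deterministic and needs no weights on disk;
#' pretrained backbones require externally supplied weights and error with
#' instructions otherwise (nothing is ever downloaded).
#'
#' @param images list of RGB arrays on 0..255.
#' @param spec a backbone name or [backbone_spec()].
#' @param batch_size number of images processed per batch (results are
#'   independent of the batch size).
#' @param ids optional row identifiers (default `img1..imgN`).
#' @return data.frame with `id` plus `d` feature columns `deep_0001..`.
#' @export
extract_deep_features <- function(images, spec = "tiny_test", batch_size = 8,
                                  ids = NULL) {
  if (is.character(spec)) spec <- get_backbone(spec)
  if (spec$loader == "external-pretrained")
    stop("backbone '", spec$name, "' needs externally supplied pretrained ",
         "weights; export its pooled features to CSV offline and load them ",
         "with read_feature_table(), or use the 'tiny_test' backbone")
  n <- length(images)
  if (n == 0) stop("no images supplied")
  if (is.null(ids)) ids <- sprintf("img%d", seq_len(n))
  out <- matrix(0, n, spec$output_dim)
  for (start in seq(1, n, by = batch_size)) {
    for (i in start:min(start + batch_size - 1, n)) {
      img <- resize_center_crop(images[[i]], spec$input_size)
      out[i, ] <- global_average_pool(tiny_test_forward(img))
    }
  }
  colnames(out) <- sprintf("deep_%04d", seq_len(spec$output_dim))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), as.data.frame(out))
}

#' Read a feature table from CSV
#'
#' Loads a CSV with an `id` column, numeric feature columns and optionally a
#' `label` column — the interchange format for externally computed deep
#' features.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature table must have an 'id' column")
  df
}
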