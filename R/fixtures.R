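# Synthetic dermoscopy-like image generation: an elliptical pigmented lesion
# with an irregular (low-order Fourier) border on a lighter skin background,
# optional dark hair strokes and a smooth illumination gradient. Per-class
# color/texture signatures make the images classifiable downstream.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generators route their randomness here.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

default_class_params <- function(n_classes) {
  # Class signatures spread along two axes: lesion color (brown -> dark brown
  # -> blue-gray -> red) and texture grain frequency. Background stays light
  # skin-toned for all classes, as in dermoscopy.
  base <- list(
    list(lesion_rgb = c(120, 70, 50),  grain = 2),
    list(lesion_rgb = c(70, 40, 30),   grain = 5),
    list(lesion_rgb = c(90, 95, 120),  grain = 3),
    list(lesion_rgb = c(150, 60, 60),  grain = 8),
    list(lesion_rgb = c(60, 60, 60),   grain = 2),
    list(lesion_rgb = c(140, 100, 60), grain = 6),
    list(lesion_rgb = c(100, 50, 90),  grain = 4),
    list(lesion_rgb = c(50, 70, 50),   grain = 7)
  )
  lapply(seq_len(n_classes), function(i) {
    p <- base[[(i - 1L) %% length(base) + 1L]]
    list(
      mean_radius = 20, radius_sd = 3,
      border_irregularity = 0.15,
      lesion_rgb = p$lesion_rgb, lesion_spread = 12,
      background_rgb = c(205, 170, 150), background_spread = 8,
      texture_grain = p$grain
    )
  })
}

#' Specification for a synthetic dermoscopy dataset
#'
#' Bundles every knob of the generator: class count and per-class image
#' counts, image size, per-class lesion parameters (mean radius in pixels,
#' border-irregularity amplitude, lesion/background RGB means and spreads,
#' texture grain scale), hair stroke density, illumination-gradient amplitude
#' and the dataset seed. The seed fixes the output bit-exactly.
#'
#' @param n_classes number of lesion classes (>= 2 for classification use).
#' @param per_class_counts integer vector of images per class (recycled to
#'   `n_classes`).
#' @param image_size `c(height, width)` in pixels.
#' @param class_params optional list of per-class parameter lists; defaults to
#'   built-in color/texture signatures.
#' @param hair_density expected number of hair strokes per image (0 = none).
#' @param illumination_gradient_amplitude peak-to-center luminance offset of
#'   the smooth illumination ramp, on the 0..255 scale.
#' @param class_names optional character vector of class labels.
#' @param seed dataset RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2,
                           per_class_counts = 10,
                           image_size = c(128, 128),
                           class_params = NULL,
                           hair_density = 0,
                           illumination_gradient_amplitude = 0,
                           class_names = NULL,
                           seed = 1) {
  stopifnot(n_classes >= 1, all(per_class_counts >= 0), all(image_size >= 8))
  per_class_counts <- rep_len(as.integer(per_class_counts), n_classes)
  if (is.null(class_params)) class_params <- default_class_params(n_classes)
  if (length(class_params) != n_classes)
    stop("class_params must have one entry per class")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  structure(list(
    n_classes = n_classes, per_class_counts = per_class_counts,
    image_size = as.integer(image_size), class_params = class_params,
    hair_density = hair_density,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    class_names = class_names, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Smooth per-pixel texture: white noise box-blurred at the class grain scale,
# rescaled to unit sd. Larger grain -> coarser texture.
texture_field <- function(h, w, grain) {
  z <- matrix(rnorm(h * w), h, w)
  g <- max(1L, as.integer(grain))
  if (g > 1L) {
    acc <- matrix(0, h, w)
    off <- seq(-(g %/% 2), g %/% 2)
    for (dr in off) for (dc in off) acc <- acc + shift_pad(z, dr, dc)
    z <- acc / length(off)^2
  }
  s <- sd(as.vector(z)); if (s > 0) z <- z / s
  z
}

# Star-shaped lesion mask: ellipse perturbed by low-order Fourier boundary
# noise. Star-shapedness guarantees a simply connected, 4-connected region.
lesion_mask_field <- function(h, w, center, radius, irregularity, aspect) {
  a <- runif(3, 0, irregularity)
  ph <- runif(3, 0, 2 * pi)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dr <- (g$r - center[1]) / aspect
  dc <- g$c - center[2]
  rho <- sqrt(dr^2 + dc^2)
  th <- atan2(dr, dc)
  rb <- radius * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                    a[3] * cos(4 * th + ph[3]))
  matrix(as.numeric(rho <= rb), h, w)
}

# Quadratic Bezier hair stroke, 1-3 px wide, dark (luminance <= 60).
draw_hair <- function(img, hair_mask) {
  h <- dim(img)[1]; w <- dim(img)[2]
  p0 <- c(runif(1, 1, h), runif(1, 1, w))
  p2 <- c(runif(1, 1, h), runif(1, 1, w))
  p1 <- (p0 + p2) / 2 + rnorm(2, 0, max(h, w) / 6)
  tt <- seq(0, 1, length.out = 4 * max(h, w))
  rr <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
  cc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
  width <- runif(1, 1, 3)
  shade <- runif(1, 20, 60)
  half <- (width - 1) / 2
  for (d in seq(-ceiling(half), ceiling(half))) {
    ri <- round(rr + d); ci <- round(cc)
    keep <- ri >= 1 & ri <= h & ci >= 1 & ci <= w & abs(d) <= half + 0.5
    idx <- cbind(ri[keep], ci[keep])
    hair_mask[idx] <- 1
    for (k in 1:3) {
      ch <- img[, , k]; ch[idx] <- shade * c(1, 0.9, 0.8)[k]; img[, , k] <- ch
    }
    # widen along columns too so diagonal strokes stay connected
    ci2 <- round(cc + d)
    keep2 <- rr >= 1 & rr <= h & ci2 >= 1 & ci2 <= w & abs(d) <= half + 0.5
    idx2 <- cbind(round(rr[keep2]), ci2[keep2])
    hair_mask[idx2] <- 1
    for (k in 1:3) {
      ch <- img[, , k]; ch[idx2] <- shade * c(1, 0.9, 0.8)[k]; img[, , k] <- ch
    }
  }
  list(img = img, hair_mask = hair_mask)
}

#' Generate one synthetic lesion image with its ground-truth mask
#'
#' Renders a single irregular-bordered pigmented lesion, darker than the skin
#' background by a class-dependent margin, with optional hair strokes and an
#' illumination gradient. Deterministic given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param class_index 1-based class index.
#' @param seed per-image RNG seed.
#' @return list with elements `image` (RGB array), `mask` (ground-truth lesion
#'   mask) and `hair_mask` (ground-truth stroke pixels).
#' @export
generate_lesion_image <- function(spec, class_index, seed = spec$seed) {
  if (class_index < 1 || class_index > spec$n_classes)
    stop("class_index out of range: ", class_index)
  p <- spec$class_params[[class_index]]
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(seed, {
    center <- c(h / 2 + runif(1, -h / 12, h / 12),
                w / 2 + runif(1, -w / 12, w / 12))
    radius <- max(4, rnorm(1, p$mean_radius, p$radius_sd))
    radius <- min(radius, min(h, w) / 2 - 4)  # keep strictly inside bounds
    aspect <- runif(1, 0.8, 1.25)
    mask <- lesion_mask_field(h, w, center, radius, p$border_irregularity, aspect)

    img <- array(0, c(h, w, 3))
    txb <- texture_field(h, w, p$texture_grain)
    txl <- texture_field(h, w, p$texture_grain)
    illum <- 0
    if (spec$illumination_gradient_amplitude > 0) {
      dirr <- runif(1, 0, 2 * pi)
      g <- expand.grid(r = seq_len(h), c = seq_len(w))
      proj <- (g$r - h / 2) * sin(dirr) + (g$c - w / 2) * cos(dirr)
      illum <- matrix(proj / max(abs(proj)), h, w) *
        spec$illumination_gradient_amplitude
    }
    for (k in 1:3) {
      bg <- p$background_rgb[k] + p$background_spread * txb
      fg <- p$lesion_rgb[k] + p$lesion_spread * txl
      img[, , k] <- clip255(bg * (1 - mask) + fg * mask + illum)
    }

    hair_mask <- matrix(0, h, w)
    n_hair <- if (spec$hair_density > 0) rpois(1, spec$hair_density) else 0L
    if (n_hair > 0) for (i in seq_len(n_hair)) {
      res <- draw_hair(img, hair_mask)
      img <- res$img; hair_mask <- res$hair_mask
    }
    img <- round(img)  # 8-bit quantization, as stored in PNG
    list(image = img, mask = mask, hair_mask = hair_mask)
  })
}

per_image_seed <- function(dataset_seed, image_index) {
  # deterministic per-image reseeding; stays well below 2^31
  (as.integer(dataset_seed) %% 1000003L) * 2011L + as.integer(image_index)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `per_class_counts[i]` images for each class. With `out_dir` set, the
#' images, their ground-truth masks (`*_mask.png`, values 0/255) and a CSV
#' manifest `manifest.csv` (`filename,label`) are written to disk; otherwise
#' everything stays in memory. Each image is seeded from
#' `(dataset seed, image index)` so any single image can be regenerated.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory, or `NULL` for an in-memory dataset.
#' @return a `labeled_dataset`: list with `records` (data.frame
#'   `filename,label`), `class_names`, `manifest_path` (or `NA`), and, for
#'   in-memory datasets, `images`, `masks` and `hair_masks` lists.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  recs <- list(); images <- list(); masks <- list(); hairs <- list()
  idx <- 0L
  for (cl in seq_len(spec$n_classes)) {
    for (j in seq_len(spec$per_class_counts[cl])) {
      idx <- idx + 1L
      g <- generate_lesion_image(spec, cl, seed = per_image_seed(spec$seed, idx))
      fn <- sprintf("img_%04d.png", idx)
      recs[[idx]] <- data.frame(filename = fn,
                                label = spec$class_names[cl],
                                stringsAsFactors = FALSE)
      if (write_out) {
        write_image(g$image, file.path(out_dir, fn))
        write_image(g$mask * 255, file.path(out_dir, sub("\\.png$", "_mask.png", fn)))
      } else {
        images[[idx]] <- g$image; masks[[idx]] <- g$mask
        hairs[[idx]] <- g$hair_mask
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
  else data.frame(filename = character(), label = character(),
                  stringsAsFactors = FALSE)
  ds <- structure(list(records = records, class_names = spec$class_names,
                       manifest_path = NA_character_, dir = out_dir),
                  class = "labeled_dataset")
  if (write_out) {
    ds$manifest_path <- file.path(out_dir, "manifest.csv")
    write_manifest(ds, ds$manifest_path)
  } else {
    ds$images <- images; ds$masks <- masks; ds$hair_masks <- hairs
  }
  ds
}

#' Read a dataset manifest
#'
#' Parses a CSV manifest with header `filename,label`. Every label must be a
#' member of the declared class set; a violating row is reported by line
#' number.
#'
#' @param path manifest CSV path.
#' @param class_names declared class labels; defaults to the sorted set of
#'   labels present in the file.
#' @return a `labeled_dataset` handle (records, class names, manifest path).
#' @export
read_manifest <- function(path, class_names = NULL) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df)[1:2], c("filename", "label")))
    stop("manifest must have header 'filename,label': ", path)
  if (nrow(df)) {
    bad <- which(is.na(df$filename) | df$filename == "" |
                   is.na(df$label) | df$label == "")
    if (length(bad))
      stop(sprintf("malformed manifest row at line %d of %s", bad[1] + 1L, path))
  }
  if (is.null(class_names)) class_names <- sort(unique(df$label))
  unknown <- which(!(df$label %in% class_names))
  if (length(unknown))
    stop(sprintf("unknown label '%s' at line %d of %s",
                 df$label[unknown[1]], unknown[1] + 1L, path))
  structure(list(records = df[, c("filename", "label")],
                 class_names = class_names,
                 manifest_path = path, dir = dirname(path)),
            class = "labeled_dataset")
}

#' Write a dataset manifest
#'
#' @param ds a `labeled_dataset`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ds, path) {
  write.csv(ds$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$records), "records,",
      length(x$class_names), "classes\n")
  print(table(factor(x$records$label, levels = x$class_names)))
  invisible(x)
}
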