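#' @useDynLib lesionlab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var quantile setNames predict
#' @importFrom utils read.csv write.csv head modifyList
NULL

# ---- internal image representation ------------------------------------------
# RGB images are h x w x 3 numeric arrays on the 0..255 scale; grayscale images
# are h x w matrices, either on 0..255 ("uint8") or 0..1 ("unit"). Masks are
# h x w matrices with values in {0, 1}; label maps are integer matrices with
# 0 = background/ridge.

#' Validate an RGB image array
#'
#' Checks the shared image contract used throughout the package: a numeric
#' `h x w x 3` array with all values in `[0, 255]` and both spatial dimensions
#' at least 8 pixels.
#'
#' @param img object to validate.
#' @param arg name used in error messages.
#' @return `img`, invisibly.
#' @export
validate_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("%s must be an h x w x 3 array", arg))
  if (dim(img)[1] < 8L || dim(img)[2] < 8L)
    stop(sprintf("%s must be at least 8 x 8 pixels", arg))
  if (!is.numeric(img) || anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("%s values must lie in [0, 255]", arg))
  invisible(img)
}

#' Validate a grayscale image matrix
#'
#' @param img object to validate.
#' @param scale `"uint8"` for the 0..255 convention, `"unit"` for 0..1.
#' @param arg name used in error messages.
#' @return `img`, invisibly.
#' @export
validate_gray <- function(img, scale = c("uint8", "unit"), arg = "img") {
  scale <- match.arg(scale)
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", arg))
  hi <- if (scale == "uint8") 255 else 1
  if (anyNA(img) || min(img) < 0 || max(img) > hi)
    stop(sprintf("%s values must lie in [0, %s]", arg, hi))
  invisible(img)
}

#' Validate a binary mask
#' @param mask object to validate.
#' @param arg name used in error messages.
#' @return `mask`, invisibly.
#' @export
validate_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop(sprintf("%s must be a matrix with values in {0, 1}", arg))
  invisible(mask)
}

#' Convert an RGB image to grayscale luminance
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, on the same 0..255 scale as
#' the input.
#'
#' @param img RGB array (`h x w x 3`, 0..255).
#' @return grayscale matrix on 0..255.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by (dr, dc) with replicate (edge-clamp) padding.
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Bilinear sampling of matrix m at fractional (row, col) coordinates with
# replicate edge handling. rows/cols are equal-length vectors.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- rows - r0; fc <- cols - c0
  idx <- function(r, c) m[cbind(r, c)]
  idx(r0, c0) * (1 - fr) * (1 - fc) + idx(r1, c0) * fr * (1 - fc) +
    idx(r0, c1) * (1 - fr) * fc + idx(r1, c1) * fr * fc
}

# Inverse-mapped affine resampling about the image center: rotation by `angle`
# degrees and isotropic scale `zoom`, bilinear interpolation, replicate
# padding. Applied per channel for RGB arrays.
affine_sample <- function(img, angle = 0, zoom = 1) {
  ap <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    th <- -angle * pi / 180  # inverse map
    g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    dr <- (g$r - cr) / zoom; dc <- (g$c - cc) / zoom
    rs <- cr + dr * cos(th) - dc * sin(th)
    cs <- cc + dr * sin(th) + dc * cos(th)
    matrix(bilinear_sample(m, rs, cs), nr, nc)
  }
  if (is.matrix(img)) return(ap(img))
  out <- img
  for (k in 1:3) out[, , k] <- ap(img[, , k])
  out
}

# ---- PNG I/O ----------------------------------------------------------------

#' Read an image file
#'
#' Reads a PNG (or JPEG, if the file extension says so) into the package's
#' 0..255 array convention. Grayscale files come back as matrices, color files
#' as `h x w x 3` arrays (any alpha channel is dropped).
#'
#' @param path file path.
#' @return numeric matrix or `h x w x 3` array on 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  round(a * 255)
}

#' Write an image file
#'
#' Writes a matrix (grayscale) or `h x w x 3` array (RGB) on the 0..255 scale
#' as an 8-bit PNG.
#'
#' @param img image to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b binary masks of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  validate_mask(a, "a"); validate_mask(b, "b")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
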