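# Enhancement = m x n average (mean) filtering followed by Laplacian
# sharpening; hair removal = DullRazor-style detection of dark strokes via
# oriented grayscale morphological closings and interpolation of the detected
# pixels.

#' Enhancement parameters
#'
#' @param window_m,window_n odd mean-filter window dimensions (default 5 x 5).
#' @param laplacian_kernel `"four"` (center -4) or `"eight"` (center -8)
#'   3 x 3 stencil.
#' @param sharpen_weight nonnegative sharpening weight `lambda`; 0 disables
#'   sharpening.
#' @param border_mode edge handling; only `"replicate"` is implemented.
#' @return list of validated parameters.
#' @export
enhancement_params <- function(window_m = 5, window_n = 5,
                               laplacian_kernel = c("four", "eight"),
                               sharpen_weight = 1,
                               border_mode = "replicate") {
  laplacian_kernel <- match.arg(laplacian_kernel)
  if (window_m %% 2 == 0 || window_n %% 2 == 0 || window_m < 3 || window_n < 3)
    stop("filter window dimensions must be odd and >= 3")
  if (sharpen_weight < 0) stop("sharpen_weight must be >= 0")
  if (border_mode != "replicate") stop("only replicate border handling is implemented")
  list(window_m = as.integer(window_m), window_n = as.integer(window_n),
       laplacian_kernel = laplacian_kernel, sharpen_weight = sharpen_weight,
       border_mode = border_mode)
}

#' Mean (average) filter
#'
#' Replaces each pixel by the arithmetic mean of its `m x n` neighborhood;
#' borders use replicate padding. RGB inputs are filtered per channel.
#'
#' @param img grayscale matrix or RGB array.
#' @param params an [enhancement_params()] list.
#' @return filtered image of the same type.
#' @export
average_filter <- function(img, params = enhancement_params()) {
  ap <- function(m) {
    acc <- matrix(0, nrow(m), ncol(m))
    hr <- (params$window_m - 1L) %/% 2L
    hc <- (params$window_n - 1L) %/% 2L
    for (dr in -hr:hr) for (dc in -hc:hc) acc <- acc + shift_pad(m, dr, dc)
    acc / (params$window_m * params$window_n)
  }
  if (is.matrix(img)) return(ap(img))
  out <- img
  for (k in 1:3) out[, , k] <- ap(img[, , k])
  out
}

#' Discrete Laplacian
#'
#' 3 x 3 approximation of `d2f/dx2 + d2f/dy2`. The default four-neighbor
#' stencil is `[0 1 0; 1 -4 1; 0 1 0]`; the eight-neighbor variant uses all
#' neighbors with center -8. Output is signed; linear ramps map to 0 in the
#' interior.
#'
#' @param img grayscale matrix.
#' @param kernel `"four"` or `"eight"`.
#' @return signed matrix of the same shape.
#' @export
laplacian_filter <- function(img, kernel = c("four", "eight")) {
  kernel <- match.arg(kernel)
  if (!is.matrix(img)) stop("laplacian_filter expects a grayscale matrix")
  out <- shift_pad(img, -1, 0) + shift_pad(img, 1, 0) +
    shift_pad(img, 0, -1) + shift_pad(img, 0, 1)
  if (kernel == "four") return(out - 4 * img)
  out + shift_pad(img, -1, -1) + shift_pad(img, -1, 1) +
    shift_pad(img, 1, -1) + shift_pad(img, 1, 1) - 8 * img
}

#' Combined mean + Laplacian enhancement
#'
#' Per channel: `out = clip(avg(img) - lambda * laplacian(avg(img)), 0, 255)`.
#' Subtracting the (negative-center) Laplacian is the classic sharpening that
#' restores edge contrast lost to the mean filter; `lambda = 0` reduces to
#' pure average filtering.
#'
#' @param img RGB array or grayscale matrix on 0..255.
#' @param params an [enhancement_params()] list.
#' @return enhanced image of the same type, values in `[0, 255]`.
#' @export
enhance <- function(img, params = enhancement_params()) {
  ap <- function(m) {
    a <- average_filter(m, params)
    clip255(a - params$sharpen_weight * laplacian_filter(a, params$laplacian_kernel))
  }
  if (is.matrix(img)) return(ap(img))
  out <- img
  for (k in 1:3) out[, , k] <- ap(img[, , k])
  out
}

#' Hair-removal parameters
#'
#' @param se_length length (px) of the oriented linear structuring elements.
#' @param se_angles stroke-detection orientations in degrees.
#' @param hair_threshold closing-minus-original intensity cutoff (0..255).
#'   Must exceed the closing residue that plain skin texture produces (a few
#'   times the local texture amplitude) while staying well below the
#'   hair-to-skin contrast, which is an order of magnitude larger.
#' @param mask_dilation binary dilation iterations applied to the hair mask.
#' @param min_stroke_area minimum pixel count of a detected component for it
#'   to count as a hair stroke; smaller detections are texture speckle.
#' @param max_thick_fraction maximum fraction of a component's pixels that may
#'   survive a 3 x 3 erosion. Hairs are at most a few pixels wide, so almost
#'   none of their pixels have a fully-detected 8-neighborhood; compact
#'   texture blobs fail this thinness test and are discarded.
#' @return list of validated parameters.
#' @export
hair_removal_params <- function(se_length = 9,
                                se_angles = c(0, 45, 90, 135),
                                hair_threshold = 25,
                                mask_dilation = 1,
                                min_stroke_area = 30,
                                max_thick_fraction = 0.25) {
  if (se_length < 3) stop("se_length must be >= 3")
  if (hair_threshold <= 0) stop("hair_threshold must be > 0")
  if (max_thick_fraction < 0 || max_thick_fraction > 1)
    stop("max_thick_fraction must lie in [0, 1]")
  list(se_length = as.integer(se_length), se_angles = se_angles,
       hair_threshold = hair_threshold, mask_dilation = as.integer(mask_dilation),
       min_stroke_area = as.integer(min_stroke_area),
       max_thick_fraction = max_thick_fraction)
}

line_offsets <- function(length, angle_deg) {
  half <- (length - 1) / 2
  th <- angle_deg * pi / 180
  t <- seq(-half, half)
  unique(cbind(round(t * sin(th)), round(t * cos(th))))
}

# Grayscale dilation/erosion with an arbitrary offset set (replicate padding).
gray_dilate <- function(m, offs) {
  out <- shift_pad(m, offs[1, 1], offs[1, 2])
  if (nrow(offs) > 1) for (i in 2:nrow(offs))
    out <- pmax(out, shift_pad(m, offs[i, 1], offs[i, 2]))
  out
}
gray_erode <- function(m, offs) {
  out <- shift_pad(m, -offs[1, 1], -offs[1, 2])
  if (nrow(offs) > 1) for (i in 2:nrow(offs))
    out <- pmin(out, shift_pad(m, -offs[i, 1], -offs[i, 2]))
  out
}
gray_closing <- function(m, offs) gray_erode(gray_dilate(m, offs), offs)

# Keep only long, thin detected components: discard speckle (area below
# min_stroke_area) and compact blobs (too many pixels whose full 3 x 3
# neighborhood is detected).
filter_stroke_components <- function(mask, params) {
  if (sum(mask) == 0) return(mask)
  lab <- .cc_label_cpp(matrix(1L, nrow(mask), ncol(mask)), mask == 1, 8L)
  eroded <- matrix(1, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1)
    eroded <- pmin(eroded, shift_pad(mask, dr, dc))
  # border pixels can never have a full interior neighborhood under
  # replicate padding, which is the conservative choice for thinness
  keep <- mask
  for (l in seq_len(max(lab))) {
    px <- lab == l
    area <- sum(px)
    thick <- sum(eroded[px]) / area
    if (area < params$min_stroke_area || thick > params$max_thick_fraction)
      keep[px] <- 0
  }
  keep
}

binary_dilate3 <- function(mask, iterations = 1) {
  for (i in seq_len(iterations)) {
    acc <- mask
    for (dr in -1:1) for (dc in -1:1) acc <- pmax(acc, shift_pad(mask, dr, dc))
    mask <- acc
  }
  mask
}

#' DullRazor-style hair removal
#'
#' Detects dark strokes as pixels where the best (brightest) of the oriented
#' grayscale closings exceeds the original luminance by more than
#' `hair_threshold`, dilates the detection mask, and replaces masked pixels by
#' linear interpolation between the nearest non-hair pixels along the
#' direction perpendicular to the detected stroke. Pixels outside the mask
#' are returned unchanged.
#'
#' @param img RGB array on 0..255.
#' @param params a [hair_removal_params()] list.
#' @return list with `cleaned` (RGB array) and `hair_mask` (binary matrix).
#' @export
remove_hair <- function(img, params = hair_removal_params()) {
  validate_rgb(img)
  gray <- rgb_to_gray(img)
  closings <- lapply(params$se_angles, function(a)
    gray_closing(gray, line_offsets(params$se_length, a)))
  best <- Reduce(pmax, closings)
  hair_mask <- matrix(as.numeric(best - gray > params$hair_threshold),
                      nrow(gray), ncol(gray))
  hair_mask <- filter_stroke_components(hair_mask, params)
  # stroke orientation = angle whose closing changed the pixel least
  resp <- vapply(closings, function(cl) as.vector(cl - gray),
                 numeric(length(gray)))
  stroke_angle <- matrix(params$se_angles[max.col(-resp, ties.method = "first")],
                         nrow(gray), ncol(gray))
  if (params$mask_dilation > 0)
    hair_mask <- binary_dilate3(hair_mask, params$mask_dilation)

  cleaned <- img
  px <- which(hair_mask == 1, arr.ind = TRUE)
  if (nrow(px) > 0) {
    h <- nrow(gray); w <- ncol(gray)
    maxstep <- max(h, w)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      perp <- (stroke_angle[r, c] + 90) * pi / 180
      dr <- sin(perp); dc <- cos(perp)
      find_edge <- function(sgn) {
        for (k in seq_len(maxstep)) {
          rr <- round(r + sgn * k * dr); cc <- round(c + sgn * k * dc)
          if (rr < 1 || rr > h || cc < 1 || cc > w) return(NULL)
          if (hair_mask[rr, cc] == 0) return(c(rr, cc, k))
        }
        NULL
      }
      e1 <- find_edge(1); e2 <- find_edge(-1)
      if (is.null(e1) && is.null(e2)) next
      for (k in 1:3) {
        v1 <- if (!is.null(e1)) img[e1[1], e1[2], k] else NA
        v2 <- if (!is.null(e2)) img[e2[1], e2[2], k] else NA
        cleaned[r, c, k] <-
          if (is.null(e2)) v1
          else if (is.null(e1)) v2
          else (v1 * e2[3] + v2 * e1[3]) / (e1[3] + e2[3])
      }
    }
  }
  list(cleaned = cleaned, hair_mask = hair_mask)
}
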