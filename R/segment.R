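# Marker-controlled watershed lesion segmentation: gradient magnitude ->
# sure background (adaptive threshold + closing) -> Euclidean distance
# transform -> sure foreground (fraction-of-max threshold) -> marker labeling
# -> priority-queue flooding -> lesion basin selection and ROI crop.

#' Watershed segmentation parameters
#'
#' @param tau sure-foreground fraction in (0, 1): the distance map is
#'   thresholded at `tau * max(D)`.
#' @param alpha_min minimum lesion basin area in pixels; smaller basins are
#'   treated as spurious.
#' @param bg_threshold_mode `"otsu"` (adaptive) or `"fixed"`.
#' @param T_bg fixed background threshold (0..255), used when
#'   `bg_threshold_mode = "fixed"`.
#' @param closing_se apply one 5 x 5 morphological closing to the background
#'   mask.
#' @param gradient_mode `"central_difference"` (the plain two-point gradient)
#'   or `"sobel"`.
#' @param smoothing `"average"` (5 x 5 mean filter) or `"median"` smoothing
#'   before background thresholding.
#' @param invert_polarity set when the lesion is brighter than the skin;
#'   default assumes a dark lesion on lighter background.
#' @param keep_lines label watershed ridge pixels 0 instead of absorbing them.
#' @param min_core_distance minimum depth (px) of the distance-transform peak
#'   for a lesion core to be accepted; guards against marker noise on
#'   lesion-free images.
#' @param min_contrast minimum luminance separation between the mean
#'   background and mean non-background intensity. Otsu's threshold always
#'   splits an image, even a unimodal lesion-free one; requiring real
#'   contrast between the two sides turns that case into a structured
#'   failure instead of a spurious segmentation.
#' @return list of validated parameters.
#' @export
watershed_params <- function(tau = 0.4, alpha_min = 100,
                             bg_threshold_mode = c("otsu", "fixed"),
                             T_bg = 128,
                             closing_se = TRUE,
                             gradient_mode = c("central_difference", "sobel"),
                             smoothing = c("average", "median"),
                             invert_polarity = FALSE,
                             keep_lines = FALSE,
                             min_core_distance = 3,
                             min_contrast = 15) {
  bg_threshold_mode <- match.arg(bg_threshold_mode)
  gradient_mode <- match.arg(gradient_mode)
  smoothing <- match.arg(smoothing)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (alpha_min < 0) stop("alpha_min must be >= 0")
  if (min_contrast < 0) stop("min_contrast must be >= 0")
  list(tau = tau, alpha_min = alpha_min,
       bg_threshold_mode = bg_threshold_mode, T_bg = T_bg,
       closing_se = closing_se, gradient_mode = gradient_mode,
       smoothing = smoothing, invert_polarity = invert_polarity,
       keep_lines = keep_lines, min_core_distance = min_core_distance,
       min_contrast = min_contrast)
}

#' Gradient magnitude of a grayscale image
#'
#' `central_difference` evaluates `Gx = I(x+1,y) - I(x-1,y)`,
#' `Gy = I(x,y+1) - I(x,y-1)` and `|grad I| = sqrt(Gx^2 + Gy^2)` per pixel;
#' `sobel` uses the standard 3 x 3 Sobel kernels. Borders use replicate
#' padding, so the output is zero along a flat border.
#'
#' @param img grayscale matrix.
#' @param mode `"central_difference"` or `"sobel"`.
#' @return nonnegative gradient magnitude matrix.
#' @export
gradient_magnitude <- function(img, mode = c("central_difference", "sobel")) {
  mode <- match.arg(mode)
  if (!is.matrix(img)) stop("gradient_magnitude expects a grayscale matrix")
  if (mode == "central_difference") {
    gx <- shift_pad(img, 1, 0) - shift_pad(img, -1, 0)
    gy <- shift_pad(img, 0, 1) - shift_pad(img, 0, -1)
  } else {
    gx <- (shift_pad(img, 1, -1) + 2 * shift_pad(img, 1, 0) + shift_pad(img, 1, 1)) -
      (shift_pad(img, -1, -1) + 2 * shift_pad(img, -1, 0) + shift_pad(img, -1, 1))
    gy <- (shift_pad(img, -1, 1) + 2 * shift_pad(img, 0, 1) + shift_pad(img, 1, 1)) -
      (shift_pad(img, -1, -1) + 2 * shift_pad(img, 0, -1) + shift_pad(img, 1, -1))
  }
  sqrt(gx^2 + gy^2)
}

box_offsets <- function(size) {
  half <- (size - 1) %/% 2
  as.matrix(expand.grid(seq(-half, half), seq(-half, half)))
}

#' Sure-background mask
#'
#' Thresholds the smoothed grayscale image (`intensity > T` marks background;
#' Otsu's method supplies `T` in adaptive mode) and applies one 5 x 5
#' morphological closing to fill small holes. With `invert_polarity` the
#' comparison is flipped for bright-lesion images.
#'
#' @param img_smoothed smoothed grayscale matrix on 0..255.
#' @param params a [watershed_params()] list.
#' @return binary background mask.
#' @export
sure_background <- function(img_smoothed, params = watershed_params()) {
  if (params$bg_threshold_mode == "otsu") {
    if (max(img_smoothed) == min(img_smoothed)) {
      warning("uniform image: falling back to global-mean threshold")
      T_bg <- mean(img_smoothed)
    } else {
      T_bg <- EBImage::otsu(EBImage::Image(img_smoothed / 255),
                            range = c(0, 1)) * 255
    }
  } else T_bg <- params$T_bg
  mask <- if (params$invert_polarity) img_smoothed < T_bg else img_smoothed > T_bg
  mask <- matrix(as.numeric(mask), nrow(img_smoothed), ncol(img_smoothed))
  if (isTRUE(params$closing_se)) {
    offs <- box_offsets(5)
    mask <- gray_erode(gray_dilate(mask, offs), offs)
  }
  attr(mask, "threshold") <- T_bg
  mask
}

#' Euclidean distance transform of the non-background support
#'
#' For each non-background pixel (`bg = 0`), the Euclidean distance to the
#' nearest background pixel; zero on the background itself.
#'
#' @param bg binary sure-background mask.
#' @return nonnegative distance matrix.
#' @export
distance_transform <- function(bg) {
  validate_mask(bg, "bg")
  s <- sum(bg)
  if (s == 0 || s == length(bg))
    stop("degenerate background mask: need both background and non-background pixels")
  d <- EBImage::distmap(EBImage::Image(1 - bg), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(bg), ncol(bg))
}

#' Sure-foreground mask
#'
#' Thresholds the distance map at a fraction `tau` of its maximum:
#' `F_sure = 1` where `D > tau * max(D)`.
#'
#' @param D distance matrix from [distance_transform()].
#' @param tau fraction in (0, 1).
#' @return binary foreground mask.
#' @export
sure_foreground <- function(D, tau = 0.4) {
  if (max(D) <= 0) stop("distance map has no positive values")
  matrix(as.numeric(D > tau * max(D)), nrow(D), ncol(D))
}

#' Label watershed markers
#'
#' Each 8-connected component of the sure-foreground mask receives a unique
#' positive label `1..K`; sure-background pixels not claimed by a foreground
#' component carry the reserved background label `K + 1`; everything else is
#' 0 (unknown, to be flooded).
#'
#' @param sure_fg,sure_bg binary masks of identical shape.
#' @return list with `labels` (integer matrix), `n_foreground` (K) and
#'   `background_label` (K + 1).
#' @export
label_markers <- function(sure_fg, sure_bg) {
  validate_mask(sure_fg, "sure_fg"); validate_mask(sure_bg, "sure_bg")
  if (!all(dim(sure_fg) == dim(sure_bg)))
    stop("sure_fg and sure_bg must share a shape")
  if (sum(sure_fg) == 0) stop("empty sure-foreground mask: no lesion marker")
  ones <- matrix(1L, nrow(sure_fg), ncol(sure_fg))
  lab <- .cc_label_cpp(ones, sure_fg == 1, 8L)
  K <- max(lab)
  bg_label <- K + 1L
  lab[sure_bg == 1 & lab == 0L] <- bg_label
  list(labels = lab, n_foreground = K, background_label = bg_label)
}

#' Marker-controlled watershed flooding
#'
#' Floods the gradient surface from the labeled markers: pixels are claimed
#' in ascending gradient order (FIFO tie-break), each joining the basin that
#' reaches it first. With `keep_lines` the pixels where two basins meet are
#' labeled 0 (watershed ridges); otherwise every pixel belongs to exactly one
#' basin.
#'
#' @param gradient nonnegative gradient matrix.
#' @param markers integer marker label matrix (0 = unknown).
#' @param keep_lines keep watershed ridge pixels as label 0.
#' @param connectivity 4 (default) or 8 for the flooding neighborhood.
#' @return integer basin label matrix.
#' @export
watershed_flood <- function(gradient, markers, keep_lines = FALSE,
                            connectivity = 4) {
  if (!all(dim(gradient) == dim(markers)))
    stop("gradient and markers must share a shape")
  if (max(markers) < 1) stop("no markers to flood from")
  storage.mode(markers) <- "integer"
  .watershed_flood_cpp(gradient, markers, as.integer(connectivity),
                       isTRUE(keep_lines))
}

#' Select the lesion basin and crop its ROI
#'
#' Among non-background basins with area at least `alpha_min`, picks the one
#' with the largest intersection with the sure-foreground mask (ties broken
#' by larger basin, then lower label). Returns the lesion mask, its tight
#' half-open bounding box `(row0, col0, row1, col1)` and the RGB crop. When
#' no basin qualifies, a structured failure result is returned so the caller
#' can fall back to the full image.
#'
#' @param basins basin label matrix from [watershed_flood()].
#' @param sure_fg sure-foreground mask.
#' @param img original RGB array.
#' @param params a [watershed_params()] list.
#' @param background_label reserved background marker label.
#' @return list with `failure` flag plus, on success, `lesion_mask`,
#'   `roi_bbox` and `roi_image`.
#' @export
select_lesion_roi <- function(basins, sure_fg, img,
                              params = watershed_params(),
                              background_label = max(basins)) {
  labs <- sort(setdiff(unique(as.vector(basins)), c(0L, background_label)))
  if (length(labs) == 0)
    return(list(failure = TRUE, reason = "no non-background basin"))
  areas <- vapply(labs, function(l) sum(basins == l), numeric(1))
  keep <- areas >= params$alpha_min
  if (!any(keep))
    return(list(failure = TRUE, reason = sprintf(
      "no basin reaches alpha_min = %d px (largest: %d)",
      params$alpha_min, as.integer(max(areas)))))
  labs <- labs[keep]; areas <- areas[keep]
  overlap <- vapply(labs, function(l) sum(basins == l & sure_fg == 1), numeric(1))
  ord <- order(-overlap, -areas, labs)
  sel <- labs[ord[1]]
  lesion_mask <- matrix(as.numeric(basins == sel), nrow(basins), ncol(basins))
  rows <- range(which(rowSums(lesion_mask) > 0))
  cols <- range(which(colSums(lesion_mask) > 0))
  bbox <- c(row0 = rows[1], col0 = cols[1], row1 = rows[2] + 1L, col1 = cols[2] + 1L)
  roi <- img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  list(failure = FALSE, lesion_mask = lesion_mask, roi_bbox = bbox,
       roi_image = roi, basin_label = sel,
       basin_areas = setNames(areas, labs))
}

#' Segment a lesion with the full marker-controlled watershed pipeline
#'
#' Composes gradient computation, background thresholding, distance
#' transform, foreground thresholding, marker labeling, flooding and ROI
#' selection. Any stage failure (for example a lesion-free image producing no
#' usable marker) is returned as a structured failure result rather than an
#' error.
#'
#' @param img preprocessed RGB array on 0..255.
#' @param params a [watershed_params()] list.
#' @return object of class `lesion_segmentation`: all intermediate grids plus
#'   `lesion_mask`, `roi_bbox`, `roi_image` and a `failure` flag.
#' @export
segment_lesion <- function(img, params = watershed_params()) {
  validate_rgb(img)
  fail <- function(stage, reason) structure(
    list(failure = TRUE, stage = stage, reason = reason),
    class = "lesion_segmentation")
  gray <- rgb_to_gray(img)
  smoothed <- if (params$smoothing == "average") {
    average_filter(gray, enhancement_params(5, 5, sharpen_weight = 0))
  } else {
    m <- EBImage::medianFilter(EBImage::Image(gray / 255), size = 2) * 255
    matrix(as.numeric(EBImage::imageData(m)), nrow(gray), ncol(gray))
  }
  gradient <- gradient_magnitude(gray, params$gradient_mode)
  bg <- tryCatch(sure_background(smoothed, params),
                 error = function(e) NULL)
  if (is.null(bg)) return(fail("sure_background", "thresholding failed"))
  mu_bg <- mean(smoothed[bg == 1]); mu_other <- mean(smoothed[bg == 0])
  if (!is.finite(mu_bg) || !is.finite(mu_other) ||
      abs(mu_bg - mu_other) < params$min_contrast)
    return(fail("sure_background", sprintf(
      "weak foreground/background contrast (%.1f < %g): no lesion evidence",
      if (is.finite(mu_bg) && is.finite(mu_other)) abs(mu_bg - mu_other) else 0,
      params$min_contrast)))
  D <- tryCatch(distance_transform(bg), error = function(e) NULL)
  if (is.null(D)) return(fail("distance_transform", "degenerate background mask"))
  if (max(D) < params$min_core_distance)
    return(fail("sure_foreground", sprintf(
      "no lesion core: max distance %.2f px < %g", max(D), params$min_core_distance)))
  fg <- sure_foreground(D, params$tau)
  mk <- tryCatch(label_markers(fg, bg), error = function(e) NULL)
  if (is.null(mk)) return(fail("label_markers", "no foreground marker"))
  basins <- watershed_flood(gradient, mk$labels, keep_lines = params$keep_lines)
  sel <- select_lesion_roi(basins, fg, img, params, mk$background_label)
  if (isTRUE(sel$failure)) return(fail("select_lesion_roi", sel$reason))
  structure(list(
    failure = FALSE, gradient = gradient, sure_bg = bg, distance = D,
    sure_fg = fg, markers = mk$labels, background_label = mk$background_label,
    basins = basins, lesion_mask = sel$lesion_mask, roi_bbox = sel$roi_bbox,
    roi_image = sel$roi_image, basin_label = sel$basin_label,
    params = params), class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  if (isTRUE(x$failure)) {
    cat("lesion_segmentation: FAILURE at", x$stage, "-", x$reason, "\n")
  } else {
    cat("lesion_segmentation:", sum(x$lesion_mask), "lesion px; bbox [",
        paste(x$roi_bbox, collapse = ", "), ")\n")
  }
  invisible(x)
}
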