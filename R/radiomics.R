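# Handcrafted radiomic signature: gray-level size-zone matrix (16 features),
# gray-level dependence matrix (14), RGB color histogram block (16), local
# binary pattern histogram (50); concatenated in that fixed order into the
# 96-dimensional vector. Texture feature formulas follow the IBSI reference
# definitions (the standard sets have exactly 16 and 14 members).

#' Radiomics configuration
#'
#' @param n_gray number of gray levels for quantization (default 16).
#' @param gldm_alpha dependence tolerance: a neighbor is dependent when its
#'   level differs by at most `alpha` (default 0).
#' @param gldm_delta Chebyshev neighborhood radius (default 1).
#' @param ch_bins histogram bins per RGB channel (default 4).
#' @param lbp_p,lbp_r LBP neighbor count and radius (classic 8, 1).
#' @param lbp_bins number of equal-width bins the 256-code LBP histogram is
#'   folded into (default 50, giving the 96-feature total).
#' @param zone_connectivity zone connectivity for the size-zone matrix (8).
#' @return list of validated parameters.
#' @export
radiomics_config <- function(n_gray = 16, gldm_alpha = 0, gldm_delta = 1,
                             ch_bins = 4, lbp_p = 8, lbp_r = 1, lbp_bins = 50,
                             zone_connectivity = 8) {
  stopifnot(n_gray >= 2, gldm_alpha >= 0, gldm_delta >= 1, ch_bins >= 1,
            lbp_bins >= 1, zone_connectivity %in% c(4, 8))
  if (lbp_p != 8 || lbp_r != 1)
    stop("only the classic LBP parameterization (P = 8, R = 1) is implemented")
  list(n_gray = as.integer(n_gray), gldm_alpha = gldm_alpha,
       gldm_delta = as.integer(gldm_delta), ch_bins = as.integer(ch_bins),
       lbp_p = 8L, lbp_r = 1L, lbp_bins = as.integer(lbp_bins),
       zone_connectivity = as.integer(zone_connectivity))
}

#' Quantize a grayscale ROI into N_g levels
#'
#' Equal-width binning of the in-mask intensity range into `n_gray` levels
#' `1..N_g`; a constant region maps entirely to level 1. Quantization is
#' monotone in intensity.
#'
#' @param img grayscale matrix.
#' @param mask binary ROI mask (same shape).
#' @param n_gray number of levels.
#' @return list with `levels` (integer matrix, NA outside the mask), `mask`
#'   and `n_gray`.
#' @export
quantize <- function(img, mask, n_gray = 16) {
  validate_mask(mask)
  if (sum(mask) == 0) stop("empty mask")
  v <- img[mask == 1]
  lev <- matrix(NA_integer_, nrow(img), ncol(img))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev[mask == 1] <- 1L
  } else {
    sc <- (img - rng[1]) / (rng[2] - rng[1]) * n_gray
    l <- pmin(floor(sc) + 1L, n_gray)
    lev[mask == 1] <- as.integer(l[mask == 1])
  }
  list(levels = lev, mask = mask, n_gray = as.integer(n_gray))
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal connected components (8-connected by default) of equal
#' quantized level inside the mask; `P[i, s]` counts zones of level `i` and
#' size `s`.
#'
#' @param q quantized ROI from [quantize()].
#' @param connectivity 4 or 8.
#' @return list with `P` (N_g x max-size matrix), `n_gray`, `n_pixels`.
#' @export
compute_glszm <- function(q, connectivity = 8) {
  lev <- q$levels
  lev[is.na(lev)] <- 0L
  storage.mode(lev) <- "integer"
  lab <- .cc_label_cpp(lev, q$mask == 1, as.integer(connectivity))
  zl <- lab[q$mask == 1]
  zv <- lev[q$mask == 1]
  sizes <- tabulate(zl)
  zone_level <- integer(max(zl))
  zone_level[zl] <- zv
  smax <- max(sizes)
  P <- matrix(0, q$n_gray, smax)
  for (z in seq_along(sizes)) P[zone_level[z], sizes[z]] <- P[zone_level[z], sizes[z]] + 1
  list(P = P, n_gray = q$n_gray, n_pixels = sum(q$mask))
}

#' Size-zone features (16)
#'
#' The 16 standard size-zone statistics: small/large-area emphasis,
#' gray-level and size-zone non-uniformity (plain and normalized), zone
#' percentage, gray-level and zone variance, zone entropy, low/high
#' gray-level zone emphasis, and the four joint small/large x low/high
#' emphases. Degenerate single-zone matrices yield zero variances.
#'
#' @param m output of [compute_glszm()].
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(m) {
  P <- m$P
  Nz <- sum(P)
  if (Nz <= 0) stop("empty size-zone matrix")
  i <- row(P); s <- col(P)
  p <- P / Nz
  Pi <- rowSums(P); Ps <- colSums(P)
  mu_i <- sum(p * i); mu_s <- sum(p * s)
  pe <- p[p > 0]
  c(
    glszm_SmallAreaEmphasis = sum(P / s^2) / Nz,
    glszm_LargeAreaEmphasis = sum(P * s^2) / Nz,
    glszm_GrayLevelNonUniformity = sum(Pi^2) / Nz,
    glszm_GrayLevelNonUniformityNormalized = sum(Pi^2) / Nz^2,
    glszm_SizeZoneNonUniformity = sum(Ps^2) / Nz,
    glszm_SizeZoneNonUniformityNormalized = sum(Ps^2) / Nz^2,
    glszm_ZonePercentage = Nz / m$n_pixels,
    glszm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    glszm_ZoneVariance = sum(p * (s - mu_s)^2),
    glszm_ZoneEntropy = -sum(pe * log2(pe)),
    glszm_LowGrayLevelZoneEmphasis = sum(P / i^2) / Nz,
    glszm_HighGrayLevelZoneEmphasis = sum(P * i^2) / Nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * s^2)) / Nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / s^2) / Nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(P * s^2 / i^2) / Nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * s^2) / Nz
  )
}

# shift with NA fill (neighbors beyond the image do not exist)
shift_na <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  vr <- rs >= 1 & rs <= nr; vc <- cs >= 1 & cs <= nc
  out[vr, vc] <- m[rs[vr], cs[vc]]
  out
}

#' Gray-level dependence matrix
#'
#' For each in-mask pixel of level `i`, the dependence `d` is the number of
#' in-mask neighbors within Chebyshev distance `delta` whose level differs by
#' at most `alpha`. `P[i, d + 1]` counts pixels (dependence bins are indexed
#' from 1).
#'
#' @param q quantized ROI from [quantize()].
#' @param alpha dependence tolerance.
#' @param delta Chebyshev neighborhood radius.
#' @return list with `P`, `n_gray`, `n_pixels`.
#' @export
compute_gldm <- function(q, alpha = 0, delta = 1) {
  lev <- q$levels
  inmask <- q$mask == 1
  d <- matrix(0, nrow(lev), ncol(lev))
  for (dr in -delta:delta) for (dc in -delta:delta) {
    if (dr == 0 && dc == 0) next
    nb <- shift_na(lev, dr, dc)
    dep <- !is.na(nb) & !is.na(lev) & abs(nb - lev) <= alpha
    d <- d + dep
  }
  dd <- d[inmask] + 1L
  ii <- lev[inmask]
  P <- matrix(0, q$n_gray, max(dd))
  for (k in seq_along(dd)) P[ii[k], dd[k]] <- P[ii[k], dd[k]] + 1
  list(P = P, n_gray = q$n_gray, n_pixels = sum(q$mask))
}

#' Dependence features (14)
#'
#' The 14 standard dependence statistics: small/large-dependence emphasis,
#' gray-level non-uniformity, dependence non-uniformity (plain and
#' normalized), gray-level and dependence variance, dependence entropy,
#' low/high gray-level emphasis and the four joint emphases.
#'
#' @param m output of [compute_gldm()].
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(m) {
  P <- m$P
  Nz <- sum(P)
  if (Nz <= 0) stop("empty dependence matrix")
  i <- row(P); j <- col(P)
  p <- P / Nz
  Pi <- rowSums(P); Pj <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  pe <- p[p > 0]
  c(
    gldm_SmallDependenceEmphasis = sum(P / j^2) / Nz,
    gldm_LargeDependenceEmphasis = sum(P * j^2) / Nz,
    gldm_GrayLevelNonUniformity = sum(Pi^2) / Nz,
    gldm_DependenceNonUniformity = sum(Pj^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(Pj^2) / Nz^2,
    gldm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    gldm_DependenceVariance = sum(p * (j - mu_j)^2),
    gldm_DependenceEntropy = -sum(pe * log2(pe)),
    gldm_LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    gldm_HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz
  )
}

#' Color-histogram features (16)
#'
#' Per-channel normalized 4-bin histograms over `[0, 255]` (12 values), the
#' per-channel means divided by 255 (3 values) and the in-mask luminance
#' standard deviation divided by 255 (1 value). All outputs lie in `[0, 1]`
#' and each channel's histogram block sums to 1.
#'
#' @param img RGB array on 0..255.
#' @param mask binary ROI mask.
#' @param config a [radiomics_config()] list.
#' @return named numeric vector of length `3 * ch_bins + 4`.
#' @export
color_histogram_features <- function(img, mask, config = radiomics_config()) {
  validate_mask(mask)
  if (sum(mask) == 0) stop("empty mask")
  nb <- config$ch_bins
  chans <- c("R", "G", "B")
  out <- numeric(0)
  for (k in 1:3) {
    v <- img[, , k][mask == 1]
    bin <- pmin(floor(v / (256 / nb)) + 1L, nb)
    h <- tabulate(bin, nbins = nb) / length(v)
    names(h) <- sprintf("ch_%s_hist%d", chans[k], seq_len(nb))
    out <- c(out, h)
  }
  means <- vapply(1:3, function(k) mean(img[, , k][mask == 1]) / 255, numeric(1))
  names(means) <- sprintf("ch_mean_%s", chans)
  lum <- rgb_to_gray(img)[mask == 1]
  n <- length(lum)
  lsd <- sqrt(sum((lum - mean(lum))^2) / n) / 255
  c(out, means, ch_luminance_sd = lsd)
}

# 8 neighbors, clockwise from top-left; bit k has weight 2^(k-1)
lbp_offsets <- cbind(
  dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
  dc = c(-1, 0, 1, 1, 1, 0, -1, -1))

#' Local binary pattern features (50)
#'
#' Classic LBP with 8 neighbors at radius 1: for each interior in-mask pixel
#' an 8-bit code is formed (clockwise from the top-left neighbor; a neighbor
#' `>=` the center sets its bit). The 256-code histogram is folded into
#' `lbp_bins` contiguous equal-width bins (width `ceiling(256 / bins)`, tail
#' truncated) and normalized to sum 1.
#'
#' @param img grayscale matrix.
#' @param mask binary ROI mask with at least 9 pixels.
#' @param config a [radiomics_config()] list.
#' @return named numeric vector of length `lbp_bins`.
#' @export
lbp_features <- function(img, mask, config = radiomics_config()) {
  validate_mask(mask)
  if (sum(mask) < 9) stop("mask too small for LBP (need >= 9 px)")
  if (nrow(img) < 3 || ncol(img) < 3) stop("image too small for LBP")
  code <- matrix(0, nrow(img), ncol(img))
  interior <- matrix(TRUE, nrow(img), ncol(img))
  interior[c(1, nrow(img)), ] <- FALSE
  interior[, c(1, ncol(img))] <- FALSE
  for (k in 1:8) {
    nb <- shift_na(img, lbp_offsets[k, 1], lbp_offsets[k, 2])
    bit <- !is.na(nb) & nb >= img
    code <- code + bit * 2^(k - 1)
  }
  use <- interior & mask == 1
  if (!any(use)) stop("no interior in-mask pixels for LBP")
  codes <- code[use]
  width <- ceiling(256 / config$lbp_bins)
  bin <- pmin(floor(codes / width) + 1L, config$lbp_bins)
  h <- tabulate(bin, nbins = config$lbp_bins)
  h <- h / sum(h)
  setNames(h, sprintf("lbp_bin%02d", seq_len(config$lbp_bins)))
}

#' Extract the 96-dimensional radiomic vector
#'
#' Concatenates, in fixed order, the size-zone (16), dependence (14), color
#' histogram (16) and LBP (50) blocks computed on the masked ROI. Texture
#' matrices operate on the quantized grayscale ROI; the color block uses the
#' RGB values directly.
#'
#' @param img RGB array on 0..255.
#' @param mask binary ROI mask.
#' @param config a [radiomics_config()] list.
#' @return named numeric vector of length 96 with stable names.
#' @export
extract_radiomics <- function(img, mask, config = radiomics_config()) {
  validate_rgb(img)
  gray <- rgb_to_gray(img)
  q <- quantize(gray, mask, config$n_gray)
  f <- c(
    glszm_features(compute_glszm(q, config$zone_connectivity)),
    gldm_features(compute_gldm(q, config$gldm_alpha, config$gldm_delta)),
    color_histogram_features(img, mask, config),
    lbp_features(gray, mask, config)
  )
  if (any(!is.finite(f))) stop("non-finite radiomic feature value")
  f
}
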