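test_that("quantize is monotone, bounded and NA outside the mask", {
  set.seed(8)
  img <- matrix(runif(100, 0, 255), 10, 10)
  mask <- matrix(1, 10, 10); mask[1, ] <- 0
  q <- quantize(img, mask, 16)
  expect_true(all(is.na(q$levels[mask == 0])))
  lev <- q$levels[mask == 1]
  expect_true(all(lev >= 1 & lev <= 16))
  # monotone: higher intensity never maps to a lower level
  v <- img[mask == 1]
  o <- order(v)
  expect_true(all(diff(lev[o]) >= 0))
  # extremes hit the first and last level
  expect_equal(lev[which.min(v)], 1L)
  expect_equal(lev[which.max(v)], 16L)
  # constant region maps to level 1
  qc <- quantize(matrix(42, 5, 5), matrix(1, 5, 5), 16)
  expect_true(all(qc$levels == 1L))
  expect_error(quantize(img, matrix(0, 10, 10)), "empty mask")
})

test_that("GLSZM matches the brute-force zone enumeration on a worked example", {
  # hand-checkable 4x4: levels with known zones (8-connected)
  lev <- matrix(c(1, 1, 2, 2,
                  1, 1, 2, 3,
                  3, 1, 2, 3,
                  3, 3, 1, 1), 4, 4, byrow = TRUE)
  mask <- matrix(1, 4, 4)
  q <- list(levels = lev, mask = mask, n_gray = 3L)
  m <- compute_glszm(q, connectivity = 8)
  # zones (8-connected): level 1 one zone of 7 (the diagonal at (3,2)-(4,3)
  # joins the two blocks), level 2 one zone of 4, level 3 zones of 2 and 3
  expect_equal(sum(m$P), 4)
  expect_equal(m$P[1, 7], 1)
  expect_equal(m$P[2, 4], 1)
  expect_equal(m$P[3, 2], 1); expect_equal(m$P[3, 3], 1)
  ref <- oracle_glszm(lev, mask, 3)
  expect_equal(m$P[, seq_len(ncol(ref))], ref)
})

test_that("GLDM matches a worked example with alpha = 0, delta = 1", {
  lev <- matrix(c(1, 1, 2,
                  1, 2, 2,
                  3, 3, 3), 3, 3, byrow = TRUE)
  mask <- matrix(1, 3, 3)
  q <- list(levels = lev, mask = mask, n_gray = 3L)
  m <- compute_gldm(q, alpha = 0, delta = 1)
  expect_equal(sum(m$P), 9)  # one entry per in-mask pixel
  ref <- oracle_gldm(lev, mask, 3)
  expect_equal(m$P[, seq_len(ncol(ref))], ref)
  # corner (1,1) = level 1 has neighbors {1, 1, 2} -> dependence 2 -> column 3
  expect_gte(m$P[1, 3], 1)
})

test_that("texture matrices and all 30 features match oracles on random ROIs", {
  for (s in 1:12) {
    roi <- random_quantized_roi(7000 + s, size = 8, n_gray = 4)
    q <- list(levels = roi$levels, mask = roi$mask, n_gray = roi$n_gray)
    mz <- compute_glszm(q, 8)
    Pz_ref <- oracle_glszm(roi$levels, roi$mask, roi$n_gray)
    expect_equal(mz$P[, seq_len(ncol(Pz_ref)), drop = FALSE], Pz_ref,
                 tolerance = 1e-10)
    expect_equal(unname(glszm_features(mz)),
                 oracle_glszm_features(Pz_ref, sum(roi$mask)),
                 tolerance = 1e-10)
    md <- compute_gldm(q, 0, 1)
    Pd_ref <- oracle_gldm(roi$levels, roi$mask, roi$n_gray)
    expect_equal(md$P[, seq_len(ncol(Pd_ref)), drop = FALSE], Pd_ref,
                 tolerance = 1e-10)
    expect_equal(unname(gldm_features(md)), oracle_gldm_features(Pd_ref),
                 tolerance = 1e-10)
  }
})

test_that("color histogram block sums to 1 per channel with correct means", {
  img <- disc_image(16, 16, radius = 5, dark = 10, light = 250)
  mask <- matrix(1, 16, 16)
  f <- color_histogram_features(img, mask)
  expect_length(f, 16)
  for (ch in c("R", "G", "B"))
    expect_equal(sum(f[sprintf("ch_%s_hist%d", ch, 1:4)]), 1)
  expect_equal(unname(f["ch_mean_R"]), mean(img[, , 1]) / 255)
  # population sd of the luminance
  lum <- rgb_to_gray(img)
  expect_equal(unname(f["ch_luminance_sd"]),
               sqrt(mean((lum - mean(lum))^2)) / 255)
  # constant image: all mass in one bin, zero sd
  flat <- array(100, c(8, 8, 3))
  ff <- color_histogram_features(flat, matrix(1, 8, 8))
  expect_equal(unname(ff["ch_R_hist2"]), 1)  # 100 %/% 64 = 1 -> bin 2
  expect_equal(unname(ff["ch_luminance_sd"]), 0)
})

test_that("LBP codes match the classic definition on a worked example", {
  # center pixel 5 with known neighbors
  img <- matrix(c(6, 2, 7,
                  4, 5, 5,
                  1, 9, 3), 3, 3, byrow = TRUE)
  mask <- matrix(1, 3, 3)
  # clockwise from top-left: 6,2,7,5,3,9,1,4 vs center 5 -> bits 1,0,1,1,0,1,0,0
  # code = 1 + 4 + 8 + 32 = 45 -> bin floor(45/6)+1 = 8
  f <- lbp_features(img, mask, radiomics_config())
  expect_equal(unname(f["lbp_bin08"]), 1)
  expect_equal(sum(f), 1)
})

test_that("LBP histogram is invariant to global affine intensity changes", {
  set.seed(12)
  img <- matrix(runif(20 * 20, 50, 200), 20, 20)
  mask <- matrix(1, 20, 20)
  f1 <- lbp_features(img, mask)
  f2 <- lbp_features(img * 1.2 + 10, mask)
  expect_equal(f1, f2)
  expect_error(lbp_features(img, matrix(0, 20, 20)), "mask")
})

test_that("extract_radiomics yields the 96-vector with stable names", {
  img <- disc_image(32, 32, radius = 10)
  set.seed(2)
  img <- clip255(img + array(rnorm(length(img), 0, 5), dim(img)))
  mask <- disc_mask(32, 32, 10)
  f <- extract_radiomics(img, mask)
  expect_length(f, 96)
  expect_true(all(is.finite(f)))
  expect_equal(sum(startsWith(names(f), "glszm_")), 16)
  expect_equal(sum(startsWith(names(f), "gldm_")), 14)
  expect_equal(sum(startsWith(names(f), "ch_")), 16)
  expect_equal(sum(startsWith(names(f), "lbp_")), 50)
  expect_false(anyDuplicated(names(f)) > 0)
  # deterministic
  expect_identical(f, extract_radiomics(img, mask))
})
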