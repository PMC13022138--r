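test_that("gradient_magnitude matches the per-pixel central-difference oracle", {
  set.seed(3)
  for (s in 1:5) {
    m <- matrix(runif(12 * 14, 0, 255), 12, 14)
    expect_equal(gradient_magnitude(m), oracle_gradient(m), tolerance = 1e-12)
  }
  # flat image has zero gradient; sobel mode is nonnegative
  expect_equal(gradient_magnitude(matrix(7, 8, 8)), matrix(0, 8, 8))
  expect_true(all(gradient_magnitude(matrix(runif(64), 8, 8), "sobel") >= 0))
})

test_that("sure_background separates a dark disc from light skin", {
  img <- disc_image(48, 48, radius = 12)
  bg <- sure_background(rgb_to_gray(img))
  expect_equal(sort(unique(as.vector(bg))), c(0, 1))
  truth <- disc_mask(48, 48, 12)
  # background mask is 1 on the skin, 0 on the lesion core
  expect_equal(bg[1, 1], 1)
  expect_equal(bg[24, 24], 0)
  expect_gt(mean(bg[truth == 0]), 0.95)
  expect_lt(mean(bg[truth == 1]), 0.2)
  expect_true(is.numeric(attr(bg, "threshold")))
})

test_that("uniform images fall back to a global-mean threshold with a warning", {
  expect_warning(sure_background(matrix(100, 16, 16)), "uniform")
})

test_that("distance_transform is the Euclidean distance to the background", {
  bg <- matrix(1, 15, 15); bg[6:10, 6:10] <- 0
  D <- distance_transform(bg)
  expect_equal(D[bg == 1], rep(0, sum(bg)))
  expect_equal(D[8, 8], 3)  # center of the 5x5 hole
  expect_equal(D[6, 6], 1)
  expect_error(distance_transform(matrix(1, 4, 4)), "degenerate")
  expect_error(distance_transform(matrix(0, 4, 4)), "degenerate")
})

test_that("sure_foreground shrinks monotonically as tau rises", {
  img <- disc_image(48, 48, radius = 14)
  bg <- sure_background(rgb_to_gray(img))
  D <- distance_transform(bg)
  taus <- c(0.2, 0.4, 0.6, 0.8)
  areas <- vapply(taus, function(t) sum(sure_foreground(D, t)), numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_gt(areas[1], 0)
  # every higher-tau mask is a subset of every lower-tau mask
  lo <- sure_foreground(D, 0.2); hi <- sure_foreground(D, 0.8)
  expect_true(all(lo[hi == 1] == 1))
})

test_that("label_markers assigns 1..K to components and K+1 to background", {
  fg <- matrix(0, 10, 10); fg[2:3, 2:3] <- 1; fg[7:8, 7:8] <- 1
  bg <- matrix(0, 10, 10); bg[1, ] <- 1
  mk <- label_markers(fg, bg)
  expect_equal(mk$n_foreground, 2)
  expect_equal(mk$background_label, 3)
  expect_setequal(unique(mk$labels[fg == 1]), c(1, 2))
  expect_true(all(mk$labels[bg == 1] == 3))
  expect_equal(sum(mk$labels == 0), 100 - sum(fg) - sum(bg))
  expect_error(label_markers(matrix(0, 4, 4), matrix(0, 4, 4)), "empty")
})

test_that("watershed basins partition the image (no lines mode)", {
  img <- disc_image(48, 48, radius = 12)
  gray <- rgb_to_gray(img)
  bg <- sure_background(gray)
  D <- distance_transform(bg)
  fg <- sure_foreground(D, 0.4)
  mk <- label_markers(fg, bg)
  basins <- watershed_flood(gradient_magnitude(gray), mk$labels)
  # every pixel belongs to exactly one basin with a valid marker label
  expect_true(all(basins >= 1 & basins <= mk$background_label))
  # markers keep their labels
  expect_true(all(basins[mk$labels > 0] == mk$labels[mk$labels > 0]))
  # keep_lines mode: ridge pixels are 0, everything else unchanged labels
  lines <- watershed_flood(gradient_magnitude(gray), mk$labels, keep_lines = TRUE)
  expect_true(all(lines >= 0))
  expect_true(all(lines[lines > 0] <= mk$background_label))
})

test_that("flooding claims cheap (low-gradient) paths first", {
  # two markers on a flat surface with a high ridge down the middle:
  # each basin should stop at the ridge
  grad <- matrix(0, 9, 9); grad[, 5] <- 100
  markers <- matrix(0L, 9, 9); markers[5, 1] <- 1L; markers[5, 9] <- 2L
  basins <- watershed_flood(grad, markers)
  expect_true(all(basins[, 1:4] == 1))
  expect_true(all(basins[, 6:9] == 2))
})

test_that("select_lesion_roi picks the basin overlapping the foreground", {
  img <- disc_image(48, 48, radius = 12)
  seg <- segment_lesion(img, watershed_params(alpha_min = 50))
  expect_s3_class(seg, "lesion_segmentation")
  expect_false(seg$failure)
  truth <- disc_mask(48, 48, 12)
  expect_gt(dice_coefficient(seg$lesion_mask, truth), 0.9)
  bb <- seg$roi_bbox
  expect_equal(dim(seg$roi_image)[1], bb["row1"] - bb["row0"], ignore_attr = TRUE)
  expect_equal(dim(seg$roi_image)[2], bb["col1"] - bb["col0"], ignore_attr = TRUE)
})

test_that("alpha_min filters small basins into a structured failure", {
  img <- disc_image(48, 48, radius = 6)  # area ~113 px
  seg <- segment_lesion(img, watershed_params(alpha_min = 2000))
  expect_true(seg$failure)
  expect_equal(seg$stage, "select_lesion_roi")
  expect_match(seg$reason, "alpha_min")
})

test_that("lesion-free images fail at the foreground stage, not with a crash", {
  set.seed(5)
  img <- clip255(array(200 + rnorm(48 * 48 * 3, 0, 3), c(48, 48, 3)))
  seg <- segment_lesion(img)
  expect_true(seg$failure)
  expect_true(is.character(seg$stage))
  expect_match(seg$reason, "contrast|lesion")
})

test_that("invert_polarity segments bright lesions on dark skin", {
  img <- disc_image(48, 48, radius = 12, dark = 220, light = 60)
  seg <- segment_lesion(img, watershed_params(alpha_min = 50,
                                              invert_polarity = TRUE))
  expect_false(seg$failure)
  expect_gt(dice_coefficient(seg$lesion_mask, disc_mask(48, 48, 12)), 0.85)
})

test_that("watershed_params validates its arguments", {
  expect_error(watershed_params(tau = 0), "tau")
  expect_error(watershed_params(tau = 1), "tau")
  expect_error(watershed_params(alpha_min = -5), "alpha_min")
})
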