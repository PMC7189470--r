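test_that("control calibration separates disjoint distributions with zero error", {
  one <- matrix(1, 16, 16)
  pos <- stain_image(tiquant:::render_od(list(dab = 0.8 * one), c(16, 16)),
                     "CD31")
  neg <- stain_image(tiquant:::render_od(list(hematoxylin = 0.2 * one),
                                         c(16, 16)), "CD31")
  thr <- calibrate_threshold(pos, neg)
  expect_equal(attr(thr, "misclassification"), 0)
  vp <- tiquant:::stain_channel(pos); vn <- tiquant:::stain_channel(neg)
  expect_true(all(vp > thr))
  expect_true(all(vn <= thr))
})

test_that("identical controls raise a separability error", {
  one <- matrix(1, 16, 16)
  tile <- stain_image(tiquant:::render_od(list(dab = 0.5 * one), c(16, 16)),
                      "CD31")
  expect_error(calibrate_threshold(tile, tile), "not separable")
})

test_that("controls of different stains are rejected", {
  one <- matrix(1, 8, 8)
  a <- stain_image(tiquant:::render_od(list(dab = 0.5 * one), c(8, 8)), "CD31")
  b <- stain_image(tiquant:::render_od(list(dab = 0.5 * one), c(8, 8)), "SMA")
  expect_error(calibrate_threshold(a, b), "same stain")
})

test_that("generator controls calibrate with under 2% misclassified pixels", {
  set <- generate_slide_set(slide_spec(noise_sd = 0.02, seed = 31))
  thr <- calibrate_slide_thresholds(set$controls)
  for (st in names(thr))
    expect_lt(attr(thr[[st]], "misclassification"), 0.02)
})

test_that("segmentation reproduces the planted mask pixel-for-pixel when noiseless", {
  set <- tiny_slide(n_vessels = 20, seed = 32)
  thr <- calibrate_slide_thresholds(set$controls)
  m <- segment_stain(set$images$CD31, thr$CD31)
  expect_identical(m$pixels, set$masks$vessel)
})

test_that("segmentation handles empty and saturated thresholds", {
  set <- tiny_slide(seed = 33)
  ch <- tiquant:::stain_channel(set$images$CD31)
  expect_equal(sum(segment_stain(set$images$CD31, max(ch) + 1)$pixels), 0)
  bg <- stain_image(tiquant:::render_od(
    list(hematoxylin = 0.2 * matrix(1, 32, 32)), c(32, 32)), "CD31")
  expect_equal(sum(segment_stain(bg, 0.4)$pixels), 0)
})

test_that("raising the threshold never increases the positive-pixel count", {
  set <- generate_slide_set(slide_spec(noise_sd = 0.03, seed = 34))
  thrs <- seq(0.1, 0.7, by = 0.1)
  counts <- vapply(thrs, function(t)
    sum(segment_stain(set$images$F480, t, min_object_px = 1)$pixels),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("viable mask is tumor minus necrosis, with clipping warned", {
  tm <- binary_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), 1)
  nm_in <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), 1)
  v <- viable_mask(tm, nm_in)
  expect_equal(sum(v$pixels), 2)
  ## empty necrosis: viable equals tumor
  v2 <- viable_mask(tm, binary_mask(matrix(FALSE, 2, 2), 1))
  expect_identical(v2$pixels, tm$pixels)
  ## necrosis = tumor: viable empty with zero area
  v3 <- viable_mask(tm, tm)
  expect_equal(sum(v3$pixels), 0)
  expect_equal(attr(v3, "area_mm2"), 0)
  ## necrosis outside the tumor is clipped with a warning
  nm_out <- binary_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2), 1)
  expect_warning(v4 <- viable_mask(tm, nm_out), "clipped")
  expect_equal(sum(v4$pixels), 3)
})

test_that("planted necrosis yields viable area within 2% of truth", {
  set <- tiny_slide(necrotic_fraction = 0.5, n_vessels = 5, n_nuclei = 40,
                    seed = 35)
  tm <- binary_mask(set$masks$tumor, 0.495)
  nm <- binary_mask(set$masks$necrosis, 0.495)
  v <- viable_mask(tm, nm)
  expect_lt(abs(mask_area_mm2(v) / set$truth$viable_area_mm2 - 1), 0.02)
})

test_that("8-connected labelling merges diagonal touches", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # touch only diagonally
  m[5, 5] <- TRUE                    # separate object
  lab <- tiquant:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
})
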