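test_that("vessel counting matches planted truth and handles merges", {
  set <- tiny_slide(n_vessels = 40, canvas_size_px = c(320, 320), seed = 41)
  viable <- binary_mask(set$masks$viable, 0.495)
  mask <- binary_mask(set$masks$vessel, 0.495)
  expect_equal(count_vessels(mask, viable), 40)
  expect_equal(count_vessels(binary_mask(matrix(FALSE, 320, 320), 0.495),
                             viable), 0)

  ## two touching rings merge into whatever the connected-component
  ## labelling of the combined mask says (here: one object)
  dm <- c(64L, 64L)
  m <- matrix(FALSE, dm[1], dm[2])
  m[tiquant:::disk_idx(dm, 25, 32, 8, 5)] <- TRUE
  m[tiquant:::disk_idx(dm, 40, 32, 8, 5)] <- TRUE   # overlaps the first
  oracle <- max(tiquant:::label_components(m))
  all_v <- binary_mask(matrix(TRUE, dm[1], dm[2]), 0.495)
  expect_equal(count_vessels(binary_mask(m, 0.495), all_v), oracle)
})

test_that("density arithmetic follows the physical pixel size", {
  expect_equal(density_per_mm2(50, 1), 50)
  expect_equal(density_per_mm2(0, 2), 0)
  expect_error(density_per_mm2(5, 0), "positive")
  ## 1 mm^2 at 0.495 um/pixel is about 4,081,216 pixels
  expect_equal(px_per_mm2(0.495), 4081216, tolerance = 1e-6)
  expect_equal(px_area_mm2(px_per_mm2(0.495), 0.495), 1)
})

test_that("vessel maturation index is the SMA:CD31 density ratio in percent", {
  expect_equal(vessel_maturation_index(10, 10), 100)
  expect_equal(vessel_maturation_index(0, 10), 0)
  expect_warning(v <- vessel_maturation_index(5, 0), "undefined")
  expect_true(is.na(v))
  ## 40 CD31 vessels, 10 coated, common viable area -> 25%
  area <- 0.01
  expect_equal(vessel_maturation_index(density_per_mm2(10, area),
                                       density_per_mm2(40, area)), 25)
})

test_that("area fraction is measured against viable tissue", {
  v <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), 1)
  full <- binary_mask(matrix(TRUE, 2, 2), 1)
  expect_equal(area_fraction(full, v), 100)
  expect_equal(area_fraction(binary_mask(matrix(FALSE, 2, 2), 1), v), 0)
  expect_error(area_fraction(full, binary_mask(matrix(FALSE, 2, 2), 1)),
               "empty")
  set <- tiny_slide(f480_area_fraction = 0.12, seed = 43)
  thr <- calibrate_slide_thresholds(set$controls)
  got <- area_fraction(segment_stain(set$images$F480, thr$F480),
                       binary_mask(set$masks$viable, 0.495))
  expect_lt(abs(got - 100 * set$truth$f480_positive_px / set$truth$viable_px),
            1)
})

test_that("nucleus detection recovers planted counts and splits touching pairs", {
  set <- tiny_slide(n_nuclei = 120, seed = 44)
  thr <- calibrate_slide_thresholds(set$controls)
  nuc <- detect_nuclei(set$images$HE, thr$HE)
  expect_lt(abs(nrow(nuc) - 120) / 120, 0.05)

  ## zero nuclei -> empty
  set0 <- tiny_slide(n_nuclei = 0, seed = 45)
  expect_equal(nrow(detect_nuclei(set0$images$HE, thr$HE)), 0)

  ## two overlapping disks at centre distance > 1 radius split in two
  dm <- c(48L, 48L)
  m <- matrix(0, dm[1], dm[2])
  m[tiquant:::disk_idx(dm, 22, 24, 4)] <- 0.85
  m[tiquant:::disk_idx(dm, 28, 24, 4)] <- 0.85
  img <- stain_image(tiquant:::render_od(list(hematoxylin = m), dm), "HE")
  pair <- detect_nuclei(img, 0.4)
  expect_equal(nrow(pair), 2)
})

test_that("Ki67 positivity is the fraction of nuclei inside the mask", {
  nuc <- data.frame(x = c(2, 5, 8), y = c(2, 5, 8))
  m <- matrix(FALSE, 10, 10); m[1:6, 1:6] <- TRUE
  expect_equal(ki67_percent(nuc, binary_mask(m, 1)), 100 * 2 / 3)
  expect_equal(ki67_percent(nuc, binary_mask(matrix(TRUE, 10, 10), 1)), 100)
  expect_equal(ki67_percent(nuc, binary_mask(matrix(FALSE, 10, 10), 1)), 0)
  expect_error(ki67_percent(nuc[0, ], binary_mask(m, 1)), "no nuclei")
})

test_that("noiseless aligned slide sets reproduce truth-derived metrics", {
  rec <- eval_slide_metric_recovery(seed = 46)
  e <- rec$errors
  expect_equal(e$vessel_count, 0)
  expect_equal(e$sma_count, 0)
  expect_equal(abs(e$mvd_rel), 0, tolerance = 1e-12)
  expect_lt(abs(e$vmi_pp), 1e-9)
  expect_lt(abs(e$f480_pp), 1e-9)
  expect_lt(abs(e$ki67_pp), 1e-9)
  expect_lt(abs(e$necrosis_pp), 1e-9)
  ## VMI algebra holds on the output object
  m <- rec$metrics
  expect_lt(abs(m$vmi_percent * m$mvd_per_mm2 - 100 * m$sma_per_mm2), 1e-9)
})

test_that("metrics under a small warp agree with the aligned metrics", {
  tf <- similarity_transform(1.01, 3, 5, -4)
  spw <- slide_spec(n_vessels = 30, transform_truth = tf, noise_sd = 0.02,
                    seed = 47)
  set <- generate_slide_set(spw)
  thr <- calibrate_slide_thresholds(set$controls)
  met <- quantify_slide(set$images, set$masks$necrosis, thr,
                        tumor_mask = binary_mask(set$masks$tumor, 0.495))
  tr <- set$truth
  expect_lt(abs(met$mvd_per_mm2 / (tr$vessel_count / tr$viable_area_mm2) - 1),
            0.05)
  expect_lt(abs(met$vmi_percent -
                100 * tr$sma_vessel_count / tr$vessel_count), 2)
  expect_lt(abs(met$f480_area_percent -
                100 * tr$f480_positive_px / tr$viable_px), 1)
  expect_lt(abs(met$ki67_percent -
                100 * tr$nuclei_ki67_pos / tr$nuclei_total), 2)
})

test_that("doubling the pixel size leaves densities consistent", {
  ## same physical scene at half resolution: a vessel count over the same
  ## physical area must give the same density within 5%
  set <- tiny_slide(n_vessels = 20, seed = 48)
  v1 <- binary_mask(set$masks$viable, 0.495)
  n1 <- count_vessels(binary_mask(set$masks$vessel, 0.495), v1)
  d1 <- density_per_mm2(n1, mask_area_mm2(v1))
  half <- function(m) m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)]
  v2 <- binary_mask(half(set$masks$viable), 0.99)
  n2 <- count_vessels(binary_mask(half(set$masks$vessel), 0.99), v2,
                      size_range = c(2, 1e4))
  d2 <- density_per_mm2(n2, mask_area_mm2(v2))
  expect_lt(abs(d2 / d1 - 1), 0.05)
})

test_that("slide_metrics enforces its invariants", {
  expect_error(slide_metrics(10, 2, 15, 5, 5, 5, 1))        # VMI algebra
  expect_error(slide_metrics(10, 2, 20, 105, 5, 5, 1))      # pct range
  m <- slide_metrics(10, 2, 20, 5, 5, 5, 1)
  expect_s3_class(m, "slide_metrics")
})
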