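test_that("identical spec and seed regenerate byte-identical slide sets", {
  sp <- slide_spec(n_vessels = 40, canvas_size_px = c(320, 320), seed = 7)
  a <- generate_slide_set(sp)
  b <- generate_slide_set(sp)
  expect_identical(a$images$CD31$pixels, b$images$CD31$pixels)
  expect_identical(a$images$HE$pixels, b$images$HE$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$masks, b$masks)
})

test_that("empty planting gives empty positives and full viable area", {
  set <- tiny_slide(n_vessels = 0, f480_area_fraction = 0,
                    necrotic_fraction = 0)
  thr <- calibrate_slide_thresholds(set$controls)
  expect_equal(sum(segment_stain(set$images$CD31, thr$CD31)$pixels), 0)
  expect_equal(sum(segment_stain(set$images$F480, thr$F480)$pixels), 0)
  expect_equal(set$truth$vessel_count, 0)
  ## no necrosis: viable area equals the whole tumor area
  expect_equal(set$truth$viable_area_mm2, set$truth$tumor_area_mm2)
})

test_that("planted-count bookkeeping matches the rendered masks", {
  set <- tiny_slide(n_vessels = 25, sma_coated_fraction = 0.4, seed = 11)
  tr <- set$truth
  expect_equal(tr$sma_vessel_count, round(0.4 * 25))
  expect_lte(tr$sma_vessel_count, tr$vessel_count)
  ## every planted vessel label appears in the mask; SMA is a subset
  expect_equal(sort(unique(set$masks$vessel_labels[set$masks$vessel])),
               seq_len(tr$vessel_count))
  expect_true(all(set$masks$vessel[set$masks$sma]))
  expect_equal(sum(set$masks$f480), tr$f480_positive_px)
  expect_equal(px_area_mm2(sum(set$masks$viable), 0.495),
               tr$viable_area_mm2)
  expect_lte(tr$necrotic_area_mm2 + tr$viable_area_mm2,
             px_area_mm2(prod(dim(set$masks$tumor)), 0.495))
})

test_that("ki67-positive nuclei are exactly the planted count", {
  set <- tiny_slide(n_nuclei = 80, ki67_positive_fraction = 0.25, seed = 13)
  expect_equal(set$truth$nuclei_ki67_pos, round(0.25 * 80))
  ## positive disks are a subset of nuclei pixels
  expect_true(all(set$masks$nuclei[set$masks$ki67_pos]))
})

test_that("infeasible vessel packing raises rather than truncating", {
  expect_error(generate_slide_set(slide_spec(n_vessels = 500, seed = 1)),
               "infeasible packing")
})

test_that("spec invariants are enforced", {
  expect_error(slide_spec(sma_coated_fraction = 1.2), "fractions")
  expect_error(slide_spec(canvas_size_px = c(128, 256)), "256")
  expect_error(slide_spec(pixel_size_um = -1), "pixel_size_um")
  expect_error(slide_spec(noise_sd = -0.1), "noise_sd")
})

test_that("F4/80 positive-pixel fraction hits its target within 1% absolute", {
  for (f in c(0.05, 0.12, 0.2)) {
    set <- tiny_slide(f480_area_fraction = f, seed = 17)
    got <- set$truth$f480_positive_px / set$truth$viable_px
    expect_lt(abs(got - f), 0.01)
  }
})
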