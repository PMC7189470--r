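test_that("noiseless standards recover 4PL parameters within 1%", {
  rec <- eval_fourpl_recovery(seed = 5)
  expect_lt(rec$param_rel_err_max, 0.01)
})

test_that("the fitted curve honours the 4PL midpoint identity", {
  x <- 10000 / 4^(0:6)
  y <- fourpl(x, a = 30, b = 1.3, c = 120, d = 25000)
  fit <- fit_standard_curve(x, y, "test")
  expect_equal(predict_response(fit, fit$c), (fit$a + fit$d) / 2,
               tolerance = 1e-6)
  ## inflection response equals the asymptote midpoint by construction
  expect_equal(fourpl(120, 30, 1.3, 120, 25000), (30 + 25000) / 2)
})

test_that("duplicate noiseless standards fit identically to singlicates", {
  x <- 10000 / 4^(0:6)
  y <- fourpl(x, 40, 1.1, 200, 18000)
  f1 <- fit_standard_curve(x, y, "t")
  f2 <- fit_standard_curve(rep(x, 2), rep(y, 2), "t")
  expect_equal(f1[c("a", "b", "c", "d")], f2[c("a", "b", "c", "d")],
               tolerance = 1e-8)
})

test_that("curve inversion is the exact inverse on the standards range", {
  x <- 10000 / 4^(0:6)
  y <- fourpl(x, 35, 1.4, 150, 22000)
  fit <- fit_standard_curve(x, y, "t")
  for (xx in c(5, 50, 150, 900, 8000)) {
    r <- invert_curve(fit, predict_response(fit, xx))
    expect_lt(abs(r$conc_pg_per_ml / xx - 1), 1e-6)
  }
  ## midpoint response inverts to the inflection
  r <- invert_curve(fit, (fit$a + fit$d) / 2)
  expect_equal(r$conc_pg_per_ml, fit$c, tolerance = 1e-9)
})

test_that("responses beyond the asymptotes or standards range are flagged", {
  x <- 10000 / 4^(0:6)
  fit <- fit_standard_curve(x, fourpl(x, 35, 1.4, 150, 22000), "t")
  at_d <- invert_curve(fit, fit$d)
  expect_true(is.na(at_d$conc_pg_per_ml))
  expect_equal(at_d$flag, "outside_asymptotes")
  ## inside the asymptotes but beyond measured standards: extrapolated
  y_low <- predict_response(fit, min(x) / 10)
  ex <- invert_curve(fit, y_low)
  expect_false(ex$in_range)
  expect_equal(ex$flag, "extrapolated")
  expect_false(is.na(ex$conc_pg_per_ml))
})

test_that("protein normalization follows conc * volume / protein", {
  expect_equal(normalize_by_protein(100, 1, 1), 100)
  expect_equal(normalize_by_protein(100, 1, 2), 50)
  expect_equal(normalize_by_protein(100, 0.5, 1), 50)
  expect_error(normalize_by_protein(100, 1, 0), "positive")
})

test_that("plate round-trip recovers truth concentrations at cv = 0.02", {
  rec <- eval_fourpl_recovery(seed = 6, cv = 0.02)
  expect_lt(rec$roundtrip_rel_err_mean, 0.05)
  expect_true(all(rec$roundtrip_rel_err < 0.10))
})

test_that("bead plates are deterministic and exact at zero cv", {
  sp <- bead_spec(replicate_cv = 0, seed = 9)
  a <- generate_bead_plate(sp)
  b <- generate_bead_plate(sp)
  expect_identical(a, b)
  an <- sp$analytes[1]
  p <- sp$fourpl_truth[[an]]
  d <- a$standards[a$standards$analyte == an, ]
  expect_equal(d$response,
               fourpl(d$concentration, p$a, p$b, p$c, p$d), tolerance = 1e-12)
  expect_error(bead_spec(standard_concentrations = c(10, 20, 30)),
               "decreasing")
})
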