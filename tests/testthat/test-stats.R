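test_that("rank-sum p for fully separated triples is exactly 0.1", {
  t <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$p_two_sided, 0.1, tolerance = 1e-12)
  expect_equal(t$method, "exact")
  expect_equal(t$statistic, 6)   # minimal possible rank sum for n1 = 3
  expect_equal(enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("identical groups give p = 1 with a warning", {
  expect_warning(t <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), "identical")
  expect_equal(t$p_two_sided, 1)
  t2 <- suppressWarnings(wilcoxon_rank_sum(c(1, 5, 9), c(9, 1, 5)))
  expect_equal(t2$p_two_sided, 1)
})

test_that("exact p equals exhaustive enumeration for all small untied samples", {
  set.seed(42)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)          # untied by construction
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    t <- wilcoxon_rank_sum(x, y)
    expect_equal(t$method, "exact")
    expect_equal(t$p_two_sided, enum_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("the exact path agrees with the normal approximation at n = 8", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8) + 0.5
    exact <- wilcoxon_rank_sum(x, y)
    expect_equal(exact$method, "exact")
    na <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact$p_two_sided - na), 0.02)
  }
  tied <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_equal(tied$method, "normal_approx")
})

test_that("Pearson with fit matches closed-form cases and symmetries", {
  x <- c(1, 2, 3, 4, 5)
  r <- pearson_with_fit(x, 2 * x + 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)

  set.seed(44)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson_with_fit(a, b)$r, pearson_with_fit(b, a)$r,
               tolerance = 1e-12)
  ## affine rescaling leaves r unchanged
  expect_equal(pearson_with_fit(a, b)$r, pearson_with_fit(3 * a - 7, b)$r,
               tolerance = 1e-12)
  expect_equal(sign(pearson_with_fit(a, b)$r),
               sign(pearson_with_fit(a, b)$slope))
  expect_error(pearson_with_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("independent variables show weak correlation at n = 200", {
  set.seed(45)
  r <- pearson_with_fit(rnorm(200), rnorm(200))
  expect_lt(abs(r$r), 0.2)
})

test_that("MAD outlier rule flags three absolute deviations from the median", {
  v <- c(10, 12, 11, 13, 50)
  ## median 12, MAD 1 (unscaled), so only |50 - 12| = 38 > 3 flags
  expect_identical(mad_outliers(v), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_warning(f <- mad_outliers(rep(4, 5)), "degenerate")
  expect_false(any(f))
  expect_false(any(mad_outliers(c(9, 10, 11, 10, 9.5))))
})

test_that("exclusion rules implement the strict viability and >= 4 rule", {
  n <- 6
  pops <- matrix(rep(c(100, 102, 98, 101, 99, 100), 8), n, 8,
                 dimnames = list(paste0("s", 1:n), paste0("p", 1:8)))
  viab <- setNames(c(49.9, 50, 80, 80, 80, 80), rownames(pops))

  ## plant a 5-population outlier in sample 3 and a 3-population one in 4
  pops[3, 1:5] <- 200
  pops[4, 6:8] <- 200
  rep <- apply_exclusions(viab, pops)
  expect_true(rep$excluded[1])                    # 49.9% -> excluded
  expect_true(rep$low_viability[1])
  expect_false(rep$low_viability[2])              # 50.0% retained (strict <)
  expect_true(rep$excluded[3])                    # 5 outlying populations
  expect_equal(rep$outlier_populations[3], 5)
  expect_false(rep$excluded[4])                   # only 3 -> retained
  expect_false(any(rep$excluded[5:6]))
  ## reasons non-empty exactly when excluded
  expect_identical(rep$excluded, nzchar(rep$reasons))
})

test_that("exclusion screening is idempotent on the retained set", {
  pops <- matrix(rep(c(50, 51, 49, 50.5, 49.5, 50, 51, 49), 5), 8, 5,
                 dimnames = list(paste0("s", 1:8), paste0("p", 1:5)))
  pops[2, ] <- 500
  viab <- setNames(rep(90, 8), rownames(pops))
  r1 <- apply_exclusions(viab, pops)
  keep <- !r1$excluded
  r2 <- apply_exclusions(viab[keep], pops[keep, , drop = FALSE])
  expect_false(any(r2$excluded))
})

test_that("group summaries are mean and sd/sqrt(n)", {
  s <- summarize_group(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-12)
  s1 <- summarize_group(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sem))
  expect_equal(s1$flag, "single_value")
  expect_equal(summarize_group(rep(7, 4))$sem, 0)
})

test_that("compare_groups assembles the study-shaped comparison table", {
  d <- rbind(
    data.frame(sample_id = paste0("c", 1:5), group = "control", day = 7,
               variable = "vmi", value = c(9, 11, 12, 10, 13)),
    data.frame(sample_id = paste0("t", 1:5), group = "treated", day = 7,
               variable = "vmi", value = c(19, 24, 22, 26, 21)))
  cmp <- compare_groups(d, c("control", "treated"))
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$n1, 5); expect_equal(cmp$n2, 5)
  expect_equal(cmp$mean1, 11); expect_equal(cmp$mean2, 22.4)
  expect_equal(cmp$p, enum_ranksum_p(c(9, 11, 12, 10, 13),
                                     c(19, 24, 22, 26, 21)),
               tolerance = 1e-12)
})
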