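#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test.  For untied samples the
#' exact rank-sum distribution is used; with ties, mid-ranks with the
#' normal approximation and continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return a `rank_sum_test` list: `statistic` (rank sum of `x` in the
#'   combined sample), `u` (Mann-Whitney U), `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both groups; p = 1")
    return(structure(list(statistic = sum(rank(c(x, y))[seq_along(x)]),
                          u = length(x) * length(y) / 2, p_two_sided = 1,
                          method = "degenerate"),
                     class = "rank_sum_test"))
  }
  exact <- !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  W <- sum(rank(c(x, y))[seq_along(x)])   # rank sum of x
  structure(list(statistic = W, u = unname(wt$statistic),
                 p_two_sided = min(wt$p.value, 1),
                 method = if (exact) "exact" else "normal_approx"),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("<rank_sum_test> W = %g (U = %g), p = %.4g [%s]\n",
              x$statistic, x$u, x$p_two_sided, x$method))
  invisible(x)
}

#' Pearson correlation with a least-squares regression line
#'
#' @param x,y numeric vectors, n >= 3; neither may be constant.
#' @return a `correlation_result`: `r`, `p` (two-sided, t distribution
#'   with n - 2 df), `slope`, `intercept`, `n`.
#' @export
pearson_with_fit <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: a variable is constant")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.4g, y = %.3g + %.3g x (n = %d)\n",
              x$r, x$p, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Flag outliers more than three absolute deviations from the median
#'
#' A value is an outlier when `|v - median(v)| > k * MAD`, with the MAD
#' unscaled (median of absolute deviations, no normal-consistency
#' constant) by default.  When the MAD is zero (over half the values
#' identical) nothing is flagged and a degenerate-spread warning is
#' issued.
#'
#' @param values numeric vector, n >= 3.
#' @param k multiplier (default 3).
#' @param scaled use the normal-consistent MAD (x 1.4826) instead.
#' @return logical flags, one per value.
#' @export
mad_outliers <- function(values, k = 3, scaled = FALSE) {
  stopifnot(length(values) >= 3)
  m <- median(values)
  s <- mad(values, constant = if (scaled) 1.4826 else 1)
  if (s == 0) {
    warning("MAD is zero (degenerate spread); no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  abs(values - m) > k * s
}

#' Apply the study's sample-exclusion rules
#'
#' A sample is excluded when its viability is strictly below
#' `viability_min` percent, or when it is a MAD outlier in at least
#' `outlier_min` of the myeloid populations.  Outlier screening is run
#' per population within each group stratum.
#'
#' @param viability named numeric vector, percent live per sample.
#' @param populations data.frame or matrix (samples x populations) of
#'   population values; rownames are sample ids.
#' @param group optional factor of group strata per sample (screening is
#'   within-stratum); one stratum when `NULL`.
#' @param viability_min viability threshold in percent (default 50).
#' @param outlier_min minimum number of outlying populations (default 4).
#' @return data.frame: `sample_id`, `excluded`, `low_viability`,
#'   `outlier_populations` (count), `reasons`.
#' @export
apply_exclusions <- function(viability, populations, group = NULL,
                             viability_min = 50, outlier_min = 4L) {
  populations <- as.matrix(populations)
  ids <- rownames(populations) %||% names(viability) %||%
    paste0("sample", seq_len(nrow(populations)))
  stopifnot(length(viability) == nrow(populations))
  if (is.null(group)) group <- rep("all", length(viability))
  flags <- matrix(FALSE, nrow(populations), ncol(populations))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 3) next   # too few samples to screen
    for (j in seq_len(ncol(populations)))
      flags[idx, j] <- suppressWarnings(mad_outliers(populations[idx, j]))
  }
  n_out <- rowSums(flags)
  low_v <- viability < viability_min
  excl <- low_v | n_out >= outlier_min
  reasons <- mapply(function(lv, no) {
    r <- c(if (lv) "low_viability", if (no >= outlier_min) "outlier_populations")
    paste(r, collapse = ";")
  }, low_v, n_out)
  data.frame(sample_id = ids, excluded = excl, low_viability = low_v,
             outlier_populations = n_out, reasons = reasons,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group summary as mean and standard error
#'
#' @param values numeric vector, n >= 1.
#' @return a `group_summary`: `n`, `mean`, `sem` (sample sd / sqrt(n);
#'   `NA` with a flag when n = 1).
#' @export
summarize_group <- function(values) {
  n <- length(values)
  stopifnot(n >= 1)
  s <- if (n > 1) sd(values) / sqrt(n) else NA_real_
  structure(list(n = n, mean = mean(values), sem = s,
                 flag = if (n == 1) "single_value" else ""),
            class = "group_summary")
}

#' Compare every variable between two groups, the study way
#'
#' For each variable (optionally within each day), computes group means
#' with SEM and a two-sided Wilcoxon rank-sum p-value, mirroring the
#' panel-by-panel group comparisons of a treatment study.  No
#' multiple-testing correction is applied.
#'
#' @param data tidy data.frame with columns `sample_id`, `group`,
#'   `variable`, `value` and optionally `day`.
#' @param group_levels length-2 character: reference and comparison group.
#' @return data.frame with one row per variable (x day): n, mean, sem per
#'   group, W, p, method.
#' @export
compare_groups <- function(data, group_levels = NULL) {
  stopifnot(all(c("sample_id", "group", "variable", "value") %in% names(data)))
  if (is.null(group_levels)) group_levels <- unique(data$group)
  stopifnot(length(group_levels) == 2)
  has_day <- "day" %in% names(data)
  keys <- if (has_day) unique(data[c("variable", "day")]) else
    data.frame(variable = unique(data$variable))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- data[data$variable == keys$variable[i], ]
    if (has_day) d <- d[d$day == keys$day[i], ]
    x <- d$value[d$group == group_levels[1]]
    y <- d$value[d$group == group_levels[2]]
    if (!length(x) || !length(y)) return(NULL)
    s1 <- summarize_group(x); s2 <- summarize_group(y)
    tst <- suppressWarnings(wilcoxon_rank_sum(x, y))
    cbind(keys[i, , drop = FALSE],
          data.frame(n1 = s1$n, mean1 = s1$mean, sem1 = s1$sem,
                     n2 = s2$n, mean2 = s2$mean, sem2 = s2$sem,
                     W = tst$statistic, p = tst$p_two_sided,
                     method = tst$method, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
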