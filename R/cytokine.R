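#' Fit a four-parameter logistic standard curve
#'
#' Least-squares 4PL fit (Levenberg-Marquardt) with deterministic
#' initialization from the data: asymptotes from the extreme responses,
#' inflection from mid-response interpolation, slope factor 1.  Optional
#' 1/y^2 weighting; a five-parameter logistic (asymmetry exponent) is
#' available for curves the 4PL cannot capture.
#'
#' @param concentrations standard concentrations (strictly monotone,
#'   positive, at least 5 levels).
#' @param responses measured responses (same length; replicates may
#'   repeat concentrations).
#' @param analyte analyte name carried into the result.
#' @param weighting `"none"` (default) or `"1/y2"`.
#' @param family `"4pl"` (default) or `"5pl"`.
#' @return a `standard_curve` with parameters `a`, `b`, `c`, `d`
#'   (and `g` for 5PL), `fit_residual` (residual standard error) and the
#'   response range of the standards.
#' @export
fit_standard_curve <- function(concentrations, responses, analyte = "",
                               weighting = c("none", "1/y2"),
                               family = c("4pl", "5pl")) {
  weighting <- match.arg(weighting)
  family <- match.arg(family)
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  ux <- sort(unique(x))
  if (length(ux) < 5) stop("need at least 5 distinct standard levels")
  if (any(ux <= 0)) stop("standard concentrations must be positive")

  ## deterministic initialization
  ord <- order(x)
  my <- tapply(y, x, mean)[as.character(ux)]
  a0 <- my[1]; d0 <- my[length(my)]          # low-x and high-x plateaus
  mid <- (a0 + d0) / 2
  c0 <- exp(approx(my, log(ux), xout = mid, ties = mean)$y)
  if (!is.finite(c0)) c0 <- exp(mean(log(range(ux))))
  start <- list(a = unname(a0), b = 1, c = unname(c0), d = unname(d0))
  w <- if (weighting == "1/y2") 1 / pmax(y, 1e-12)^2 else rep(1, length(y))

  df <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (family == "4pl")
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b), data = df,
                        start = start, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b)^g, data = df,
                        start = c(start, list(g = 1)), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop("standard-curve fit did not converge for '", analyte, "': ",
         conditionMessage(e)))
  cf <- as.list(coef(fit))
  structure(list(analyte = analyte, a = cf$a, b = cf$b, c = cf$c, d = cf$d,
                 g = cf$g %||% 1, family = family,
                 fit_residual = sqrt(mean(residuals(fit)^2)),
                 resp_range = range(y), conc_range = range(ux)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> %s  a=%.3g b=%.3g c=%.4g d=%.4g",
                     if (x$family == "5pl") " g=%.3g" else "%s",
                     "  rmse=%.3g\n"),
              x$analyte, x$a, x$b, x$c, x$d,
              if (x$family == "5pl") x$g else "", x$fit_residual))
  invisible(x)
}

#' Predict the response of a fitted standard curve
#' @param curve a `standard_curve`.
#' @param x concentration(s).
#' @export
predict_response <- function(curve, x) {
  curve$d + (curve$a - curve$d) / (1 + (x / curve$c)^curve$b)^curve$g
}

#' Invert a standard curve: response to concentration
#'
#' Closed-form inverse of the logistic on its monotone branch:
#' `x = c * ((a - d) / (y - d) - 1)^(1/b)` (with the asymmetry exponent
#' for 5PL).  Responses outside the open interval between the asymptotes
#' have no finite inverse and are flagged; responses outside the
#' standards' measured response range are extrapolations, reported but
#' flagged `in_range = FALSE`.
#'
#' @param curve a `standard_curve`.
#' @param response measured response (scalar).
#' @return list (`concentration_result`): `analyte`, `conc_pg_per_ml`
#'   (`NA` if no finite inverse), `in_range`, `flag`.
#' @export
invert_curve <- function(curve, response) {
  y <- as.numeric(response)
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  if (!(y > lo && y < hi)) {
    return(structure(list(analyte = curve$analyte,
                          conc_pg_per_ml = NA_real_, in_range = FALSE,
                          flag = "outside_asymptotes"),
                     class = "concentration_result"))
  }
  q <- ((curve$a - curve$d) / (y - curve$d))^(1 / curve$g) - 1
  x <- curve$c * q^(1 / curve$b)
  in_range <- y >= curve$resp_range[1] && y <= curve$resp_range[2]
  structure(list(analyte = curve$analyte, conc_pg_per_ml = x,
                 in_range = in_range,
                 flag = if (in_range) "" else "extrapolated"),
            class = "concentration_result")
}

#' Normalize a cytokine concentration by total sample protein
#'
#' Converts an assay concentration (pg per mL of lysate) to pg per mg of
#' total protein: `conc * volume / protein`.
#'
#' @param conc_pg_per_ml assay concentration in pg/mL.
#' @param sample_volume_ml lysate volume in mL.
#' @param protein_mg total protein in mg (e.g. from a NanoDrop reading).
#' @return concentration in pg per mg protein.
#' @export
normalize_by_protein <- function(conc_pg_per_ml, sample_volume_ml, protein_mg) {
  if (!isTRUE(all(protein_mg > 0))) stop("protein mass must be positive")
  conc_pg_per_ml * sample_volume_ml / protein_mg
}

#' Quantify a full multiplex plate
#'
#' Fits one standard curve per analyte, averages replicate responses per
#' unknown, inverts to concentration and (optionally) normalizes by total
#' protein.
#'
#' @param standards data.frame `analyte, concentration, response`
#'   (replicate rows allowed).
#' @param unknowns data.frame `analyte, sample_id, response`.
#' @param protein optional data.frame `sample_id, protein_mg, volume_ml`.
#' @param ... passed to [fit_standard_curve()].
#' @return list with `curves` (per analyte) and `results` (data.frame:
#'   analyte, sample_id, response, conc_pg_per_ml, normalized_pg_per_mg,
#'   in_range).
#' @export
quantify_plate <- function(standards, unknowns, protein = NULL, ...) {
  curves <- lapply(split(standards, standards$analyte), function(d)
    fit_standard_curve(d$concentration, d$response, analyte = d$analyte[1], ...))
  resp <- stats::aggregate(response ~ analyte + sample_id, unknowns, mean)
  rows <- lapply(seq_len(nrow(resp)), function(i) {
    cv <- curves[[resp$analyte[i]]]
    r <- invert_curve(cv, resp$response[i])
    norm <- NA_real_
    if (!is.null(protein) && !is.na(r$conc_pg_per_ml)) {
      pr <- protein[protein$sample_id == resp$sample_id[i], ]
      if (nrow(pr) == 1)
        norm <- normalize_by_protein(r$conc_pg_per_ml, pr$volume_ml,
                                     pr$protein_mg)
    }
    data.frame(analyte = resp$analyte[i], sample_id = resp$sample_id[i],
               response = resp$response[i],
               conc_pg_per_ml = r$conc_pg_per_ml,
               normalized_pg_per_mg = norm, in_range = r$in_range,
               stringsAsFactors = FALSE)
  })
  list(curves = curves, results = do.call(rbind, rows))
}
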