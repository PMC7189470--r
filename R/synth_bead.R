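## the 12-analyte murine panel
DEFAULT_ANALYTES <- c("VEGF-A", "TNF-alpha", "IL-1beta", "CCL21", "CCL7",
                      "CXCL10", "IL-6", "IL-4", "IL-10", "IL-13", "IL-23",
                      "MMP-12")

#' Specification for a synthetic multiplex bead plate
#'
#' Each analyte has a true four-parameter logistic (4PL) response curve
#' `y(x) = d + (a - d) / (1 + (x / c)^b)`; standards follow the curve with
#' multiplicative log-normal noise at `replicate_cv`, and unknown samples
#' are generated from their true concentrations the same way.
#'
#' @param analytes analyte names (default: the 12-analyte murine panel).
#' @param fourpl_truth per-analyte named list `list(a =, b =, c =, d =)`;
#'   drawn from realistic Luminex ranges when `NULL`.
#' @param standard_concentrations descending standard series in pg/mL
#'   (default a seven-point 1:4 dilution from 10000 pg/mL).
#' @param n_replicates replicate wells per standard and per unknown.
#' @param replicate_cv multiplicative coefficient of variation per well.
#' @param sample_concentrations_truth matrix (analyte x sample) of true
#'   unknown concentrations in pg/mL; drawn mid-curve when `NULL`.
#' @param n_samples number of unknown samples when truth is drawn.
#' @param seed RNG seed.
#' @return a `bead_spec` object.
#' @export
bead_spec <- function(analytes = DEFAULT_ANALYTES,
                      fourpl_truth = NULL,
                      standard_concentrations = 10000 / 4^(0:6),
                      n_replicates = 2L,
                      replicate_cv = 0.02,
                      sample_concentrations_truth = NULL,
                      n_samples = 4L,
                      seed = 1L) {
  sc <- standard_concentrations
  if (any(sc <= 0) || any(diff(sc) >= 0))
    stop("standard concentrations must be strictly positive and strictly decreasing")
  if (replicate_cv < 0) stop("replicate_cv must be non-negative")
  with_seed(seed, {
    if (is.null(fourpl_truth)) {
      fourpl_truth <- lapply(seq_along(analytes), function(i)
        list(a = runif(1, 10, 60), b = runif(1, 1.0, 1.8),
             c = 10^runif(1, 1.8, 2.8), d = runif(1, 15000, 30000)))
      names(fourpl_truth) <- analytes
    }
    if (is.null(sample_concentrations_truth)) {
      sample_concentrations_truth <- t(vapply(analytes, function(an) {
        cc <- fourpl_truth[[an]]$c
        cc * 2^runif(n_samples, -1, 1)
      }, numeric(n_samples)))
      colnames(sample_concentrations_truth) <-
        paste0("sample", seq_len(n_samples))
    }
  })
  for (an in analytes)
    if (abs(fourpl_truth[[an]]$a - fourpl_truth[[an]]$d) < 1e-9)
      stop("degenerate 4PL truth (a == d) for ", an)
  structure(list(analytes = analytes, fourpl_truth = fourpl_truth,
                 standard_concentrations = sc,
                 n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv,
                 sample_concentrations_truth = sample_concentrations_truth,
                 seed = as.integer(seed)),
            class = "bead_spec")
}

#' Evaluate a four-parameter logistic curve
#'
#' `y(x) = d + (a - d) / (1 + (x / c)^b)`: `a` is the response at zero
#' concentration, `d` the response at infinite concentration, `c` the
#' inflection concentration (where y = (a + d) / 2) and `b` the slope
#' factor.
#'
#' @param x concentration(s).
#' @param a,b,c,d curve parameters.
#' @export
fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' Generate a synthetic bead plate (standards + unknowns) with truth
#'
#' @param spec a [bead_spec()].
#' @return list with `standards` (analyte, concentration, replicate,
#'   response), `unknowns` (analyte, sample_id, replicate, response) and
#'   `truth` (the spec's 4PL parameters and sample concentrations).
#' @export
generate_bead_plate <- function(spec) {
  stopifnot(inherits(spec, "bead_spec"))
  with_seed(spec$seed + 1L, {
    noisy <- function(mu, n) {
      if (spec$replicate_cv == 0) return(rep(mu, n))
      sdl <- sqrt(log(1 + spec$replicate_cv^2))
      mu * rlnorm(n, -sdl^2 / 2, sdl)   # mean-preserving multiplicative noise
    }
    std <- do.call(rbind, lapply(spec$analytes, function(an) {
      p <- spec$fourpl_truth[[an]]
      do.call(rbind, lapply(spec$standard_concentrations, function(x)
        data.frame(analyte = an, concentration = x,
                   replicate = seq_len(spec$n_replicates),
                   response = noisy(fourpl(x, p$a, p$b, p$c, p$d),
                                    spec$n_replicates))))
    }))
    truth_m <- spec$sample_concentrations_truth
    unk <- do.call(rbind, lapply(spec$analytes, function(an) {
      p <- spec$fourpl_truth[[an]]
      do.call(rbind, lapply(colnames(truth_m), function(sid)
        data.frame(analyte = an, sample_id = sid,
                   replicate = seq_len(spec$n_replicates),
                   response = noisy(fourpl(truth_m[an, sid],
                                           p$a, p$b, p$c, p$d),
                                    spec$n_replicates))))
    }))
    list(standards = std, unknowns = unk,
         truth = list(fourpl = spec$fourpl_truth,
                      sample_concentrations = truth_m))
  })
}
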