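## Validation experiments: each generates synthetic inputs with planted
## truth, runs the corresponding pipeline stage, and reports recovery.
## They are the package's own calibration evidence and are exercised by
## the test suite and the acceptance script.

#' Registration recovery experiment
#'
#' Generates slide pairs under random similarity transforms
#' (scale 0.97-1.03, rotation -8..8 degrees, |shift| <= 15 px), registers
#' the CD31 section to H&E, and reports per-pair errors.
#'
#' @param n_pairs number of slide pairs.
#' @param seed RNG seed.
#' @param tol named tolerances (`scale`, `rot_deg`, `shift_px`) defining a
#'   recovered pair.
#' @return data.frame of per-pair errors with attribute `recovery_rate`.
#' @export
eval_registration_recovery <- function(n_pairs = 20, seed = 1L,
                                       tol = c(scale = 0.005, rot_deg = 0.2,
                                               shift_px = 0.5)) {
  seeds <- derive_seeds(seed, 2L * n_pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    tf <- with_seed(seeds[2L * i - 1L], similarity_transform(
      scale = runif(1, 0.97, 1.03), rotation_deg = runif(1, -8, 8),
      tx_px = runif(1, -15, 15), ty_px = runif(1, -15, 15)))
    set <- generate_slide_set(slide_spec(transform_truth = tf,
                                         seed = seeds[2L * i]))
    est <- register_similarity(set$images$CD31, set$images$HE)
    data.frame(d_scale = est$scale - tf$scale,
               d_rot = est$rotation_deg - tf$rotation_deg,
               d_tx = est$tx_px - tf$tx_px, d_ty = est$ty_px - tf$ty_px,
               converged = isTRUE(attr(est, "converged")))
  })
  out <- do.call(rbind, rows)
  ok <- abs(out$d_scale) < tol["scale"] & abs(out$d_rot) < tol["rot_deg"] &
    abs(out$d_tx) < tol["shift_px"] & abs(out$d_ty) < tol["shift_px"]
  attr(out, "recovery_rate") <- mean(ok)
  out
}

#' Slide-metric recovery experiment
#'
#' Quantifies a noiseless, aligned slide set with 40 CD31 vessels of which
#' 10 are SMA-coated and compares every metric with the planted truth.
#'
#' @param seed RNG seed.
#' @return list with `metrics`, `truth_metrics` and `errors`
#'   (relative errors for densities, percentage-point errors for
#'   percentages, exact count differences).
#' @export
eval_slide_metric_recovery <- function(seed = 1L) {
  spec <- slide_spec(canvas_size_px = c(320L, 320L), n_vessels = 40L,
                     sma_coated_fraction = 0.25, necrotic_fraction = 0.10,
                     n_nuclei = 200L, ki67_positive_fraction = 0.25,
                     f480_area_fraction = 0.12, noise_sd = 0, seed = seed)
  set <- generate_slide_set(spec)
  thr <- calibrate_slide_thresholds(set$controls)
  met <- quantify_slide(set$images, set$masks$necrosis, thr,
                        tumor_mask = binary_mask(set$masks$tumor,
                                                 spec$pixel_size_um),
                        register = FALSE)
  tr <- set$truth
  truth <- list(
    vessel_count = tr$vessel_count,
    sma_vessel_count = tr$sma_vessel_count,
    mvd_per_mm2 = tr$vessel_count / tr$viable_area_mm2,
    sma_per_mm2 = tr$sma_vessel_count / tr$viable_area_mm2,
    vmi_percent = 100 * tr$sma_vessel_count / tr$vessel_count,
    f480_area_percent = 100 * tr$f480_positive_px / tr$viable_px,
    ki67_percent = 100 * tr$nuclei_ki67_pos / tr$nuclei_total,
    necrosis_percent = 100 * tr$necrotic_area_mm2 / tr$tumor_area_mm2)
  cnt <- attr(met, "vessel_counts")
  list(metrics = met, truth_metrics = truth,
       errors = list(
         vessel_count = unname(cnt["cd31"] - truth$vessel_count),
         sma_count = unname(cnt["sma"] - truth$sma_vessel_count),
         mvd_rel = met$mvd_per_mm2 / truth$mvd_per_mm2 - 1,
         sma_rel = if (truth$sma_per_mm2 > 0)
           met$sma_per_mm2 / truth$sma_per_mm2 - 1 else 0,
         vmi_pp = met$vmi_percent - truth$vmi_percent,
         f480_pp = met$f480_area_percent - truth$f480_area_percent,
         ki67_pp = met$ki67_percent - truth$ki67_percent,
         necrosis_pp = met$necrosis_percent - truth$necrosis_percent))
}

#' Gating recovery experiment
#'
#' Generates seeded event tables, gates them with data-driven thresholds,
#' and checks each population estimate (four myeloid fractions of CD45+,
#' four quadrant fractions of macrophages) against the labelled truth
#' within `k` binomial standard deviations.
#'
#' @param n_tables number of event tables.
#' @param n_events events per table.
#' @param seed RNG seed.
#' @param k allowed deviation in binomial SDs.
#' @return data.frame, one row per table x population, with attribute
#'   `recovery_rate` (fraction of estimates within `k` SD) and
#'   `quadrant_sum_ok` (quadrant counts always sum to the parent count).
#' @export
eval_gating_recovery <- function(n_tables = 30, n_events = 10000L,
                                 seed = 1L, k = 3) {
  seeds <- derive_seeds(seed, n_tables)
  rows <- list(); qsum_ok <- TRUE
  for (t in seq_len(n_tables)) {
    spec <- flow_spec(n_events = n_events, seed = seeds[t])
    fl <- generate_flow_events(spec)
    thr <- auto_gate_thresholds(fl$events)
    gates <- apply_gate_tree(fl$events, default_gate_tree(thr))
    memb <- attr(gates, "membership")
    quads <- macrophage_quadrants(fl$events[memb$macrophage, ],
                                  thr["CD38"], thr["CD206"])
    qsum_ok <- qsum_ok && sum(quads$count) ==
      gates$count[gates$name == "macrophage"]
    n_cd45 <- fl$truth$n_live_cd45
    for (p in c("macrophage", "dc", "gmdsc", "mmdsc")) {
      tr <- fl$truth$fraction_of_cd45[[p]]
      est <- gates$pct_of_cd45[gates$name == p] / 100
      sdv <- sqrt(tr * (1 - tr) / n_cd45)
      rows[[length(rows) + 1L]] <- data.frame(
        table = t, population = p, truth = tr, estimate = est,
        binom_sd = sdv, within = abs(est - tr) <= k * sdv)
    }
    n_mac <- fl$truth$n_live_macrophage
    for (q in c("M0", "M1", "M2", "co")) {
      tr <- fl$truth$quadrant_fractions[[q]]
      est <- quads$pct_of_parent[quads$name == q] / 100
      sdv <- sqrt(tr * (1 - tr) / n_mac)
      rows[[length(rows) + 1L]] <- data.frame(
        table = t, population = q, truth = tr, estimate = est,
        binom_sd = sdv, within = abs(est - tr) <= k * sdv)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "recovery_rate") <- mean(out$within)
  attr(out, "quadrant_sum_ok") <- qsum_ok
  out
}

#' Compensation round-trip experiment
#'
#' Mixes a labelled event table through a non-trivial spillover matrix and
#' compensates it back; reports the maximum relative discrepancy against
#' the unmixed table.
#'
#' @param n_events events.
#' @param seed RNG seed.
#' @param amount spillover preset strength.
#' @return maximum relative round-trip error.
#' @export
eval_compensation_roundtrip <- function(n_events = 5000L, seed = 1L,
                                        amount = 0.06) {
  S <- spillover_preset(amount)
  clean <- generate_flow_events(flow_spec(n_events = n_events, seed = seed))
  mixed <- generate_flow_events(flow_spec(n_events = n_events, seed = seed,
                                          spillover = S))
  comp <- compensate(mixed$events, S)
  max(abs(as.matrix(comp) - as.matrix(clean$events)) /
        pmax(as.matrix(clean$events), 1e-12))
}

#' Empirical type-I error of the rank-sum test under the null
#'
#' @param n_sims null simulations.
#' @param n per-group sample size.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return empirical rejection rate.
#' @export
eval_wilcoxon_type1 <- function(n_sims = 10000L, n = 6L, alpha = 0.05,
                                seed = 1L) {
  with_seed(seed, {
    rej <- 0L
    for (i in seq_len(n_sims)) {
      x <- rnorm(n); y <- rnorm(n)
      if (wilcoxon_rank_sum(x, y)$p_two_sided <= alpha) rej <- rej + 1L
    }
    rej / n_sims
  })
}

#' Four-parameter logistic recovery experiment
#'
#' Fits noiseless standards for every analyte of a default bead plate and
#' reports the worst relative parameter error, then runs a noisy plate
#' round trip (cv = 0.02) and reports per-analyte mean relative
#' concentration errors.
#'
#' Concentration recovery is summarized as the mean relative error per
#' analyte and overall: individual wells carry replicate noise, so the
#' recovery statement is about the estimator's accuracy, not any single
#' draw.
#'
#' @param seed RNG seed.
#' @param cv replicate coefficient of variation for the round trip.
#' @return list `param_rel_err_max`, `roundtrip_rel_err` (mean relative
#'   error per analyte), `roundtrip_rel_err_mean` (overall mean).
#' @export
eval_fourpl_recovery <- function(seed = 1L, cv = 0.02) {
  spec0 <- bead_spec(replicate_cv = 0, n_replicates = 1L, seed = seed)
  plate0 <- generate_bead_plate(spec0)
  perr <- vapply(spec0$analytes, function(an) {
    d <- plate0$standards[plate0$standards$analyte == an, ]
    fit <- fit_standard_curve(d$concentration, d$response, an)
    tr <- spec0$fourpl_truth[[an]]
    max(abs(c(fit$a / tr$a, fit$b / tr$b, fit$c / tr$c, fit$d / tr$d) - 1))
  }, numeric(1))

  spec <- bead_spec(replicate_cv = cv, n_replicates = 2L, seed = seed)
  plate <- generate_bead_plate(spec)
  q <- quantify_plate(plate$standards, plate$unknowns)
  rerr <- vapply(spec$analytes, function(an) {
    res <- q$results[q$results$analyte == an, ]
    tr <- spec$sample_concentrations_truth[an, res$sample_id]
    mean(abs(res$conc_pg_per_ml / tr - 1))
  }, numeric(1))
  list(param_rel_err_max = max(perr), roundtrip_rel_err = rerr,
       roundtrip_rel_err_mean = mean(rerr))
}

#' Planted-correlation study experiment
#'
#' Runs the full pipeline on a two-arm cohort whose treated arm has
#' jointly elevated M1 fraction and vessel maturation, over several seeds,
#' and reports how often a positive VMI-M1 Pearson correlation is
#' detected.
#'
#' @param n_seeds number of independent study replicates.
#' @param seed master seed.
#' @param n_per_arm animals per arm.
#' @return data.frame (seed, r, p) with attribute `positive_rate`.
#' @export
eval_planted_correlation <- function(n_seeds = 20, seed = 1L, n_per_arm = 5L) {
  g <- study_design(n = n_per_arm)$groups
  design <- study_design(g[g$name %in% c("d7_24h_ctrl", "d7_24h_tx"), ])
  seeds <- derive_seeds(seed, n_seeds)
  rows <- lapply(seq_len(n_seeds), function(i) {
    res <- run_synthetic_study(design, run_config(seed = seeds[i]),
                               quiet = TRUE)
    cr <- res$correlations$vmi_vs_m1
    data.frame(seed = seeds[i], r = cr$r %||% NA_real_, p = cr$p %||% NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "positive_rate") <- mean(out$r > 0, na.rm = TRUE)
  out
}

#' Null-design false-positive experiment
#'
#' Runs the full pipeline on a two-arm cohort with identical truth in both
#' arms and reports, per seed, the fraction of compared variables reaching
#' p <= 0.05.
#'
#' @inheritParams eval_planted_correlation
#' @return data.frame (seed, n_variables, frac_significant) with attribute
#'   `mean_significant_fraction`.
#' @export
eval_null_design <- function(n_seeds = 20, seed = 1L, n_per_arm = 5L) {
  g0 <- study_design(n = n_per_arm)$groups
  g <- g0[g0$name %in% c("d7_24h_ctrl", "d7_24h_tx"), ]
  ctrl_truth <- default_group_truth("control", 7, 3)
  design <- study_design(g, truth = list(d7_24h_ctrl = ctrl_truth,
                                         d7_24h_tx = ctrl_truth))
  seeds <- derive_seeds(seed + 1L, n_seeds)
  rows <- lapply(seq_len(n_seeds), function(i) {
    res <- run_synthetic_study(design, run_config(seed = seeds[i]),
                               quiet = TRUE)
    cmp <- res$comparisons
    data.frame(seed = seeds[i], n_variables = nrow(cmp),
               frac_significant = mean(cmp$p <= 0.05))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_significant_fraction") <- mean(out$frac_significant)
  out
}
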