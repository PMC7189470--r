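## Group-level truth for the default synthetic study: magnitudes typical
## of trastuzumab response in a HER2+ xenograft model (macrophage influx
## 24 h after dosing, M1 skewing and vessel maturation after a third
## dose, VEGF-A drop with inflammatory-cytokine rises).  Quadrant
## fractions are renormalized to 1.
default_group_truth <- function(treatment, day, doses) {
  ctrl <- list(
    macrophage = 0.30, dc = 0.08, gmdsc = 0.10, mmdsc = 0.07,
    quadrants = c(M0 = 0.45, M1 = 0.13, M2 = 0.15, co = 0.27),
    vmi_fraction = 0.11, n_vessels = 30, ki67 = 0.35, f480 = 0.08,
    necrotic = 0.12, live = 0.88,
    cytokines = c("VEGF-A" = 1200, "TNF-alpha" = 40, "IL-1beta" = 30,
                  "CCL21" = 150, "CCL7" = 200, "CXCL10" = 250, "IL-6" = 100,
                  "IL-4" = 25, "IL-10" = 50, "IL-13" = 30, "IL-23" = 60,
                  "MMP-12" = 500))
  if (treatment == "control") return(ctrl)
  tx <- ctrl
  if (day == 4) {                      # 24 h after the second dose
    tx$macrophage <- 0.459
    tx$quadrants <- c(M0 = 0.19, M1 = 0.13, M2 = 0.11, co = 0.57)
    tx$f480 <- 0.12
  } else if (day == 7 && doses == 2) { # 96 h after the second dose
    tx$macrophage <- 0.203
  } else {                             # 24 h after the third dose
    tx$macrophage <- 0.50
    tx$quadrants <- c(M0 = 0.34, M1 = 0.31, M2 = 0.10, co = 0.25)
    tx$vmi_fraction <- 0.226
    tx$f480 <- 0.11
    tx$cytokines <- c("VEGF-A" = 600, "TNF-alpha" = 90, "IL-1beta" = 60,
                      "CCL21" = 300, "CCL7" = 400, "CXCL10" = 550,
                      "IL-6" = 100, "IL-4" = 25, "IL-10" = 50, "IL-13" = 30,
                      "IL-23" = 60, "MMP-12" = 500)
  }
  tx$ki67 <- 0.22
  tx$quadrants <- tx$quadrants / sum(tx$quadrants)
  tx
}

#' Define a synthetic treatment study
#'
#' A study is a set of arms, each with a treatment label, an extraction
#' day, a dose count, a group size and a group-level truth (flow
#' population fractions, macrophage quadrants, vessel maturation, Ki67,
#' F4/80, necrosis, viability and cytokine levels).  The default mirrors
#' a four-arm schedule: baseline Day 0; Day 4 (24 h after two doses);
#' Day 7 (96 h after two doses); Day 7 (24 h after three doses); each
#' treated arm paired with a control arm.
#'
#' @param groups data.frame with columns `name`, `treatment`
#'   (`"control"`/`"treated"`), `day`, `doses`, `n`.  `NULL` for the
#'   default four-arm design with n = 5 per arm.
#' @param truth optional named list (one entry per group name) overriding
#'   the per-group truth.
#' @param n group size used when building the default design.
#' @return a `study_design` object.
#' @export
study_design <- function(groups = NULL, truth = NULL, n = 5L) {
  if (is.null(groups)) {
    groups <- data.frame(
      name = c("d0_ctrl", "d4_ctrl", "d4_tx", "d7_96h_ctrl", "d7_96h_tx",
               "d7_24h_ctrl", "d7_24h_tx"),
      treatment = c("control", "control", "treated", "control", "treated",
                    "control", "treated"),
      day = c(0, 4, 4, 7, 7, 7, 7),
      doses = c(0, 2, 2, 2, 2, 3, 3),
      n = n, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "treatment", "day", "doses", "n") %in%
                names(groups)),
            all(groups$n >= 1))
  if (is.null(truth)) {
    truth <- lapply(seq_len(nrow(groups)), function(i)
      default_group_truth(groups$treatment[i], groups$day[i], groups$doses[i]))
    names(truth) <- groups$name
  }
  stopifnot(setequal(names(truth), groups$name))
  structure(list(groups = groups, truth = truth), class = "study_design")
}

#' Run configuration for a synthetic study
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param n_events flow events per animal.
#' @param canvas_px slide canvas edge length (>= 256).
#' @param noise_sd slide RGB noise.
#' @param animal_cv between-animal log-normal coefficient of variation
#'   applied to the group-truth levels.
#' @param spillover flow spillover matrix (identity when `NULL`).
#' @param register `TRUE` to register slide sections,
#'   `FALSE` to trust the generator's alignment.
#' @param reg_levels registration pyramid profile used inside studies.
#' @param reg_maxit per-level iteration caps for in-study registration.
#' @param max_warp list of `scale`, `rot_deg`, `shift_px` bounds for the
#'   random section-to-section transforms.
#' @param sample_volume_ml lysate volume per animal for normalization.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `run_config` object.
#' @export
run_config <- function(seed = 1L, n_events = 10000L, canvas_px = 256L,
                       noise_sd = 0.02, animal_cv = 0.15, spillover = NULL,
                       register = TRUE, reg_levels = c(4, 2),
                       reg_maxit = c(70, 45),
                       max_warp = list(scale = 0.015, rot_deg = 4,
                                       shift_px = 6),
                       sample_volume_ml = 0.5, out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_events = as.integer(n_events),
                 canvas_px = as.integer(canvas_px), noise_sd = noise_sd,
                 animal_cv = animal_cv, spillover = spillover,
                 register = register, reg_levels = reg_levels,
                 reg_maxit = reg_maxit,
                 max_warp = max_warp, sample_volume_ml = sample_volume_ml,
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration (and optionally a gate tree) up front
#'
#' @param config a [run_config()].
#' @param tree optional gating tree checked against the panel channels.
#' @return list with `ok` and a character vector `errors`.
#' @export
validate_config <- function(config, tree = NULL) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(config$n_events >= 1, "n_events must be positive")
  chk(config$canvas_px >= 256, "canvas_px must be at least 256")
  chk(config$noise_sd >= 0, "noise_sd must be non-negative")
  chk(config$animal_cv >= 0, "animal_cv must be non-negative")
  chk(config$sample_volume_ml > 0, "sample_volume_ml must be positive")
  if (!is.null(config$spillover)) {
    chk(is.matrix(config$spillover) &&
          all(dim(config$spillover) == length(FLOW_CHANNELS)),
        "spillover must be square over the panel channels")
    if (is.matrix(config$spillover))
      chk(all(abs(diag(config$spillover) - 1) < 1e-9),
          "spillover diagonal must be 1")
  }
  if (!is.null(config$out_dir))
    chk(dir.exists(dirname(config$out_dir)) || dir.exists(config$out_dir),
        sprintf("output location '%s' does not exist", config$out_dir))
  if (!is.null(tree)) {
    bad <- unlist(lapply(tree, function(nd)
      setdiff(names(nd$thresholds), FLOW_CHANNELS)))
    chk(length(bad) == 0,
        paste("gate tree references unknown channels:",
              paste(unique(bad), collapse = ", ")))
  }
  list(ok = length(errs) == 0, errors = errs)
}

## multiplicative log-normal animal-level jitter, clamped to a range
jitter_level <- function(mu, cv, lo = 0, hi = Inf) {
  pmin(pmax(mu * exp(rnorm(length(mu), 0, cv)), lo), hi)
}

## per-animal flow spec from group truth
animal_flow_spec <- function(tr, cv, n_events, spillover, seed) {
  my <- c(macrophage = jitter_level(tr$macrophage, cv, 0.02, 0.8),
          dc = jitter_level(tr$dc, cv, 0.005, 0.5),
          gmdsc = jitter_level(tr$gmdsc, cv, 0.005, 0.5),
          mmdsc = jitter_level(tr$mmdsc, cv, 0.005, 0.5))
  if (sum(my) > 0.95) my <- my * 0.95 / sum(my)  # keep some other CD45+ cells
  cd45 <- 0.45
  pf <- my * cd45
  pf <- c(pf, other_cd45 = cd45 - sum(pf), non_cd45 = 1 - cd45)
  qd <- jitter_level(tr$quadrants, cv, 0.01)
  qd <- qd / sum(qd)
  flow_spec(n_events = n_events, population_fractions = pf,
            macrophage_quadrant_fractions = qd, spillover = spillover,
            live_fraction = jitter_level(tr$live, cv / 2, 0.55, 0.98),
            seed = seed)
}

#' Run a full synthetic study end to end
#'
#' For every animal of every arm: generates flow events, slide images and
#' bead responses from the arm's truth (with animal-level variability),
#' then runs the complete analysis pipeline - compensation and sequential
#' gating with data-driven thresholds, slide registration/segmentation
#' /metrics with control-calibrated thresholds, standard-curve fitting and
#' inversion - applies the viability/outlier exclusion rules, compares
#' treated vs control arms per day with Wilcoxon rank-sum tests, and
#' computes the cross-modality correlations (VMI vs %M1; F4/80 area vs
#' flow macrophage fraction).
#'
#' @param design a [study_design()].
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return list: `samples` (wide per-animal table), `data` (tidy long
#'   table), `exclusions`, `comparisons`, `correlations`, `truth`
#'   (per-animal planted values), `manifest`.
#' @export
run_synthetic_study <- function(design, config = run_config(),
                                quiet = FALSE) {
  stopifnot(inherits(design, "study_design"), inherits(config, "run_config"))
  v <- validate_config(config)
  if (!v$ok) stop("invalid config:\n  ", paste(v$errors, collapse = "\n  "))
  say <- function(...) if (!quiet) message(sprintf(...))

  groups <- design$groups
  n_total <- sum(groups$n)
  seeds <- derive_seeds(config$seed, n_total + 1L)
  bead_seed <- seeds[n_total + 1L]
  spill <- config$spillover
  if (is.null(spill)) {
    spill <- diag(length(FLOW_CHANNELS))
    dimnames(spill) <- list(FLOW_CHANNELS, FLOW_CHANNELS)
  }

  rows <- list(); truths <- list(); cyt_truth <- list()
  thresholds <- NULL
  k <- 0L
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    tr <- design$truth[[g$name]]
    for (ai in seq_len(g$n)) {
      k <- k + 1L
      sid <- sprintf("%s_a%d", g$name, ai)
      aseed <- seeds[k]
      sub <- derive_seeds(aseed, 4L)

      ## ---- flow cytometry ----
      fspec <- with_seed(sub[1], animal_flow_spec(tr, config$animal_cv,
                                                  config$n_events, spill,
                                                  sub[2]))
      fl <- generate_flow_events(fspec)
      ev <- compensate(fl$events, spill)
      thr <- with_seed(sub[2], auto_gate_thresholds(ev))
      gates <- apply_gate_tree(ev, default_gate_tree(thr))
      memb <- attr(gates, "membership")
      mac_ev <- ev[memb$macrophage, ]
      quads <- macrophage_quadrants(mac_ev, thr["CD38"], thr["CD206"])
      viab <- viability_fraction(ev, thr["PI"])

      ## ---- histology ----
      warp <- config$max_warp
      sspec <- with_seed(sub[3], slide_spec(
        canvas_size_px = c(config$canvas_px, config$canvas_px),
        n_vessels = round(jitter_level(tr$n_vessels, config$animal_cv, 8, 36)),
        sma_coated_fraction = jitter_level(tr$vmi_fraction, config$animal_cv,
                                           0, 0.95),
        necrotic_fraction = jitter_level(tr$necrotic, config$animal_cv,
                                         0.02, 0.35),
        n_nuclei = 120L,
        ki67_positive_fraction = jitter_level(tr$ki67, config$animal_cv,
                                              0.02, 0.95),
        f480_area_fraction = jitter_level(tr$f480, config$animal_cv,
                                          0.005, 0.4),
        vessel_radius_range = c(4, 6.5),  # packs up to ~36 vessels at 256 px
        transform_truth = similarity_transform(
          scale = 1 + runif(1, -warp$scale, warp$scale),
          rotation_deg = runif(1, -warp$rot_deg, warp$rot_deg),
          tx_px = runif(1, -warp$shift_px, warp$shift_px),
          ty_px = runif(1, -warp$shift_px, warp$shift_px)),
        noise_sd = config$noise_sd, seed = sub[4]))
      slide <- generate_slide_set(sspec)
      if (is.null(thresholds))  # one uniform calibration for the study
        thresholds <- calibrate_slide_thresholds(slide$controls)
      met <- quantify_slide(slide$images, slide$masks$necrosis, thresholds,
                            tumor_mask = binary_mask(slide$masks$tumor,
                                                     sspec$pixel_size_um),
                            register = if (isTRUE(config$register)) TRUE
                                       else FALSE,
                            reg_args = list(
                              levels = config$reg_levels,
                              maxit = config$reg_maxit,
                              rot_grid = if (warp$rot_deg <= 4) 0 else
                                c(-warp$rot_deg, 0, warp$rot_deg)))

      ## ---- cytokine truth (plate generated after the loop) ----
      cyt_truth[[sid]] <- with_seed(sub[1] + 1L,
        jitter_level(tr$cytokines, config$animal_cv))

      pick <- function(nm, col) {
        i <- match(nm, gates$name); gates[[col]][i]
      }
      qpick <- function(nm) quads$pct_of_parent[match(nm, quads$name)]
      rows[[sid]] <- data.frame(
        sample_id = sid, group = g$name, treatment = g$treatment,
        day = g$day, doses = g$doses,
        viability_pct = viab,
        pct_macrophage = pick("macrophage", "pct_of_cd45"),
        pct_dc = pick("dc", "pct_of_cd45"),
        pct_gmdsc = pick("gmdsc", "pct_of_cd45"),
        pct_mmdsc = pick("mmdsc", "pct_of_cd45"),
        pct_m0 = qpick("M0"), pct_m1 = qpick("M1"), pct_m2 = qpick("M2"),
        pct_co = qpick("co"),
        mvd_per_mm2 = met$mvd_per_mm2, sma_per_mm2 = met$sma_per_mm2,
        vmi_percent = met$vmi_percent,
        f480_area_percent = met$f480_area_percent,
        ki67_percent = met$ki67_percent,
        necrosis_percent = met$necrosis_percent,
        stringsAsFactors = FALSE)
      truths[[sid]] <- list(flow = fspec[c("population_fractions",
                                           "macrophage_quadrant_fractions",
                                           "live_fraction")],
                            slide = slide$truth,
                            realized = fl$truth[c("fraction_of_cd45",
                                                  "quadrant_fractions")])
    }
    say("group %s done (%d animals)", g$name, g$n)
  }
  samples <- do.call(rbind, rows); rownames(samples) <- NULL

  ## ---- multiplex cytokine plate: one plate, all animals ----
  say("fitting cytokine standard curves")
  conc_truth <- do.call(cbind, cyt_truth)
  bspec <- bead_spec(sample_concentrations_truth = conc_truth,
                     seed = bead_seed)
  plate <- generate_bead_plate(bspec)
  protein <- with_seed(bead_seed + 1L, data.frame(
    sample_id = colnames(conc_truth),
    protein_mg = runif(ncol(conc_truth), 0.8, 1.2),
    volume_ml = config$sample_volume_ml))
  cyt <- quantify_plate(plate$standards, plate$unknowns, protein)
  cw <- reshape(cyt$results[c("analyte", "sample_id", "conc_pg_per_ml")],
                idvar = "sample_id", timevar = "analyte", direction = "wide")
  names(cw) <- sub("^conc_pg_per_ml\\.", "cyt_", names(cw))
  samples <- merge(samples, cw, by = "sample_id", sort = FALSE)
  samples <- samples[order(match(samples$sample_id, names(rows))), ]
  rownames(samples) <- NULL

  ## ---- exclusions: viability < 50% or >= 4 outlying populations ----
  popcols <- c("pct_macrophage", "pct_dc", "pct_gmdsc", "pct_mmdsc",
               "pct_m0", "pct_m1", "pct_m2", "pct_co")
  excl <- apply_exclusions(
    setNames(samples$viability_pct, samples$sample_id),
    as.matrix(`rownames<-`(samples[popcols], samples$sample_id)),
    group = samples$group)
  retained <- samples[!excl$excluded, ]

  ## ---- tidy table + per-day treated-vs-control comparisons ----
  metcols <- setdiff(names(samples),
                     c("sample_id", "group", "treatment", "day", "doses"))
  tidy <- do.call(rbind, lapply(metcols, function(vcol)
    data.frame(sample_id = retained$sample_id, group = retained$group,
               treatment = retained$treatment, day = retained$day,
               doses = retained$doses, variable = vcol,
               value = retained[[vcol]], stringsAsFactors = FALSE)))
  comparisons <- list()
  for (d in unique(groups$day)) {
    for (ds in unique(groups$doses[groups$day == d])) {
      sub_t <- tidy[tidy$day == d & tidy$doses == ds, ]
      if (length(unique(sub_t$treatment)) < 2) next
      cmp <- compare_groups(
        data.frame(sample_id = sub_t$sample_id, group = sub_t$treatment,
                   variable = sub_t$variable, value = sub_t$value,
                   stringsAsFactors = FALSE),
        group_levels = c("control", "treated"))
      cmp$day <- d; cmp$doses <- ds
      comparisons[[sprintf("d%s_x%s", d, ds)]] <- cmp
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  ## ---- cross-modality correlations ----
  correlations <- list(
    vmi_vs_m1 = tryCatch(
      pearson_with_fit(retained$vmi_percent, retained$pct_m1),
      error = function(e) NULL),
    f480_ihc_vs_flow = tryCatch(
      pearson_with_fit(retained$f480_area_percent, retained$pct_macrophage),
      error = function(e) NULL))

  manifest <- list(seed = config$seed,
                   config = unclass(config[setdiff(names(config),
                                                   c("spillover", "out_dir"))]),
                   groups = groups, animal_seeds = setNames(
                     seeds[seq_len(n_total)], samples$sample_id[seq_len(n_total)]),
                   package_version = as.character(utils::packageVersion("tiquant")),
                   slide_thresholds = thresholds)

  out <- list(samples = samples, data = tidy, exclusions = excl,
              comparisons = comparisons, correlations = correlations,
              truth = truths, cytokine = cyt, manifest = manifest)
  if (!is.null(config$out_dir)) write_study_outputs(out, config$out_dir)
  out
}

## CSV/JSON artifacts for a finished run
write_study_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(res$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  if (!is.null(res$comparisons))
    write.csv(res$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  cors <- res$correlations
  cor_df <- do.call(rbind, lapply(names(cors), function(nm) {
    cr <- cors[[nm]]
    if (is.null(cr)) return(NULL)
    data.frame(comparison = nm, r = cr$r, p = cr$p, slope = cr$slope,
               intercept = cr$intercept, n = cr$n)
  }))
  if (!is.null(cor_df))
    write.csv(cor_df, file.path(dir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
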