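#' Specification for a synthetic stained-slide set
#'
#' Describes one tumor's worth of serial-section images: an H&E reference
#' plus CD31, alpha-SMA, F4/80 and Ki67 sections sharing the same tissue
#' geometry, each non-H&E section warped by a known similarity transform.
#' Vessels are rendered as non-overlapping endothelial rings (annuli,
#' ring thickness 3 px) and the smooth-muscle-coated subset is the first
#' `round(sma_coated_fraction * n_vessels)` vessels, so SMA+ vessels are an
#' exact subset of CD31+ vessels.
#'
#' @param canvas_size_px integer pair, both >= 256.
#' @param pixel_size_um physical pixel size (default 0.495, a 20x scan).
#' @param n_vessels number of planted vessel rings.
#' @param sma_coated_fraction fraction of vessels with an alpha-SMA coat.
#' @param necrotic_fraction fraction of tumor area rendered necrotic
#'   (one simply connected eosin-pale region); must be <= 0.9 so the
#'   region fits inside the tumor.
#' @param n_nuclei number of planted nuclei (viable tissue only).
#' @param ki67_positive_fraction fraction of nuclei Ki67-positive; exactly
#'   `round(ki67_positive_fraction * n_nuclei)` nuclei are marked.
#' @param f480_area_fraction target F4/80+ pixel fraction of viable tissue.
#' @param transform_truth `similarity_transform` applied to every non-H&E
#'   section relative to the H&E frame.
#' @param noise_sd Gaussian RGB noise standard deviation (0 = noiseless).
#' @param vessel_radius_range outer-radius range of vessel rings in px.
#' @param nucleus_radius_px nucleus radius in px.
#' @param seed RNG seed; identical specs generate identical slide sets.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(canvas_size_px = c(256L, 256L),
                       pixel_size_um = 0.495,
                       n_vessels = 30L,
                       sma_coated_fraction = 0.25,
                       necrotic_fraction = 0.10,
                       n_nuclei = 120L,
                       ki67_positive_fraction = 0.30,
                       f480_area_fraction = 0.10,
                       transform_truth = similarity_transform(),
                       noise_sd = 0.02,
                       vessel_radius_range = c(4, 8),
                       nucleus_radius_px = 3,
                       seed = 1L) {
  spec <- list(canvas_size_px = as.integer(canvas_size_px),
               pixel_size_um = pixel_size_um, n_vessels = as.integer(n_vessels),
               sma_coated_fraction = sma_coated_fraction,
               necrotic_fraction = necrotic_fraction,
               n_nuclei = as.integer(n_nuclei),
               ki67_positive_fraction = ki67_positive_fraction,
               f480_area_fraction = f480_area_fraction,
               transform_truth = transform_truth, noise_sd = noise_sd,
               vessel_radius_range = vessel_radius_range,
               nucleus_radius_px = nucleus_radius_px, seed = as.integer(seed))
  validate_slide_spec(spec)
  structure(spec, class = "slide_spec")
}

validate_slide_spec <- function(s) {
  fr <- c(sma = s$sma_coated_fraction, nec = s$necrotic_fraction,
          ki67 = s$ki67_positive_fraction, f480 = s$f480_area_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (s$necrotic_fraction > 0.9)
    stop("necrotic_fraction > 0.9 cannot be rendered as one region inside the tumor")
  if (length(s$canvas_size_px) != 2L || any(s$canvas_size_px < 256L))
    stop("canvas dimensions must be at least 256 px")
  if (s$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (s$n_vessels < 0 || s$n_nuclei < 0) stop("counts must be non-negative")
  if (s$noise_sd < 0) stop("noise_sd must be non-negative")
  if (!inherits(s$transform_truth, "similarity_transform"))
    stop("transform_truth must be a similarity_transform")
  invisible(TRUE)
}

## disk / annulus pixel masks on an [nx, ny] raster
disk_mask <- function(dm, cx, cy, r) {
  g <- coord_grids(dm)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

## indices of disk/annulus pixels, computed on a bounding box only
disk_idx <- function(dm, cx, cy, r_out, r_in = 0) {
  xs <- max(1, floor(cx - r_out)):min(dm[1], ceiling(cx + r_out))
  ys <- max(1, floor(cy - r_out)):min(dm[2], ceiling(cy + r_out))
  d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  sel <- d2 <= r_out^2 & d2 >= r_in^2
  (rep(xs, length(ys)))[sel] + (rep(ys, each = length(xs))[sel] - 1) * dm[1]
}

## rejection-sample non-overlapping centres inside the viable ellipse,
## away from the necrotic disk; errors out rather than silently truncating
place_objects <- function(n, radii, ellipse, necrosis, min_gap = 3,
                          max_tries_per = 2000) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)))
  xs <- ys <- numeric(0)
  tries <- 0L; max_tries <- max_tries_per * n
  while (length(xs) < n) {
    if (tries >= max_tries)
      stop(sprintf("infeasible packing: placed %d of %d objects after %d tries",
                   length(xs), n, tries))
    tries <- tries + 1L
    i <- length(xs) + 1L
    r <- radii[i]
    x <- runif(1, ellipse$cx - ellipse$a, ellipse$cx + ellipse$a)
    y <- runif(1, ellipse$cy - ellipse$b, ellipse$cy + ellipse$b)
    in_ell <- ((x - ellipse$cx) / (ellipse$a - r - 2))^2 +
              ((y - ellipse$cy) / (ellipse$b - r - 2))^2 <= 1
    if (!in_ell) next
    if (!is.null(necrosis) && necrosis$r > 0 &&
        sqrt((x - necrosis$cx)^2 + (y - necrosis$cy)^2) < necrosis$r + r + 2)
      next
    if (length(xs) &&
        any(sqrt((xs - x)^2 + (ys - y)^2) < radii[seq_along(xs)] + r + min_gap))
      next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys, r = radii[seq_len(n)])
}

#' Generate a synthetic serial-section slide set with planted ground truth
#'
#' Renders five co-localized stain images (H&E, CD31, SMA, F4/80, Ki67) on a
#' shared elliptical tumor with glass background, plus per-stain
#' positive/negative control tiles, and returns the planted truth
#' (counts, areas, masks).  Non-H&E sections are warped by
#' `spec$transform_truth`; truth masks live in the H&E frame, standing in
#' for the manual annotations (e.g. necrosis) a study would supply.
#'
#' @param spec a [slide_spec()].
#' @return a `slide_set` list with elements `images` (named `stain_image`s),
#'   `controls` (per stain, `list(pos =, neg =)`), `truth` (`slide_truth`)
#'   and `masks` (logical matrices in the H&E frame: `tumor`, `necrosis`,
#'   `viable`, `vessel`, `sma`, `f480`, `nuclei`, `ki67_pos`).
#' @export
generate_slide_set <- function(spec) {
  validate_slide_spec(spec)
  with_seed(spec$seed, {
    dm <- spec$canvas_size_px
    nx <- dm[1]; ny <- dm[2]
    ## anisotropic, lobed tumor boundary: real sections are irregular, and
    ## the irregularity is what makes the section-to-section similarity
    ## transform identifiable from intensities
    a0 <- 0.37 * nx; b0 <- 0.31 * ny
    amp <- c(runif(1, 0.04, 0.07), runif(1, 0.03, 0.05))
    ph <- runif(2, 0, 2 * pi)
    g <- coord_grids(dm)
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    u <- (g$x - cx) / a0; v <- (g$y - cy) / b0
    rho <- sqrt(u^2 + v^2); phi <- atan2(v, u)
    rim <- 1 + amp[1] * sin(2 * phi + ph[1]) + amp[2] * sin(3 * phi + ph[2])
    tumor <- rho <= rim
    tumor_px <- sum(tumor)
    ## conservative inscribed ellipse used for object placement
    shrink <- 1 - sum(amp)
    ell <- list(cx = cx, cy = cy, a = a0 * shrink, b = b0 * shrink)

    ## one simply connected necrotic disk inside the tumor
    nec <- list(cx = ell$cx, cy = ell$cy, r = 0)
    necrosis <- matrix(FALSE, nx, ny)
    if (spec$necrotic_fraction > 0) {
      rn <- sqrt(spec$necrotic_fraction * tumor_px / pi)
      max_off <- max(min(ell$a, ell$b) - rn - 3, 0)
      off <- runif(1, 0, max_off); ang <- runif(1, 0, 2 * pi)
      nec <- list(cx = ell$cx + off * cos(ang), cy = ell$cy + off * sin(ang),
                  r = rn)
      necrosis <- disk_mask(dm, nec$cx, nec$cy, nec$r) & tumor
    }
    viable <- tumor & !necrosis

    ## vessels: non-overlapping annuli in viable tissue
    rr <- spec$vessel_radius_range
    radii <- if (spec$n_vessels > 0) runif(spec$n_vessels, rr[1], rr[2]) else numeric(0)
    vess <- place_objects(spec$n_vessels, radii, ell, nec)
    vessel_mask <- matrix(FALSE, nx, ny)
    vessel_labels <- matrix(0L, nx, ny)
    n_sma <- round(spec$sma_coated_fraction * spec$n_vessels)
    sma_mask <- matrix(FALSE, nx, ny)
    for (i in seq_len(nrow(vess))) {
      idx <- disk_idx(dm, vess$x[i], vess$y[i], vess$r[i],
                      max(vess$r[i] - 3, 1))
      vessel_mask[idx] <- TRUE
      vessel_labels[idx] <- i
      if (i <= n_sma) sma_mask[idx] <- TRUE
    }

    ## nuclei: disks in viable tissue; Ki67+ = first k
    rn_nuc <- spec$nucleus_radius_px
    nuc <- place_objects(spec$n_nuclei, rep(rn_nuc, spec$n_nuclei), ell, nec,
                         min_gap = 2, max_tries_per = 2000)
    nuclei_mask <- matrix(FALSE, nx, ny)
    k_pos <- round(spec$ki67_positive_fraction * spec$n_nuclei)
    ki67_mask <- matrix(FALSE, nx, ny)
    for (i in seq_len(nrow(nuc))) {
      idx <- disk_idx(dm, nuc$x[i], nuc$y[i], rn_nuc)
      nuclei_mask[idx] <- TRUE
      if (i <= k_pos) ki67_mask[idx] <- TRUE
    }

    ## F4/80: blob texture grown to an exact positive-pixel count
    viable_px <- sum(viable)
    target <- round(spec$f480_area_fraction * viable_px)
    f480_mask <- matrix(FALSE, nx, ny)
    if (target > 0) {
      vidx <- which(viable)
      guard <- 0L
      while (sum(f480_mask) < target && guard < 10000L) {
        guard <- guard + 1L
        ctr_i <- vidx[sample.int(length(vidx), 1)]
        bcx <- (ctr_i - 1) %% nx + 1; bcy <- (ctr_i - 1) %/% nx + 1
        bidx <- disk_idx(dm, bcx, bcy, runif(1, 2.5, 5))
        bidx <- bidx[viable[bidx] & !f480_mask[bidx]]
        need <- target - sum(f480_mask)
        if (length(bidx) > need) {
          ## add the innermost pixels of the final blob only
          bx <- (bidx - 1) %% nx + 1; by <- (bidx - 1) %/% nx + 1
          bidx <- bidx[order((bx - bcx)^2 + (by - bcy)^2)][seq_len(need)]
        }
        f480_mask[bidx] <- TRUE
      }
      if (sum(f480_mask) < target)
        stop("could not reach target F4/80 area fraction")
    }

    ## ---- render amounts (H&E frame), then warp + colorize ----
    ## shared tissue texture: serial sections show the same density
    ## pattern in every stain's counterstain, which is what makes
    ## intensity-based cross-stain registration work
    tex <- matrix(rnorm(nx * ny), nx, ny)
    tex <- as.matrix(EBImage::gblur(tex, sigma = 6))
    tex <- pmin(pmax(tex / sd(tex), -2), 2)
    he_am <- list(hematoxylin = 0.10 * viable + 0.03 * necrosis + 0.85 * nuclei_mask,
                  eosin = (0.45 + 0.10 * tex) * viable + 0.15 * necrosis)
    ## the hematoxylin counterstain shows the same nuclei in every section
    counter <- (0.25 + 0.08 * tex) * tumor + 0.50 * nuclei_mask
    scene <- list(
      HE   = he_am,
      CD31 = list(hematoxylin = counter, dab = 0.80 * vessel_mask),
      SMA  = list(hematoxylin = counter, dab = 0.80 * sma_mask),
      F480 = list(hematoxylin = counter, dab = 0.70 * f480_mask),
      KI67 = list(hematoxylin = (0.20 + 0.08 * tex) * tumor + 0.50 * nuclei_mask,
                  dab = 0.80 * ki67_mask))
    tf <- spec$transform_truth
    images <- list()
    for (st in names(scene)) {
      am <- scene[[st]]
      if (st != "HE" && !is_identity_transform(tf))
        am <- lapply(am, warp_from_fixed, tf = tf)
      rgb <- render_od(am, dm)
      if (spec$noise_sd > 0) {
        rgb <- rgb + array(rnorm(length(rgb), 0, spec$noise_sd), dim(rgb))
        rgb <- pmin(pmax(rgb, 0), 1)
      }
      images[[st]] <- stain_image(rgb, st, spec$pixel_size_um)
    }

    controls <- make_control_tiles(spec)

    truth <- structure(list(
      vessel_count = nrow(vess),
      sma_vessel_count = n_sma,
      viable_area_mm2 = px_area_mm2(viable_px, spec$pixel_size_um),
      necrotic_area_mm2 = px_area_mm2(sum(necrosis), spec$pixel_size_um),
      tumor_area_mm2 = px_area_mm2(tumor_px, spec$pixel_size_um),
      nuclei_total = nrow(nuc),
      nuclei_ki67_pos = k_pos,
      f480_positive_px = sum(f480_mask),
      viable_px = viable_px,
      vessel_centers = vess,
      nuclei_centers = nuc,
      transform = tf), class = "slide_truth")
    stopifnot(truth$sma_vessel_count <= truth$vessel_count,
              truth$nuclei_ki67_pos <= truth$nuclei_total)

    structure(list(images = images, controls = controls, truth = truth,
                   masks = list(tumor = tumor, necrosis = necrosis,
                                viable = viable, vessel = vessel_mask,
                                vessel_labels = vessel_labels,
                                sma = sma_mask, f480 = f480_mask,
                                nuclei = nuclei_mask, ki67_pos = ki67_mask)),
              class = "slide_set")
  })
}

## pure-stain and background control tiles, 64 x 64, per stain
make_control_tiles <- function(spec, side = 64L) {
  dm <- c(side, side)
  one <- matrix(1, side, side)
  tile <- function(am) {
    rgb <- render_od(am, dm)
    if (spec$noise_sd > 0) {
      rgb <- rgb + array(rnorm(length(rgb), 0, spec$noise_sd), dim(rgb))
      rgb <- pmin(pmax(rgb, 0), 1)
    }
    rgb
  }
  ctl <- list()
  for (st in c("CD31", "SMA", "F480", "KI67")) {
    amt <- if (st == "F480") 0.70 else 0.80
    ctl[[st]] <- list(
      pos = stain_image(tile(list(hematoxylin = 0.25 * one, dab = amt * one)),
                        st, spec$pixel_size_um),
      neg = stain_image(tile(list(hematoxylin = 0.25 * one)),
                        st, spec$pixel_size_um))
  }
  ## H&E controls calibrate the hematoxylin (nucleus) channel
  ctl$HE <- list(
    pos = stain_image(tile(list(hematoxylin = 0.85 * one, eosin = 0.45 * one)),
                      "HE", spec$pixel_size_um),
    neg = stain_image(tile(list(hematoxylin = 0.10 * one, eosin = 0.45 * one)),
                      "HE", spec$pixel_size_um))
  ctl
}
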