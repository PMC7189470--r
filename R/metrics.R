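#' Count vessel objects in a segmented CD31 (or SMA) mask
#'
#' A vessel is an 8-connected component of the stain mask with size inside
#' `size_range` pixels.  Components straddling the viable-tissue boundary
#' are counted when the majority of their pixels lie in viable tissue.
#'
#' @param mask segmented stain `binary_mask`.
#' @param viable viable-tissue `binary_mask` (co-registered).
#' @param size_range component size gates in pixels, default `c(8, 1e4)`.
#' @return integer vessel count.
#' @export
count_vessels <- function(mask, viable, size_range = c(8, 1e4)) {
  m <- mask_pixels(mask); v <- mask_pixels(viable)
  stopifnot(all(dim(m) == dim(v)))
  if (!any(m)) return(0L)
  lab <- label_components(m)
  nlab <- max(lab)
  sz <- tabulate(lab[lab > 0], nbins = nlab)
  in_v <- tabulate(lab[lab > 0 & v], nbins = nlab)
  sum(sz >= size_range[1] & sz <= size_range[2] & in_v > sz / 2)
}

#' Object density per square millimetre
#'
#' @param count object count.
#' @param viable_area_mm2 viable tissue area in mm^2 (> 0).
#' @return objects per mm^2.
#' @export
density_per_mm2 <- function(count, viable_area_mm2) {
  if (!isTRUE(viable_area_mm2 > 0)) stop("viable area must be positive")
  count / viable_area_mm2
}

#' Vessel maturation index
#'
#' The ratio of alpha-SMA+ (mural-coated) vessel density to CD31
#' microvessel density, expressed as a percentage.
#'
#' @param sma_per_mm2 SMA+ vessel density.
#' @param mvd_per_mm2 CD31 microvessel density; 0 makes the index
#'   undefined (`NA` with a warning).
#' @return percentage (100 means every microvessel is coated).
#' @export
vessel_maturation_index <- function(sma_per_mm2, mvd_per_mm2) {
  if (!isTRUE(mvd_per_mm2 > 0)) {
    warning("vessel maturation index undefined: microvessel density is zero")
    return(NA_real_)
  }
  100 * sma_per_mm2 / mvd_per_mm2
}

#' Positive-stain area as a percentage of viable tissue
#'
#' @param stain_mask segmented stain `binary_mask`.
#' @param viable viable-tissue `binary_mask`.
#' @return percent of viable-tissue pixels that are stain-positive.
#' @export
area_fraction <- function(stain_mask, viable) {
  s <- mask_pixels(stain_mask); v <- mask_pixels(viable)
  stopifnot(all(dim(s) == dim(v)))
  nv <- sum(v)
  if (nv == 0) stop("viable mask is empty")
  100 * sum(s & v) / nv
}

#' Detect nuclei in a hematoxylin-counterstained image
#'
#' Thresholds the hematoxylin channel and splits touching blobs with a
#' distance-transform watershed.
#'
#' @param image H&E or Ki67 `stain_image` (the Ki67 counterstain is
#'   hematoxylin, so both work).
#' @param threshold hematoxylin-channel threshold, e.g. calibrated from
#'   H&E controls.
#' @param min_px blobs smaller than this are discarded as debris.
#' @return data.frame of nucleus centroids (`x`, `y`) in pixels.
#' @export
detect_nuclei <- function(image, threshold, min_px = 6L) {
  stopifnot(inherits(image, "stain_image"))
  basis <- if (image$stain == "HE") "h_e" else "h_dab"
  ch <- color_deconvolve(image, basis)$hematoxylin
  mask <- ch > threshold
  if (!any(mask)) return(data.frame(x = numeric(0), y = numeric(0)))
  dist <- EBImage::distmap(mask * 1)
  lab <- as.matrix(EBImage::watershed(dist))
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_px)
  if (!length(keep)) return(data.frame(x = numeric(0), y = numeric(0)))
  idx <- which(lab > 0 & matrix(lab %in% keep, nrow(lab), ncol(lab)))
  li <- lab[idx]
  xs <- (idx - 1) %% nrow(lab) + 1
  ys <- (idx - 1) %/% nrow(lab) + 1
  data.frame(x = as.vector(tapply(xs, li, mean)),
             y = as.vector(tapply(ys, li, mean)))
}

#' Ki67 positivity as a percentage of total nuclei
#'
#' A nucleus is positive when its centroid (nearest pixel) falls inside
#' the segmented Ki67 mask.
#'
#' @param nuclei centroid data.frame from [detect_nuclei()].
#' @param ki67_mask segmented Ki67 `binary_mask`.
#' @return percent of nuclei positive.
#' @export
ki67_percent <- function(nuclei, ki67_mask) {
  if (nrow(nuclei) == 0) stop("no nuclei detected; Ki67 percent undefined")
  m <- mask_pixels(ki67_mask)
  xi <- pmin(pmax(round(nuclei$x), 1), nrow(m))
  yi <- pmin(pmax(round(nuclei$y), 1), ncol(m))
  100 * mean(m[cbind(xi, yi)])
}

#' Per-tumor slide metrics
#'
#' @param mvd_per_mm2,sma_per_mm2 vessel densities.
#' @param vmi_percent vessel maturation index (percent).
#' @param f480_area_percent,ki67_percent,necrosis_percent percentages.
#' @param viable_area_mm2 viable tissue area.
#' @return a `slide_metrics` object.
#' @export
slide_metrics <- function(mvd_per_mm2, sma_per_mm2, vmi_percent,
                          f480_area_percent, ki67_percent, necrosis_percent,
                          viable_area_mm2) {
  pct <- c(f480_area_percent, ki67_percent, necrosis_percent)
  stopifnot(mvd_per_mm2 >= 0, sma_per_mm2 >= 0, viable_area_mm2 >= 0,
            all(pct >= 0 & pct <= 100))
  if (mvd_per_mm2 > 0)
    stopifnot(abs(vmi_percent * mvd_per_mm2 - 100 * sma_per_mm2) < 1e-9 *
                max(1, 100 * sma_per_mm2))
  structure(list(mvd_per_mm2 = mvd_per_mm2, sma_per_mm2 = sma_per_mm2,
                 vmi_percent = vmi_percent,
                 f480_area_percent = f480_area_percent,
                 ki67_percent = ki67_percent,
                 necrosis_percent = necrosis_percent,
                 viable_area_mm2 = viable_area_mm2),
            class = "slide_metrics")
}

#' @export
print.slide_metrics <- function(x, ...) {
  cat(sprintf(paste0("<slide_metrics> MVD %.1f /mm2 | SMA %.1f /mm2 | ",
                     "VMI %.1f%% | F4/80 %.2f%% | Ki67 %.1f%% | ",
                     "necrosis %.1f%% | viable %.3f mm2\n"),
              x$mvd_per_mm2, x$sma_per_mm2, x$vmi_percent,
              x$f480_area_percent, x$ki67_percent, x$necrosis_percent,
              x$viable_area_mm2))
  invisible(x)
}

#' Quantify one tumor's slide set into the six histology metrics
#'
#' Registers each stained section to the H&E reference (unless `register`
#' is `FALSE`, for pre-aligned sets), resamples the stain channel into the
#' H&E frame, segments with the control-calibrated thresholds, and computes
#' microvessel density, SMA+ vessel density, vessel maturation index,
#' F4/80 area fraction, Ki67 positivity and necrosis fraction.  All
#' cross-stain mask arithmetic happens after registration.
#'
#' @param images named list of `stain_image`s (`HE`, `CD31`, `SMA`,
#'   `F480`, `KI67`), e.g. `generate_slide_set(spec)$images`.
#' @param necrosis_mask necrotic-region `binary_mask` (or logical matrix)
#'   in the H&E frame; necrosis is annotated manually in practice, so it
#'   is an input here.
#' @param thresholds named list of calibrated thresholds per stain
#'   (see [calibrate_slide_thresholds()]).
#' @param tumor_mask optional tumor-tissue mask; derived from the H&E
#'   image (tissue vs glass) when `NULL`.
#' @param register `TRUE` to estimate registrations, `FALSE` to treat the
#'   set as already aligned, or a named list of `similarity_transform`s.
#' @param reg_args extra arguments passed to [register_similarity()].
#' @return a `slide_metrics` object with attributes `transforms` and
#'   `vessel_counts`.
#' @export
quantify_slide <- function(images, necrosis_mask, thresholds,
                           tumor_mask = NULL, register = TRUE,
                           reg_args = list()) {
  need <- c("HE", "CD31", "SMA", "F480", "KI67")
  if (!all(need %in% names(images)))
    stop("missing stains: ", paste(setdiff(need, names(images)), collapse = ", "))
  he <- images$HE
  psz <- he$pixel_size_um
  if (is.null(tumor_mask)) tumor_mask <- tumor_mask_from_he(he)
  if (!inherits(necrosis_mask, "binary_mask"))
    necrosis_mask <- binary_mask(necrosis_mask, psz)
  viable <- viable_mask(tumor_mask, necrosis_mask)
  viable_area <- mask_area_mm2(viable)
  if (viable_area <= 0) stop("stage viable_mask: no viable tissue")

  transforms <- list()
  masks <- list()
  amounts_fixed <- list()
  for (st in c("CD31", "SMA", "F480", "KI67")) {
    img <- images[[st]]
    tf <- if (isTRUE(register)) {
      do.call(register_similarity, c(list(moving = img, fixed = he), reg_args))
    } else if (is.list(register) && !is.null(register[[st]])) {
      register[[st]]
    } else similarity_transform()
    transforms[[st]] <- tf
    ch <- stain_channel(img)
    ch_fixed <- if (is_identity_transform(tf)) ch else resample_to_fixed(ch, tf)
    amounts_fixed[[st]] <- ch_fixed
    m <- ch_fixed > thresholds[[st]]
    lab <- label_components(m)
    if (max(lab) > 0) {
      sz <- tabulate(lab[lab > 0])
      m <- matrix(lab %in% which(sz >= 4), nrow(m), ncol(m))
    }
    masks[[st]] <- binary_mask(m, psz)
  }

  n_cd31 <- count_vessels(masks$CD31, viable)
  n_sma <- count_vessels(masks$SMA, viable)
  mvd <- density_per_mm2(n_cd31, viable_area)
  sma_d <- density_per_mm2(n_sma, viable_area)
  vmi <- if (mvd > 0) vessel_maturation_index(sma_d, mvd) else {
    warning("stage vmi: no microvessels; index undefined"); NA_real_
  }
  f480 <- area_fraction(masks$F480, viable)

  ## nuclei from the Ki67 counterstain, resampled into the H&E frame
  ki_img <- images$KI67
  tf_ki <- transforms$KI67
  hem <- color_deconvolve(ki_img, "h_dab")$hematoxylin
  hem_fixed <- if (is_identity_transform(tf_ki)) hem else
    resample_to_fixed(hem, tf_ki)
  ki_counter <- stain_image(10^(-(hem_fixed %o% STAIN_VECTORS$hematoxylin)),
                            "KI67", psz)
  nuclei <- detect_nuclei(ki_counter, thresholds$HE)
  ki67 <- if (nrow(nuclei) > 0) ki67_percent(nuclei, masks$KI67) else {
    warning("stage ki67: no nuclei detected"); NA_real_
  }

  tumor_px <- sum(mask_pixels(tumor_mask))
  nec_pct <- 100 * sum(mask_pixels(necrosis_mask) & mask_pixels(tumor_mask)) /
    tumor_px

  out <- slide_metrics(mvd_per_mm2 = mvd, sma_per_mm2 = sma_d,
                       vmi_percent = if (is.na(vmi)) 0 else vmi,
                       f480_area_percent = f480,
                       ki67_percent = if (is.na(ki67)) 0 else ki67,
                       necrosis_percent = nec_pct,
                       viable_area_mm2 = viable_area)
  if (is.na(vmi)) out$vmi_percent <- NA_real_
  if (is.na(ki67)) out$ki67_percent <- NA_real_
  attr(out, "transforms") <- transforms
  attr(out, "vessel_counts") <- c(cd31 = n_cd31, sma = n_sma)
  attr(out, "n_nuclei") <- nrow(nuclei)
  out
}

#' Calibrate every stain threshold from a control set
#'
#' @param controls per-stain list of `list(pos =, neg =)` control tiles,
#'   e.g. `generate_slide_set(spec)$controls`.
#' @return named list of scalar thresholds.
#' @export
calibrate_slide_thresholds <- function(controls) {
  lapply(controls, function(p) calibrate_threshold(p$pos, p$neg))
}
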