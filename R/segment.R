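#' Binary mask with physical pixel size
#'
#' @param pixels logical matrix.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size_um) {
  stopifnot(is.logical(pixels) || all(pixels %in% c(0, 1, TRUE, FALSE)),
            pixel_size_um > 0)
  structure(list(pixels = matrix(as.logical(pixels), nrow(pixels), ncol(pixels)),
                 pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

mask_pixels <- function(m) if (inherits(m, "binary_mask")) m$pixels else m

#' Area of a binary mask in square millimetres
#' @param mask a `binary_mask`.
#' @export
mask_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  px_area_mm2(sum(mask$pixels), mask$pixel_size_um)
}

## 8-connected component labelling: EBImage's bwlabel is 4-connected, so
## labels touching only diagonally are merged with a union-find pass
label_components <- function(mask) {
  m <- mask_pixels(mask)
  lab <- as.matrix(EBImage::bwlabel(m * 1))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nx, -ny]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-1, -ny]), as.vector(lab[-nx, -1])))   # / diagonal
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, 1L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Calibrate a stain threshold from positive and negative controls
#'
#' Picks the scalar threshold on the unmixed stain channel that minimizes
#' the misclassification between the two control intensity distributions
#' (minimum-error threshold between the two histograms, midpoint of the
#' minimizing interval).  The value is then reused uniformly across every
#' tumor for that stain.
#'
#' @param positive_ctrl,negative_ctrl `stain_image`s of the same stain:
#'   a pure-stain tile and a background tile.
#' @param max_overlap maximum tolerated misclassification fraction before
#'   the controls are declared inseparable.
#' @return scalar threshold with attribute `misclassification`.
#' @export
calibrate_threshold <- function(positive_ctrl, negative_ctrl,
                                max_overlap = 0.25) {
  stopifnot(inherits(positive_ctrl, "stain_image"),
            inherits(negative_ctrl, "stain_image"))
  if (positive_ctrl$stain != negative_ctrl$stain)
    stop("controls must be of the same stain")
  vp <- as.vector(stain_channel(positive_ctrl))
  vn <- as.vector(stain_channel(negative_ctrl))
  cand <- seq(min(vn, vp), max(vn, vp), length.out = 512L)
  ## classify positive when value > threshold (ties to background,
  ## matching segment_stain's strict inequality)
  err <- vapply(cand, function(t) (mean(vp <= t) + mean(vn > t)) / 2,
                numeric(1))
  best <- min(err)
  if (best > max_overlap)
    stop(sprintf(paste0("controls are not separable: minimum ",
                        "misclassification %.1f%% exceeds %.1f%%"),
                 100 * best, 100 * max_overlap))
  thr <- mean(range(cand[err == best]))
  attr(thr, "misclassification") <- best
  thr
}

#' Segment a stain image by a calibrated threshold
#'
#' Pixels whose unmixed stain-channel value strictly exceeds the threshold,
#' followed by morphological cleanup removing objects smaller than
#' `min_object_px` pixels.
#'
#' @param image a `stain_image`.
#' @param threshold scalar from [calibrate_threshold()] for the same stain.
#' @param min_object_px objects below this size are removed (default 4).
#' @return a `binary_mask`.
#' @export
segment_stain <- function(image, threshold, min_object_px = 4L) {
  stopifnot(inherits(image, "stain_image"))
  ch <- stain_channel(image)
  mask <- ch > threshold
  if (any(mask) && min_object_px > 1) {
    lab <- label_components(mask)
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  binary_mask(mask, image$pixel_size_um)
}

#' Viable-tissue mask: total tumor area minus necrotic area
#'
#' @param tumor_mask,necrosis_mask `binary_mask`s of identical shape.
#'   Necrotic pixels outside the tumor raise a warning and are clipped.
#' @return a `binary_mask` of viable tissue, with attribute `area_mm2`.
#' @export
viable_mask <- function(tumor_mask, necrosis_mask) {
  tm <- mask_pixels(tumor_mask); nm <- mask_pixels(necrosis_mask)
  if (!all(dim(tm) == dim(nm))) stop("mask shapes differ")
  outside <- sum(nm & !tm)
  if (outside > 0) {
    warning(sprintf("%d necrosis pixels outside the tumor were clipped",
                    outside))
    nm <- nm & tm
  }
  v <- binary_mask(tm & !nm, tumor_mask$pixel_size_um)
  attr(v, "area_mm2") <- mask_area_mm2(v)
  v
}

## tissue-vs-glass mask from the H&E image: glass transmits nearly all
## light; tissue is thresholded on grayscale, holes filled, largest
## component kept
tumor_mask_from_he <- function(he_image, glass_level = 0.93) {
  g <- to_grayscale(he_image)
  m <- g < glass_level
  lab <- as.matrix(EBImage::fillHull(EBImage::bwlabel(m * 1)))
  if (max(lab) > 1) {
    sz <- tabulate(lab[lab > 0])
    m <- lab == which.max(sz)
  } else m <- lab > 0
  binary_mask(m, he_image$pixel_size_um)
}
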