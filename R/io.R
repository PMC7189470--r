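#' Write / read a stain image as TIFF with a JSON sidecar
#'
#' The raster goes to `path` (TIFF or PNG by extension) and the stain
#' label plus physical pixel size to `path.json`.
#'
#' @param image a `stain_image`.
#' @param path output file (`.tif` or `.png`).
#' @return `path`, invisibly.
#' @export
write_stain_image <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  px <- image$pixels
  img <- EBImage::Image(px, dim = dim(px),
                        colormode = if (length(dim(px)) == 3) "Color"
                                    else "Grayscale")
  EBImage::writeImage(img, path)
  jsonlite::write_json(list(stain = image$stain,
                            pixel_size_um = image$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_image
#' @export
read_stain_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  img <- EBImage::readImage(path)
  px <- as.array(img)
  if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
  stain_image(px, meta$stain, meta$pixel_size_um)
}

#' Write / read a binary mask as a 0/255 PNG
#'
#' @param mask a `binary_mask`.
#' @param path output PNG.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  EBImage::writeImage(EBImage::Image(mask$pixels * 1), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param pixel_size_um physical pixel size of the stored mask.
#' @export
read_mask_png <- function(path, pixel_size_um = 0.495) {
  px <- as.array(EBImage::readImage(path))
  if (length(dim(px)) == 3) px <- px[, , 1]
  binary_mask(px > 0.5, pixel_size_um)
}

#' Write a generated slide set to a directory
#'
#' Emits the five stain TIFFs with sidecar JSON, per-stain control tiles,
#' the truth masks (including the necrosis mask, standing in for a manual
#' annotation) as 0/255 PNGs, and the planted truth as JSON.
#'
#' @param set a `slide_set` from [generate_slide_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_slide_set <- function(set, dir) {
  dir.create(file.path(dir, "controls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  psz <- set$images$HE$pixel_size_um
  for (st in names(set$images))
    write_stain_image(set$images[[st]], file.path(dir, paste0(st, ".tif")))
  for (st in names(set$controls)) {
    write_stain_image(set$controls[[st]]$pos,
                      file.path(dir, "controls", paste0(st, "_pos.tif")))
    write_stain_image(set$controls[[st]]$neg,
                      file.path(dir, "controls", paste0(st, "_neg.tif")))
  }
  for (mk in c("tumor", "necrosis", "viable", "vessel", "sma", "f480"))
    write_mask_png(binary_mask(set$masks[[mk]], psz),
                   file.path(dir, "masks", paste0(mk, ".png")))
  tr <- set$truth
  jsonlite::write_json(
    list(vessel_count = tr$vessel_count,
         sma_vessel_count = tr$sma_vessel_count,
         viable_area_mm2 = tr$viable_area_mm2,
         necrotic_area_mm2 = tr$necrotic_area_mm2,
         tumor_area_mm2 = tr$tumor_area_mm2,
         nuclei_total = tr$nuclei_total,
         nuclei_ki67_pos = tr$nuclei_ki67_pos,
         f480_positive_px = tr$f480_positive_px,
         transform = unclass(tr$transform)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a flow-cytometry event table as CSV
#'
#' One header row of channel names, one row per event.
#'
#' @param path CSV file.
#' @param require_panel check that every panel channel is present.
#' @return event data.frame.
#' @export
read_event_table <- function(path, require_panel = TRUE) {
  ev <- read.csv(path, check.names = FALSE)
  if (require_panel) {
    miss <- setdiff(FLOW_CHANNELS, colnames(ev))
    if (length(miss)) stop("event table missing channels: ",
                           paste(miss, collapse = ", "))
  }
  if (any(!complete.cases(ev))) stop("event table contains missing values")
  ev
}

#' @rdname read_event_table
#' @param events event data.frame to write.
#' @export
write_event_table <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' QC overlay: mask boundaries painted on the source image
#'
#' @param image a `stain_image`.
#' @param mask a `binary_mask` in the same frame.
#' @param path output PNG.
#' @param color RGB triplet in [0, 1] for the boundary.
#' @export
write_qc_overlay <- function(image, mask, path, color = c(0, 1, 0)) {
  m <- mask_pixels(mask)
  er <- as.matrix(EBImage::erode(m * 1, EBImage::makeBrush(3, "box"))) > 0.5
  edge <- m & !er
  px <- image$pixels
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  for (ch in 1:3) {
    pl <- px[, , ch]; pl[edge] <- color[ch]; px[, , ch] <- pl
  }
  EBImage::writeImage(EBImage::Image(px, dim = dim(px), colormode = "Color"),
                      path)
  invisible(path)
}
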