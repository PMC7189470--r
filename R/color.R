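## Optical-density stain vectors (Ruifrok-Johnston convention, unit length).
## Chromogenic stains combine linearly in OD space: OD = -log10(I/I0).
STAIN_VECTORS <- local({
  nrm <- function(v) v / sqrt(sum(v^2))
  list(
    hematoxylin = nrm(c(0.650, 0.704, 0.286)),
    eosin       = nrm(c(0.072, 0.990, 0.105)),
    dab         = nrm(c(0.268, 0.570, 0.776))
  )
})

## residual vector orthogonal to two stain vectors (completes the basis)
stain_residual <- function(v1, v2) {
  v <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  v / sqrt(sum(v^2))
}

VALID_STAINS <- c("HE", "CD31", "SMA", "F480", "KI67")

#' Construct a stained-section image
#'
#' Bundles an RGB raster with its stain label and physical pixel size.
#' Pixel values are stored as given; the synthetic generator produces
#' values in [0, 1] (transmitted-light fractions).
#'
#' @param pixels numeric array `[nx, ny, 3]` (RGB) or `[nx, ny]`.
#' @param stain one of `"HE"`, `"CD31"`, `"SMA"`, `"F480"`, `"KI67"`.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @return a `stain_image` object.
#' @export
stain_image <- function(pixels, stain, pixel_size_um = 0.495) {
  stain <- match.arg(stain, VALID_STAINS)
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2L, 3L),
            pixel_size_um > 0, all(dim(pixels)[1:2] >= 1))
  if (length(dim(pixels)) == 3L) stopifnot(dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, stain = stain,
                 pixel_size_um = pixel_size_um),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image> %s  %d x %d px  (%.4g um/px)\n",
              x$stain, d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Convert an RGB image to grayscale
#'
#' Luminance-weighted sum (0.299 R + 0.587 G + 0.114 B); the numeric range
#' of the input is preserved (0-255 input gives 0-255 output).
#'
#' @param image a `stain_image` or an RGB array `[nx, ny, 3]`.
#' @return a single-channel numeric matrix.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "stain_image")) image$pixels else image
  if (length(dim(px)) == 2L) return(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

## Render stain amounts to a transmitted-light RGB array.
## amounts: named list of [nx,ny] matrices keyed by stain vector name.
render_od <- function(amounts, dm) {
  od <- array(0, c(dm[1], dm[2], 3))
  for (nm in names(amounts)) {
    v <- STAIN_VECTORS[[nm]]
    for (ch in 1:3) od[, , ch] <- od[, , ch] + amounts[[nm]] * v[ch]
  }
  10^(-od)
}

#' Unmix an RGB image into stain amounts (color deconvolution)
#'
#' Projects per-pixel optical density onto a fixed two-stain basis
#' (hematoxylin plus either eosin or the brown chromogen) completed by an
#' orthogonal residual.  One scalar threshold per stain is meaningful on
#' the unmixed amount channel across tiles, which is what makes
#' control-calibrated thresholds transferable.
#'
#' @param image `stain_image` or RGB array with values in (0, 1].
#' @param basis `"h_dab"` (default, for chromogenic IHC) or `"h_e"`.
#' @return list of matrices `hematoxylin`, `chromogen`, `residual`.
#' @export
color_deconvolve <- function(image, basis = c("h_dab", "h_e")) {
  basis <- match.arg(basis)
  px <- if (inherits(image, "stain_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3L)
  v1 <- STAIN_VECTORS$hematoxylin
  v2 <- if (basis == "h_dab") STAIN_VECTORS$dab else STAIN_VECTORS$eosin
  v3 <- stain_residual(v1, v2)
  M <- rbind(v1, v2, v3)            # rows = stain OD vectors; od = amounts %*% M
  Minv <- solve(M)
  dm <- dim(px)[1:2]
  od <- -log10(pmax(px, 1 / 256))   # guard against log(0)
  flat <- matrix(od, ncol = 3L)
  am <- flat %*% Minv
  list(hematoxylin = matrix(am[, 1], dm[1], dm[2]),
       chromogen   = matrix(am[, 2], dm[1], dm[2]),
       residual    = matrix(am[, 3], dm[1], dm[2]))
}

## the channel a scalar threshold is applied to, per stain:
## H&E thresholds act on hematoxylin (nuclei), IHC stains on the chromogen
stain_channel <- function(image) {
  if (image$stain == "HE")
    color_deconvolve(image, "h_e")$hematoxylin
  else
    color_deconvolve(image, "h_dab")$chromogen
}
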