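#' Similarity transform (scale, rotation, translation)
#'
#' Maps moving-image coordinates into the fixed (H&E) frame:
#' `x_fixed = scale * R(rotation) * (x_moving - c) + c + t`,
#' where `c` is the image centre and `t = (tx_px, ty_px)`.
#' Rotation is counter-clockwise in pixel coordinates.
#'
#' @param scale positive scale factor.
#' @param rotation_deg rotation in degrees.
#' @param tx_px,ty_px translation in pixels.
#' @return a `similarity_transform` object.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 tx_px = 0, ty_px = 0) {
  stopifnot(is.finite(scale), scale > 0,
            is.finite(rotation_deg), is.finite(tx_px), is.finite(ty_px))
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 tx_px = tx_px, ty_px = ty_px),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale=%.4f rot=%.3f deg t=(%.2f, %.2f) px\n",
              x$scale, x$rotation_deg, x$tx_px, x$ty_px))
  invisible(x)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  abs(tf$scale - 1) < tol && abs(tf$rotation_deg) < tol &&
    abs(tf$tx_px) < tol && abs(tf$ty_px) < tol
}

## forward-map points (moving -> fixed) about centre `ctr`
transform_points <- function(tf, x, y, ctr) {
  th <- tf$rotation_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  dx <- x - ctr[1]; dy <- y - ctr[2]
  list(x = tf$scale * (cs * dx - sn * dy) + ctr[1] + tf$tx_px,
       y = tf$scale * (sn * dx + cs * dy) + ctr[2] + tf$ty_px)
}

invert_transform <- function(tf) {
  th <- tf$rotation_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  ## inverse of x' = sR(x-c)+c+t is x = (1/s)R^T(x'-c-t)+c
  ## expressed in the same centred form: scale 1/s, rot -theta,
  ## t_inv = -(1/s) R^T t
  similarity_transform(
    scale = 1 / tf$scale,
    rotation_deg = -tf$rotation_deg,
    tx_px = -( cs * tf$tx_px + sn * tf$ty_px) / tf$scale,
    ty_px = -(-sn * tf$tx_px + cs * tf$ty_px) / tf$scale)
}

## bilinear lookup of img at (xs, ys); out-of-bounds -> fill, valid flag
sample_bilinear <- function(img, xs, ys, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  valid <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); y0 <- pmin(floor(ys), ny - 1L)
  fx <- xs - x0; fy <- ys - y0
  i00 <- x0 + (y0 - 1) * nx
  v <- (img[i00]          * (1 - fx) + img[i00 + 1]      * fx) * (1 - fy) +
       (img[i00 + nx]     * (1 - fx) + img[i00 + nx + 1] * fx) * fy
  v[!valid] <- fill
  list(values = v, valid = valid)
}

## resample a moving-frame raster into the fixed frame under `tf`
## (moving -> fixed); for each fixed pixel, look up moving at T^-1(x)
resample_to_fixed <- function(moving, tf, fixed_dim = dim(moving), fill = 0) {
  g <- coord_grids(fixed_dim)
  ctr <- (fixed_dim[1:2] + 1) / 2
  inv <- invert_transform(tf)
  p <- transform_points(inv, g$x, g$y, ctr)
  s <- sample_bilinear(moving, p$x, p$y, fill = fill)
  out <- matrix(s$values, fixed_dim[1], fixed_dim[2])
  attr(out, "valid") <- matrix(s$valid, fixed_dim[1], fixed_dim[2])
  out
}

## synthesize the moving image of a fixed-frame scene: moving(x) = scene(T(x))
warp_from_fixed <- function(scene, tf, fill = 0) {
  dm <- dim(scene)
  g <- coord_grids(dm)
  ctr <- (dm + 1) / 2
  p <- transform_points(tf, g$x, g$y, ctr)
  matrix(sample_bilinear(scene, p$x, p$y, fill = fill)$values, dm[1], dm[2])
}

## mean-squared grayscale difference between fixed and the warped moving
## image, over pixels where the moving lookup is in-bounds; a coverage
## penalty keeps the optimizer from "explaining" the image away.
## Hot path of the optimizer: the inverse mapping and the bilinear gather
## are inlined and restricted to in-bounds pixels.
msd_criterion <- function(par, moving, fixed, ctr) {
  s <- par[1]
  if (!is.finite(s) || s < 0.2 || s > 5) return(1e9)
  th <- par[2] * pi / 180
  cs <- cos(th) / s; sn <- sin(th) / s
  g <- attr(fixed, "grids")
  dx <- g$x - (ctr[1] + par[3]); dy <- g$y - (ctr[2] + par[4])
  xs <- cs * dx + sn * dy + ctr[1]
  ys <- cs * dy - sn * dx + ctr[2]
  nx <- nrow(moving); ny <- ncol(moving)
  ok <- which(xs >= 1 & xs < nx & ys >= 1 & ys < ny)
  nvalid <- length(ok)
  if (nvalid < 16) return(1e9)
  xs <- xs[ok]; ys <- ys[ok]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  i00 <- x0 + (y0 - 1) * nx
  v <- (moving[i00] * (1 - fx) + moving[i00 + 1] * fx) * (1 - fy) +
       (moving[i00 + nx] * (1 - fx) + moving[i00 + nx + 1] * fx) * fy
  d <- v - fixed[ok]
  msd <- sum(d * d) / nvalid
  cover <- nvalid / length(fixed)
  msd + 1e4 * max(0, 0.5 - cover)^2
}

downsample2 <- function(img) {
  nx <- 2 * (nrow(img) %/% 2); ny <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(nx), seq_len(ny)]
  (img[seq(1, nx, 2), seq(1, ny, 2)] + img[seq(2, nx, 2), seq(1, ny, 2)] +
   img[seq(1, nx, 2), seq(2, ny, 2)] + img[seq(2, nx, 2), seq(2, ny, 2)]) / 4
}

#' Register a stained section to its H&E reference (similarity transform)
#'
#' Estimates the scale/rotation/translation mapping `moving` onto `fixed`
#' by minimizing the mean-squared grayscale intensity difference with a
#' multi-resolution pyramid (Nelder-Mead at each level, coarse-to-fine).
#' Suited to serial sections, where the misalignment is small.
#'
#' @param moving,fixed `stain_image`s (or grayscale matrices) with
#'   overlapping content.
#' @param levels downsampling factors of the pyramid, coarse to fine.
#'   The default `c(4, 2, 1)` refines down to full resolution;
#'   `c(4, 2)` is a faster profile adequate for mask arithmetic.
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @param tol convergence tolerance at which the result is considered
#'   converged (relative decrease of the criterion at the finest level).
#' @param rot_grid rotation starts (degrees) tried at the coarsest level;
#'   near-elliptical tissue makes rotation multimodal, so several starts
#'   are searched and the best is refined.
#' @return the estimated `similarity_transform`, with attributes
#'   `criterion` (final mean-squared difference) and `converged`.
#'   Non-convergence is flagged, never silently replaced by identity.
#' @export
register_similarity <- function(moving, fixed, levels = c(4, 2, 1),
                                maxit = c(150, 150, 150), tol = 1e-9,
                                rot_grid = seq(-9, 9, by = 3)) {
  gm <- to_grayscale(moving); gf <- to_grayscale(fixed)
  maxit <- rep_len(maxit, length(levels))
  ## build pyramids by factor-2 block averaging
  pyr_m <- list(gm); pyr_f <- list(gf)
  fmax <- max(levels)
  f <- 1
  while (f < fmax) {
    pyr_m <- c(pyr_m, list(downsample2(pyr_m[[length(pyr_m)]])))
    pyr_f <- c(pyr_f, list(downsample2(pyr_f[[length(pyr_f)]])))
    f <- f * 2
  }
  par <- c(1, 0, 0, 0)
  conv <- FALSE; val <- NA_real_
  for (k in seq_along(levels)) {
    lev <- levels[k]
    li <- as.integer(log2(lev)) + 1L
    m <- pyr_m[[li]]; fx <- pyr_f[[li]]
    attr(fx, "grids") <- coord_grids(dim(fx))
    ctr <- (dim(fx) + 1) / 2
    ps <- c(0.02, 2, max(2 / lev, 0.5), max(2 / lev, 0.5))
    nm <- function(p0, it) optim(p0, msd_criterion, moving = m, fixed = fx,
                                 ctr = ctr, method = "Nelder-Mead",
                                 control = list(maxit = it, reltol = 1e-12,
                                                parscale = ps))
    if (k == 1) {
      ## rotation has shallow local minima on near-elliptical tissue:
      ## seed the coarsest level from a grid of rotation starts
      best <- NULL
      for (r0 in rot_grid) {
        o <- nm(c(1, r0, 0, 0), maxit[k])
        if (is.null(best) || o$value < best$value) best <- o
      }
      o <- nm(best$par, maxit[k])   # polish the winner
    } else {
      o <- nm(c(par[1], par[2], par[3] / lev, par[4] / lev), maxit[k])
    }
    if (k == length(levels)) {
      ## confirmation run: converged when a restart no longer improves
      o2 <- nm(o$par, 60)
      conv <- o2$convergence == 0 ||
        abs(o$value - o2$value) <= max(tol, 1e-5 * max(o$value, 1e-12))
      o <- o2
    }
    val <- o$value
    par <- c(o$par[1], o$par[2], o$par[3] * lev, o$par[4] * lev)
  }
  tf <- similarity_transform(par[1], par[2], par[3], par[4])
  attr(tf, "criterion") <- val
  attr(tf, "converged") <- conv
  tf
}
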