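#' Rolling-ball background subtraction
#'
#' Subtracts, slice by slice, the morphological background estimated by a
#' grayscale opening with a non-flat ball structuring element of the given
#' radius (the exact morphological form of the classic rolling-ball filter).
#' The output never exceeds the input and is clipped at zero.
#'
#' @param stack an [image_stack].
#' @param ball_radius ball radius in voxels (default 60).
#' @return The background-subtracted [image_stack].
#' @export
subtract_background <- function(stack, ball_radius = 60) {
  assert_stack(stack)
  if (!is.numeric(ball_radius) || ball_radius < 1)
    stop("`ball_radius` must be >= 1")
  d <- dim(stack$voxels)
  if (ball_radius > d[2] && ball_radius > d[3])
    stop("ball_radius larger than both slice dimensions")
  out <- stack$voxels
  for (k in seq_len(d[1])) {
    sl <- matrix(stack$voxels[k, , ], d[2], d[3])
    bg <- cpp_ball_opening2d(sl, as.integer(ball_radius))
    res <- sl - bg
    res[res < 0] <- 0
    out[k, , ] <- res
  }
  image_stack(out, stack$pitch_xy, stack$pitch_z, stack$bit_depth)
}

#' Rescale a stack along z to isotropic voxels
#'
#' Multiplies the z dimension by an integer factor using linear interpolation
#' between slices. Output slice `k` (1-based) samples the input at position
#' `1 + (k - 1) / factor`; positions beyond the last input slice replicate
#' it. The axial pitch becomes `pitch_z / factor`, so a stack with 4:1
#' anisotropy (e.g. 2.616 um z, 0.654 um xy) and factor 4 becomes isotropic
#' at 0.654 um.
#'
#' @param stack an [image_stack].
#' @param factor integer rescale factor >= 1.
#' @return The rescaled [image_stack].
#' @export
rescale_z <- function(stack, factor = 4) {
  assert_stack(stack)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be an integer >= 1")
  factor <- as.integer(factor)
  ratio <- stack$pitch_z / stack$pitch_xy
  if (abs(ratio - factor) / factor > 0.1)
    warning(sprintf(
      "pitch_z / pitch_xy = %.3g does not match the rescale factor %d",
      ratio, factor))
  d <- dim(stack$voxels)
  nz_out <- d[1] * factor
  pos <- 1 + (seq_len(nz_out) - 1) / factor
  i0 <- pmin(floor(pos), d[1])
  i1 <- pmin(i0 + 1, d[1])
  w <- pos - floor(pos)
  out <- array(0, c(nz_out, d[2], d[3]))
  for (k in seq_len(nz_out)) {
    out[k, , ] <- (1 - w[k]) * stack$voxels[i0[k], , ] +
      w[k] * stack$voxels[i1[k], , ]
  }
  image_stack(out, stack$pitch_xy, stack$pitch_z / factor, stack$bit_depth)
}

#' Rotational maximum-intensity projection series
#'
#' "Brightest point" projections over a full 360-degree rotation about the
#' y axis. Frame `k` rotates the volume by `(k - 1) * increment` degrees in
#' the z-x plane about the volume centre (nearest-neighbour sampling, so
#' maxima are never interpolated) and takes the per-ray maximum along z.
#' Frame 1 equals the axis-aligned maximum projection exactly.
#'
#' @param stack an [image_stack] (isotropic voxels assumed).
#' @param increment angular increment in degrees; must divide 360.
#' @param axis rotation axis; only `"y"` is implemented.
#' @return A `projection_series`: list of `(y, x)` frames plus the increment.
#' @export
max_projection_series <- function(stack, increment = 10, axis = "y") {
  assert_stack(stack)
  if (!identical(axis, "y")) stop("only rotation about the y axis is supported")
  if (!is.numeric(increment) || increment <= 0 || 360 %% increment != 0)
    stop("`increment` must divide 360")
  d <- dim(stack$voxels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  nframes <- as.integer(360 / increment)
  cz <- (nz + 1) / 2
  cx <- (nx + 1) / 2
  # voxel values as an (z*x, y) matrix so each frame reduces over (z, x) bins
  vmat <- matrix(aperm(stack$voxels, c(1, 3, 2)), nz * nx, ny)
  zg <- rep(seq_len(nz), times = nx)
  xg <- rep(seq_len(nx), each = nz)
  frames <- vector("list", nframes)
  for (k in seq_len(nframes)) {
    theta <- (k - 1) * increment * pi / 180
    if (k == 1L) {
      frames[[1]] <- apply(stack$voxels, c(2, 3), max)
      next
    }
    # forward map: lateral position of every voxel in the rotated view
    xr <- round(cx + (xg - cx) * cos(theta) + (zg - cz) * sin(theta))
    acc <- matrix(0, ny, nx)
    for (col in unique(xr)) {
      if (col < 1 || col > nx) next
      sel <- xr == col
      acc[, col] <- if (sum(sel) == 1L) vmat[sel, ]
                    else apply(vmat[sel, , drop = FALSE], 2, max)
    }
    frames[[k]] <- acc
  }
  structure(list(frames = frames, increment = increment, axis = axis),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("<projection_series> %d frames, %g deg increment, axis %s\n",
              length(x$frames), x$increment, x$axis))
  invisible(x)
}

#' Write a projection series as a multi-page TIFF
#'
#' @param series a `projection_series` from [max_projection_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_series <- function(series, path) {
  if (!inherits(series, "projection_series"))
    stop("expected a `projection_series`")
  d <- dim(series$frames[[1]])
  vox <- array(0, c(length(series$frames), d[1], d[2]))
  for (k in seq_along(series$frames)) vox[k, , ] <- series$frames[[k]]
  write_stack(image_stack(vox, 1, 1), path)
}
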