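#' 3D image stack with voxel pitch
#'
#' The basic currency of the package: a 3D intensity array ordered `(z, y, x)`
#' (axial axis slowest-varying conceptually, first array dimension) plus the
#' lateral and axial voxel pitch in micrometres per voxel.
#'
#' @param voxels 3D numeric array, dimensions `(z, y, x)`, non-negative.
#' @param pitch_xy lateral voxel pitch in micrometres (> 0).
#' @param pitch_z axial voxel pitch in micrometres (> 0).
#' @param bit_depth integer bit depth of the source data (8 or 16) or
#'   `"float"` for in-memory floating point volumes.
#'
#' @return An object of class `image_stack`.
#' @export
#' @examples
#' s <- image_stack(array(0, c(2, 4, 4)), pitch_xy = 0.654, pitch_z = 2.616)
#' dim(s$voxels)
image_stack <- function(voxels, pitch_xy, pitch_z, bit_depth = "float") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array ordered (z, y, x)")
  if (any(dim(voxels) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(pitch_xy) || length(pitch_xy) != 1L || !is.finite(pitch_xy) ||
      pitch_xy <= 0)
    stop("`pitch_xy` must be a single finite positive number")
  if (!is.numeric(pitch_z) || length(pitch_z) != 1L || !is.finite(pitch_z) ||
      pitch_z <= 0)
    stop("`pitch_z` must be a single finite positive number")
  if (anyNA(voxels)) stop("`voxels` must not contain missing values")
  if (min(voxels) < 0)
    stop("signed/negative intensities are rejected; stacks must be non-negative")
  structure(
    list(voxels = voxels, pitch_xy = pitch_xy, pitch_z = pitch_z,
         bit_depth = bit_depth),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d (z, y, x), pitch %.4g x %.4g um (xy, z), %s\n",
    d[1], d[2], d[3], x$pitch_xy, x$pitch_z,
    if (identical(x$bit_depth, "float")) "float" else paste0(x$bit_depth, "-bit")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

is_image_stack <- function(x) inherits(x, "image_stack")

assert_stack <- function(x) {
  if (!is_image_stack(x)) stop("expected an `image_stack` object")
  invisible(x)
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages map to z-slices; each page is a `(y, x)` matrix. Integer TIFFs are
#' read at their native scale (e.g. 0..65535 for 16-bit).
#'
#' @param path path to a single- or multi-page grayscale TIFF file.
#' @param pitch_xy,pitch_z voxel pitch in micrometres.
#' @return An [image_stack] with `z` equal to the page count.
#' @export
read_stack <- function(path, pitch_xy, pitch_z) {
  if (!file.exists(path)) stop("missing file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("not a readable TIFF payload: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("only single-channel grayscale TIFF pages are supported")
  d <- dim(pages[[1]])
  if (any(d == 0L)) stop("zero-sized TIFF pages")
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages differ in shape")
  vox <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  bd <- attr(pages[[1]], "bits.per.sample")
  image_stack(vox, pitch_xy, pitch_z,
              bit_depth = if (is.null(bd)) "float" else as.integer(bd))
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded and clamped to the 16-bit unsigned range, the
#' canonical on-disk dialect. `write_stack()` followed by [read_stack()] is a
#' voxelwise identity for integer stacks within 0..65535.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  assert_stack(stack)
  v <- round(stack$voxels)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE] / 65535)
  pages <- lapply(pages, function(p) {
    if (is.null(dim(p))) dim(p) <- dim(v)[2:3]
    p
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write TIFF: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Crop a stack to a sub-block
#'
#' @param stack an [image_stack].
#' @param z,y,x integer index ranges (1-based, within the stack).
#' @return The cropped [image_stack]; pitches are unchanged.
#' @export
crop <- function(stack, z = NULL, y = NULL, x = NULL) {
  assert_stack(stack)
  d <- dim(stack$voxels)
  rng <- list(z = z, y = y, x = x)
  for (i in 1:3) {
    if (is.null(rng[[i]])) rng[[i]] <- seq_len(d[i])
    r <- rng[[i]]
    if (length(r) == 0L) stop("empty crop bounds for axis ", names(rng)[i])
    if (any(r != as.integer(r)) || min(r) < 1L || max(r) > d[i])
      stop("crop bounds out of range for axis ", names(rng)[i])
    rng[[i]] <- as.integer(r)
  }
  image_stack(stack$voxels[rng$z, rng$y, rng$x, drop = FALSE],
              stack$pitch_xy, stack$pitch_z, stack$bit_depth)
}
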