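#' 3D median filter
#'
#' Replaces each voxel by the median of its cubic neighbourhood; for the
#' default range 3 the window is the 3x3x3 cube (half-width
#' `floor(range / 2)`). Borders are handled by symmetric reflection.
#'
#' @param stack an [image_stack] or 3D array.
#' @param range filter range in voxels (>= 1).
#' @return Same type as the input, filtered.
#' @export
median_filter3d <- function(stack, range = 3) {
  if (!is.numeric(range) || range < 1) stop("`range` must be >= 1")
  arr <- if (is_image_stack(stack)) stack$voxels else stack
  if (!is.array(arr) || length(dim(arr)) != 3L) stop("expected a 3D array")
  h <- as.integer(floor(range / 2))
  out <- arr
  if (h > 0) {
    out <- array(cpp_median_filter3d(as.numeric(arr), dim(arr), h), dim(arr))
  }
  if (is_image_stack(stack))
    image_stack(out, stack$pitch_xy, stack$pitch_z, stack$bit_depth)
  else out
}

#' Local-mean threshold
#'
#' A voxel is foreground iff its intensity is strictly greater than the
#' arithmetic mean over the cubic window of the given radius centred on it
#' (reflected borders). The strictly-greater rule means a constant stack
#' yields an all-background mask.
#'
#' @param stack an [image_stack] or 3D array.
#' @param range window radius in voxels (default 10, i.e. a 21^3 window).
#' @return A logical 3D array (`TRUE` = foreground).
#' @export
local_threshold <- function(stack, range = 10) {
  if (!is.numeric(range) || range < 1) stop("`range` must be >= 1")
  arr <- if (is_image_stack(stack)) stack$voxels else stack
  if (!is.array(arr) || length(dim(arr)) != 3L) stop("expected a 3D array")
  m <- array(cpp_box_mean3d(as.numeric(arr), dim(arr), as.integer(range)),
             dim(arr))
  arr > m
}

#' Multiscale Laplacian-of-Gaussian seed detection
#'
#' Computes the scale-normalised Laplacian-of-Gaussian response at
#' `n_scales` scales whose blob-diameter equivalents are evenly spaced in
#' `[range_min, range_max]` (sigma = D / (2 sqrt(3)), the scale at which the
#' 3D response of a ball of diameter D peaks). The response is the negated
#' discrete Laplacian of the Gaussian-smoothed volume times sigma^2, so
#' bright blobs give positive responses. Seeds are strict local maxima over
#' the joint 3D + scale neighbourhood with response at least
#' `response_threshold` times the global maximum response.
#'
#' @param stack an [image_stack] or 3D array.
#' @param range_min,range_max blob diameter range in voxels.
#' @param n_scales number of scales.
#' @param response_threshold relative response threshold in (0, 1].
#' @return A `seed_set`: list with `points` (n x 3 matrix of 1-based
#'   `(z, y, x)` indices), `scales` (blob diameter per seed, voxels) and
#'   `responses`.
#' @export
detect_seeds_log <- function(stack, range_min = 8, range_max = 12,
                             n_scales = 5, response_threshold = 0.1) {
  arr <- if (is_image_stack(stack)) stack$voxels else stack
  if (!is.array(arr) || length(dim(arr)) != 3L) stop("expected a 3D array")
  if (length(arr) == 0L) stop("empty stack")
  if (range_min >= range_max) stop("range_min < range_max required")
  d <- dim(arr)
  diameters <- seq(range_min, range_max, length.out = n_scales)
  sigmas <- diameters / (2 * sqrt(3))
  empty <- list(points = matrix(integer(0), 0, 3,
                                dimnames = list(NULL, c("z", "y", "x"))),
                scales = numeric(0), responses = numeric(0))
  class(empty) <- "seed_set"
  if (max(arr) == min(arr)) return(empty)
  resp <- array(0, c(n_scales, d))
  for (s in seq_len(n_scales)) {
    sm <- gaussian_blur3d(arr, sigmas[s])
    resp[s, , , ] <- sigmas[s]^2 * neg_laplacian3d(sm)
  }
  thr <- response_threshold * max(resp)
  if (thr <= 0) return(empty)
  found <- cpp_scale_maxima(as.numeric(resp), c(n_scales, d), thr)
  pts <- found$points
  if (nrow(pts) == 0L) return(empty)
  out <- list(points = pts[, 2:4, drop = FALSE],
              scales = diameters[pts[, 1]],
              responses = as.numeric(found$values))
  colnames(out$points) <- c("z", "y", "x")
  class(out) <- "seed_set"
  out
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds, diameters %s\n", nrow(x$points),
              paste(format(sort(unique(x$scales))), collapse = ", ")))
  invisible(x)
}

# separable Gaussian smoothing, sigma in voxels, truncated at 4 sigma
gaussian_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  v <- as.numeric(arr)
  for (axis in 0:2) v <- cpp_conv_axis(v, d, k, axis)
  array(v, d)
}

# negated 6-neighbour discrete Laplacian (positive on bright blobs)
neg_laplacian3d <- function(arr) {
  d <- dim(arr)
  lap <- array(0, d)
  for (axis in 1:3) {
    k <- c(1, -2, 1)
    lap <- lap + array(cpp_conv_axis(as.numeric(arr), d, k, axis - 1L), d)
  }
  -lap
}

#' Dilate seed points into watershed markers
#'
#' Each seed becomes a digital ball of the given radius (voxels at Euclidean
#' distance <= radius from the seed, clipped at the borders) carrying a
#' unique marker id (the seed's row number). Overlapping balls are an error:
#' they indicate a seeding failure that would otherwise corrupt counts.
#'
#' @param seeds a `seed_set` or an n x 3 matrix of 1-based `(z, y, x)` indices.
#' @param radius dilation radius in voxels (default 3; an interior marker
#'   then has 123 voxels).
#' @param dim integer vector `(nz, ny, nx)` of the target volume.
#' @return An integer 3D marker array (0 = background).
#' @export
dilate_seeds <- function(seeds, radius = 3, dim) {
  pts <- if (inherits(seeds, "seed_set")) seeds$points else seeds
  pts <- matrix(as.integer(pts), ncol = 3)
  markers <- array(0L, dim)
  if (nrow(pts) == 0L) return(markers)
  if (any(pts < 1L) || any(pts[, 1] > dim[1]) || any(pts[, 2] > dim[2]) ||
      any(pts[, 3] > dim[3]))
    stop("seeds outside the target shape")
  if (nrow(pts) > 1L) {
    dd <- as.matrix(dist(pts))
    diag(dd) <- Inf
    bad <- which(dd < 2 * radius, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      p <- bad[1, ]
      stop(sprintf("seeds %d and %d are closer than 2 * radius (%g < %g)",
                   min(p), max(p), dd[bad[1, 1], bad[1, 2]], 2 * radius))
    }
  }
  r <- as.integer(floor(radius))
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    vz <- pts[i, 1] + off[, 1]
    vy <- pts[i, 2] + off[, 2]
    vx <- pts[i, 3] + off[, 3]
    ok <- vz >= 1 & vz <= dim[1] & vy >= 1 & vy <= dim[2] &
      vx >= 1 & vx <= dim[3]
    idx <- cbind(vz[ok], vy[ok], vx[ok])
    hit <- markers[idx]
    if (any(hit != 0L))
      stop(sprintf("dilated markers %d and %d overlap", hit[hit != 0L][1], i))
    markers[idx] <- i
  }
  markers
}

#' Marker-controlled immersion watershed
#'
#' Floods the intensity landscape from the markers (lowest intensities
#' first), restricted to the mask, with 26-connectivity. Every mask voxel
#' reachable from a marker is assigned exactly one marker's label; voxels
#' outside the mask stay 0. Equal-intensity voxels flood in FIFO order of
#' queue insertion (markers enqueued in increasing linear-index order,
#' neighbours in fixed `(dz, dy, dx)` order), making the result
#' bit-reproducible. To segment bright nuclei, pass the inverted intensity
#' (see [segment_nuclei()]).
#'
#' @param stack an [image_stack] or 3D array: the landscape to flood.
#' @param markers integer 3D array of marker labels (0 = background).
#' @param mask logical 3D array restricting the flood.
#' @return An integer 3D label array.
#' @export
watershed_segment <- function(stack, markers, mask) {
  arr <- if (is_image_stack(stack)) stack$voxels else stack
  if (!identical(dim(arr), dim(markers)) || !identical(dim(arr), dim(mask)))
    stop("stack, markers and mask must share one shape")
  lab <- cpp_watershed(as.numeric(arr), as.integer(markers),
                       as.integer(mask), dim(arr))
  array(lab, dim(arr))
}

#' Volume gate for label maps
#'
#' Keeps regions with `vmin < volume < vmax` (both bounds strict: regions of
#' exactly `vmin` or `vmax` voxels are rejected). Survivors are relabelled
#' 1..K preserving the original label order, and feature records are
#' computed for survivors only.
#'
#' @param labels integer 3D label array.
#' @param vmin,vmax strict volume bounds in voxels.
#' @param intensity optional intensity array for `mean_intensity`.
#' @param pitch_xy,pitch_z voxel pitch for physical volumes.
#' @return A list with `labels` (relabelled array) and `records`
#'   (data frame, see [nucleus_records()]).
#' @export
filter_by_volume <- function(labels, vmin = 500, vmax = 18000,
                             intensity = NULL, pitch_xy = 1,
                             pitch_z = pitch_xy) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L)
    return(list(labels = array(0L, dim(labels)),
                records = nucleus_records(array(0L, dim(labels)))))
  vol <- table(factor(as.integer(labels[labels > 0]), levels = ids))
  keep <- ids[vol > vmin & vol < vmax]
  lut <- integer(max(ids) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  out <- array(lut[as.integer(labels) + 1L], dim(labels))
  list(labels = out,
       records = nucleus_records(out, intensity, pitch_xy, pitch_z))
}

#' Segment nuclei in an isotropic stack
#'
#' The full segmentation chain: 3D median filter, local-mean threshold,
#' multiscale Laplacian-of-Gaussian seed detection, marker dilation,
#' marker-controlled immersion watershed of the inverted median-filtered
#' intensity restricted to the foreground mask, and the strict volume gate.
#' Seeds falling outside the foreground mask are discarded and the dilated
#' markers are clipped to the mask, so the watershed precondition
#' (markers within mask) holds by construction. Deterministic for a fixed
#' input.
#'
#' @param stack an [image_stack] with isotropic voxels (after [rescale_z()]).
#' @param config a [pipeline_config()].
#' @return A list with `labels` (integer 3D array), `records` (feature data
#'   frame) and `seeds` (the detected `seed_set`).
#' @export
segment_nuclei <- function(stack, config = pipeline_config()) {
  assert_stack(stack)
  if (abs(stack$pitch_z - stack$pitch_xy) / stack$pitch_xy > 1e-6)
    warning("stack is not isotropic; run rescale_z() first")
  med <- median_filter3d(stack$voxels, config$median_range)
  mask <- local_threshold(med, config$local_threshold_range)
  empty <- list(labels = array(0L, dim(stack$voxels)),
                records = nucleus_records(array(0L, dim(stack$voxels))),
                seeds = NULL)
  if (!any(mask)) return(empty)
  seeds <- detect_seeds_log(med, config$log_range_min, config$log_range_max,
                            n_scales = config$log_n_scales,
                            response_threshold = config$seed_response_threshold)
  if (nrow(seeds$points) > 0L) {
    inside <- mask[seeds$points]
    seeds$points <- seeds$points[inside, , drop = FALSE]
    seeds$scales <- seeds$scales[inside]
    seeds$responses <- seeds$responses[inside]
  }
  if (nrow(seeds$points) == 0L) {
    empty$seeds <- seeds
    return(empty)
  }
  markers <- dilate_seeds(seeds, config$dilation_radius, dim(stack$voxels))
  markers[!mask] <- 0L
  lab <- watershed_segment(-med, markers, mask)
  gated <- filter_by_volume(lab, config$volume_min, config$volume_max,
                            intensity = stack$voxels,
                            pitch_xy = stack$pitch_xy,
                            pitch_z = stack$pitch_z)
  list(labels = gated$labels, records = gated$records, seeds = seeds)
}
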