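# run code with a private RNG state seeded from `seed`
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bead phantom specification
#'
#' Describes a stack of sub-resolution fluorescent beads: each bead is a
#' point source convolved with an anisotropic Gaussian PSF. The defaults
#' emulate 0.5 um beads imaged with a detection lens of moderate numerical
#' aperture: lateral PSF sigma 0.6 um, axial sigma 1.8 um, on a grid with
#' 0.654 um lateral and 1.308 um axial pitch.
#'
#' @param n_beads number of beads (default 10, the per-condition bead count
#'   of the resolution assay).
#' @param bead_diameter physical bead diameter in um (default 0.5;
#'   sub-resolution, so the rendered spot is the PSF itself).
#' @param psf_sigma_lateral,psf_sigma_axial PSF Gaussian sigmas in um;
#'   `psf_sigma_axial >= psf_sigma_lateral > 0`.
#' @param amplitude peak intensity of one bead above background.
#' @param background constant background offset.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param shape stack shape `(nz, ny, nx)`.
#' @param pitch_xy,pitch_z voxel pitch in um.
#' @param seed integer random seed.
#' @return A `bead_phantom_spec` (named list).
#' @export
bead_phantom_spec <- function(n_beads = 10, bead_diameter = 0.5,
                              psf_sigma_lateral = 0.6, psf_sigma_axial = 1.8,
                              amplitude = 200, background = 10, noise_sd = 2,
                              shape = c(48, 96, 96), pitch_xy = 0.654,
                              pitch_z = 1.308, seed = 1L) {
  if (psf_sigma_lateral <= 0 || psf_sigma_axial < psf_sigma_lateral)
    stop("require psf_sigma_axial >= psf_sigma_lateral > 0")
  if (n_beads < 0) stop("n_beads must be >= 0")
  if (length(shape) != 3L || any(shape < 1)) stop("invalid stack shape")
  structure(list(n_beads = as.integer(n_beads), bead_diameter = bead_diameter,
                 psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 shape = as.integer(shape), pitch_xy = pitch_xy,
                 pitch_z = pitch_z, seed = as.integer(seed)),
            class = "bead_phantom_spec")
}

#' Generate a bead phantom stack
#'
#' Renders each bead as an anisotropic Gaussian spot (point source convolved
#' with the PSF) at a random position, then adds Gaussian noise. Bead
#' positions keep a 3-sigma margin from the stack faces and a pairwise
#' separation of at least 6 times the axial sigma; explicit `centres` that
#' violate the separation are an error. The same seed always yields the
#' identical stack.
#'
#' @param spec a [bead_phantom_spec()].
#' @param centres optional n x 3 matrix of bead centres in fractional
#'   1-based voxel coordinates `(z, y, x)`; if `NULL`, positions are drawn.
#' @return A list with `stack` (an [image_stack]) and `centres` (n x 3
#'   matrix of true centres, fractional 1-based voxel coordinates).
#' @export
generate_bead_stack <- function(spec, centres = NULL) {
  stopifnot(inherits(spec, "bead_phantom_spec"))
  d <- spec$shape
  sz <- spec$psf_sigma_axial / spec$pitch_z      # sigmas in voxels
  sl <- spec$psf_sigma_lateral / spec$pitch_xy
  margin <- c(3 * sz, 3 * sl, 3 * sl) + 1
  min_sep_um <- 6 * spec$psf_sigma_axial
  if (is.null(centres)) {
    centres <- with_local_seed(spec$seed, {
      out <- matrix(0, 0, 3)
      attempts <- 0L
      while (nrow(out) < spec$n_beads) {
        if (attempts > 1000L * max(spec$n_beads, 1L))
          stop("could not place ", spec$n_beads, " beads; placed ", nrow(out))
        attempts <- attempts + 1L
        cand <- c(runif(1, 1 + margin[1], d[1] - margin[1]),
                  runif(1, 1 + margin[2], d[2] - margin[2]),
                  runif(1, 1 + margin[3], d[3] - margin[3]))
        if (nrow(out) > 0L) {
          dz <- (out[, 1] - cand[1]) * spec$pitch_z
          dy <- (out[, 2] - cand[2]) * spec$pitch_xy
          dx <- (out[, 3] - cand[3]) * spec$pitch_xy
          if (min(sqrt(dz^2 + dy^2 + dx^2)) < min_sep_um) next
        }
        out <- rbind(out, cand)
      }
      out
    })
  } else {
    centres <- matrix(as.numeric(centres), ncol = 3)
    if (nrow(centres) > 1L) {
      sc <- sweep(centres, 2, c(spec$pitch_z, spec$pitch_xy, spec$pitch_xy),
                  "*")
      dd <- as.matrix(dist(sc))
      diag(dd) <- Inf
      if (min(dd) < min_sep_um)
        stop("beads overlap within 3 sigma (separation < ", min_sep_um, " um)")
    }
  }
  rownames(centres) <- NULL
  colnames(centres) <- c("z", "y", "x")
  vox <- array(spec$background, d)
  for (i in seq_len(nrow(centres))) {
    cz <- centres[i, 1]; cy <- centres[i, 2]; cx <- centres[i, 3]
    rz <- max(1, ceiling(cz - 4 * sz)):min(d[1], floor(cz + 4 * sz))
    ry <- max(1, ceiling(cy - 4 * sl)):min(d[2], floor(cy + 4 * sl))
    rx <- max(1, ceiling(cx - 4 * sl)):min(d[3], floor(cx + 4 * sl))
    gz <- exp(-((rz - cz)^2) / (2 * sz^2))
    gy <- exp(-((ry - cy)^2) / (2 * sl^2))
    gx <- exp(-((rx - cx)^2) / (2 * sl^2))
    vox[rz, ry, rx] <- vox[rz, ry, rx] +
      spec$amplitude * outer(outer(gz, gy), gx)
  }
  if (spec$noise_sd > 0) {
    vox <- vox + with_local_seed(spec$seed + 1L,
                                 array(rnorm(length(vox), 0, spec$noise_sd), d))
    vox[vox < 0] <- 0
  }
  list(stack = image_stack(vox, spec$pitch_xy, spec$pitch_z),
       centres = centres)
}

#' Organoid phantom specification
#'
#' Describes a hollow-monolayer organoid: axis-aligned ellipsoidal nuclei
#' whose centres lie on a spherical shell around an empty lumen, rendered
#' with a 4:1 axial:lateral voxel anisotropy and a constant background
#' offset. The default nucleus (semi-axes 5.2 x 4.3 x 4.3 um) occupies about
#' 1440 isotropic 0.654 um voxels, strictly inside the (500, 18000) volume
#' gate, so pipeline recall is attributable to segmentation rather than
#' gating.
#'
#' @param shell_radius radius of the nucleus-centre shell, um.
#' @param shell_thickness radial jitter band of the monolayer, um.
#' @param n_nuclei number of nuclei.
#' @param nucleus_semi_axes ellipsoid semi-axes `(z, y, x)` in um.
#' @param nucleus_intensity intensity added inside nuclei.
#' @param lumen_intensity intensity of the lumen interior (approximately the
#'   background).
#' @param background constant background offset.
#' @param noise_sd additive Gaussian noise SD.
#' @param psf_sigma_lateral,psf_sigma_axial rendering PSF sigmas, um.
#' @param shape stack shape `(nz, ny, nx)` (anisotropic grid).
#' @param pitch_xy,pitch_z voxel pitch, um (default 0.654 and 2.616, the 4:1
#'   anisotropic grid that [rescale_z()] maps to isotropic 0.654 um voxels).
#' @param seed integer random seed.
#' @return An `organoid_phantom_spec` (named list).
#' @export
organoid_phantom_spec <- function(shell_radius = 30, shell_thickness = 2,
                                  n_nuclei = 50,
                                  nucleus_semi_axes = c(5.2, 4.3, 4.3),
                                  nucleus_intensity = 120,
                                  lumen_intensity = 10, background = 10,
                                  noise_sd = 6, psf_sigma_lateral = 0.5,
                                  psf_sigma_axial = 1.0,
                                  shape = c(32, 128, 128), pitch_xy = 0.654,
                                  pitch_z = 2.616, seed = 1L) {
  if (length(nucleus_semi_axes) != 3L || any(nucleus_semi_axes <= 0))
    stop("nucleus_semi_axes must be 3 positive lengths")
  if (shell_radius <= 0 || shell_thickness < 0) stop("invalid shell geometry")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  structure(list(shell_radius = shell_radius,
                 shell_thickness = shell_thickness,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_semi_axes = nucleus_semi_axes,
                 nucleus_intensity = nucleus_intensity,
                 lumen_intensity = lumen_intensity, background = background,
                 noise_sd = noise_sd,
                 psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial,
                 shape = as.integer(shape), pitch_xy = pitch_xy,
                 pitch_z = pitch_z, seed = as.integer(seed)),
            class = "organoid_phantom_spec")
}

# near-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  k <- seq_len(n)
  zu <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - zu^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(z = zu, y = r * sin(phi), x = r * cos(phi))
}

#' Generate an organoid phantom stack with ground truth
#'
#' Places `n_nuclei` ellipsoidal nuclei on a spherical shell (golden-angle
#' spiral positions plus seeded jitter, rejection-sampled so that centre
#' distances stay above 1.2 times the nucleus extent), rasterises them into
#' a ground-truth label map on the anisotropic grid, renders the intensity
#' as background plus `nucleus_intensity` inside the ellipsoids, blurs with
#' the anisotropic Gaussian PSF and adds noise. Identical seeds give
#' identical stacks and label maps.
#'
#' @param spec an [organoid_phantom_spec()].
#' @return A list with `stack` (an [image_stack]), `truth` (integer label
#'   array on the same grid, one label per nucleus) and `centres`
#'   (n x 3 matrix, fractional 1-based voxel coordinates `(z, y, x)`).
#' @export
generate_organoid_stack <- function(spec) {
  stopifnot(inherits(spec, "organoid_phantom_spec"))
  d <- spec$shape
  pitches <- c(spec$pitch_z, spec$pitch_xy, spec$pitch_xy)
  centre_um <- (d + 1) / 2 * pitches
  min_sep <- 2.4 * max(spec$nucleus_semi_axes)
  pos <- with_local_seed(spec$seed, {
    base <- fibonacci_sphere(max(spec$n_nuclei, 1L))
    placed <- matrix(0, 0, 3)
    attempts <- 0L
    k <- 1L
    while (nrow(placed) < spec$n_nuclei) {
      if (attempts >= 10L * spec$n_nuclei)
        stop("nucleus placement failed after ", attempts,
             " attempts; placed ", nrow(placed), " of ", spec$n_nuclei)
      attempts <- attempts + 1L
      u <- base[((k - 1L) %% nrow(base)) + 1L, ]
      radius <- spec$shell_radius +
        runif(1, -spec$shell_thickness / 2, spec$shell_thickness / 2)
      cand <- centre_um + u * radius + rnorm(3, 0, 0.3)
      if (nrow(placed) == 0L || min(sqrt(rowSums(
        sweep(placed, 2, cand)^2))) >= min_sep) {
        placed <- rbind(placed, cand)
        k <- k + 1L
      }
    }
    placed
  })
  if (spec$n_nuclei == 0L) pos <- matrix(0, 0, 3)
  truth <- array(0L, d)
  vox <- array(spec$background, d)
  # lumen interior (defaults render it at the background level)
  lumen_r <- spec$shell_radius - spec$shell_thickness / 2 -
    max(spec$nucleus_semi_axes) - 0.5
  if (lumen_r > 0 && spec$lumen_intensity != spec$background) {
    gz <- (seq_len(d[1]) * pitches[1] - centre_um[1])^2
    gy <- (seq_len(d[2]) * pitches[2] - centre_um[2])^2
    gx <- (seq_len(d[3]) * pitches[3] - centre_um[3])^2
    inside <- outer(outer(gz, gy, "+"), gx, "+") < lumen_r^2
    vox[inside] <- spec$lumen_intensity
  }
  ax <- spec$nucleus_semi_axes  # (z, y, x) um
  for (i in seq_len(nrow(pos))) {
    c_um <- pos[i, ]
    rz <- max(1, floor((c_um[1] - ax[1]) / pitches[1])):
      min(d[1], ceiling((c_um[1] + ax[1]) / pitches[1]))
    ry <- max(1, floor((c_um[2] - ax[2]) / pitches[2])):
      min(d[2], ceiling((c_um[2] + ax[2]) / pitches[2]))
    rx <- max(1, floor((c_um[3] - ax[3]) / pitches[3])):
      min(d[3], ceiling((c_um[3] + ax[3]) / pitches[3]))
    qz <- ((rz * pitches[1] - c_um[1]) / ax[1])^2
    qy <- ((ry * pitches[2] - c_um[2]) / ax[2])^2
    qx <- ((rx * pitches[3] - c_um[3]) / ax[3])^2
    inside <- outer(outer(qz, qy, "+"), qx, "+") <= 1
    sub_t <- truth[rz, ry, rx, drop = FALSE]
    sub_t[inside] <- i
    truth[rz, ry, rx] <- sub_t
    sub_v <- vox[rz, ry, rx, drop = FALSE]
    sub_v[inside] <- spec$background + spec$nucleus_intensity
    vox[rz, ry, rx] <- sub_v
  }
  sig_vox <- c(spec$psf_sigma_axial / spec$pitch_z,
               spec$psf_sigma_lateral / spec$pitch_xy,
               spec$psf_sigma_lateral / spec$pitch_xy)
  for (axis in 1:3) {
    if (sig_vox[axis] > 0.05) {
      h <- max(1L, as.integer(ceiling(4 * sig_vox[axis])))
      k <- exp(-((-h:h)^2) / (2 * sig_vox[axis]^2))
      vox <- array(cpp_conv_axis(as.numeric(vox), d, k / sum(k), axis - 1L), d)
    }
  }
  if (spec$noise_sd > 0) {
    vox <- vox + with_local_seed(spec$seed + 1L,
                                 array(rnorm(length(vox), 0, spec$noise_sd), d))
    vox[vox < 0] <- 0
  }
  centres_vox <- sweep(pos, 2, pitches, "/")
  colnames(centres_vox) <- c("z", "y", "x")
  rownames(centres_vox) <- NULL
  list(stack = image_stack(vox, spec$pitch_xy, spec$pitch_z),
       truth = truth, centres = centres_vox)
}

#' Match two centroid sets one-to-one
#'
#' Greedy nearest-pair matching between reference (e.g. ground-truth) and
#' estimated centroids: repeatedly pairs the globally closest unmatched
#' reference/estimate pair while the distance is at most `max_dist`.
#'
#' @param reference,estimate matrices with one centroid per row, same
#'   coordinate convention.
#' @param max_dist maximal matching distance (same units as the coordinates).
#' @return A list with `matches` (data frame `ref`, `est`, `dist`), `recall`
#'   (matched / reference count) and `precision` (matched / estimate count).
#' @export
match_centroids <- function(reference, estimate, max_dist = 3) {
  ref <- matrix(as.numeric(as.matrix(reference)), ncol = ncol(as.matrix(reference)))
  est <- matrix(as.numeric(as.matrix(estimate)), ncol = ncol(ref))
  nr <- nrow(ref); ne <- nrow(est)
  if (nr == 0L || ne == 0L)
    return(list(matches = data.frame(ref = integer(0), est = integer(0),
                                     dist = numeric(0)),
                recall = if (nr == 0L) NA_real_ else 0,
                precision = if (ne == 0L) NA_real_ else 0))
  dd <- matrix(0, nr, ne)
  for (j in seq_len(ne))
    dd[, j] <- sqrt(colSums((t(ref) - est[j, ])^2))
  matches <- data.frame(ref = integer(0), est = integer(0), dist = numeric(0))
  while (TRUE) {
    m <- which.min(dd)
    if (!length(m) || !is.finite(dd[m]) || dd[m] > max_dist) break
    i <- as.integer(((m - 1) %% nr) + 1)
    j <- as.integer(((m - 1) %/% nr) + 1)
    matches <- rbind(matches,
                     data.frame(ref = i, est = j, dist = dd[m]))
    dd[i, ] <- Inf
    dd[, j] <- Inf
  }
  list(matches = matches, recall = nrow(matches) / nr,
       precision = nrow(matches) / ne)
}
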