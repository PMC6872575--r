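FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # FWHM = 2 sqrt(2 ln 2) sigma

#' Extract a line intensity profile through a bead
#'
#' Samples the stack along the lateral axis (`direction = "lateral"`, the
#' x axis of the xy plane) or along the optical axis (`direction = "axial"`,
#' the z axis) through the bead centre. The abscissa is physical (um, using
#' the relevant pitch) and the profile is normalised by its maximum.
#'
#' @param stack an [image_stack].
#' @param centre bead centre `(z, y, x)` in 1-based voxel coordinates
#'   (fractional values are rounded to the nearest voxel).
#' @param direction `"lateral"` (alias `"xy"`) or `"axial"` (alias `"yz"`).
#' @param half_length half profile length in voxels (clipped at the stack).
#' @return A data frame with `position_um` (0 at the centre voxel) and
#'   `intensity` (max-normalised).
#' @export
extract_profile <- function(stack, centre, direction = c("lateral", "axial",
                                                         "xy", "yz"),
                            half_length = 15) {
  assert_stack(stack)
  direction <- match.arg(direction)
  direction <- switch(direction, xy = "lateral", yz = "axial", direction)
  d <- dim(stack$voxels)
  c0 <- round(as.numeric(centre))
  if (length(c0) != 3L || any(c0 < 1L) || any(c0 > d))
    stop("bead centre outside the stack")
  if (direction == "lateral") {
    rng <- max(1, c0[3] - half_length):min(d[3], c0[3] + half_length)
    vals <- stack$voxels[c0[1], c0[2], rng]
    pos <- (rng - c0[3]) * stack$pitch_xy
  } else {
    rng <- max(1, c0[1] - half_length):min(d[1], c0[1] + half_length)
    vals <- stack$voxels[rng, c0[2], c0[3]]
    pos <- (rng - c0[1]) * stack$pitch_z
  }
  data.frame(position_um = pos, intensity = vals / max(vals))
}

#' Fit a Gaussian to a line profile
#'
#' Least-squares (Levenberg-Marquardt) fit of
#' `A * exp(-(x - mu)^2 / (2 sigma^2)) + b` to a bead intensity profile.
#' Two starting widths are tried -- the profile's second moment and its
#' half-maximum width -- and the converged fit with the lower residual is
#' kept; fits that collapse sigma onto a single sample are rejected. The
#' FWHM is derived from sigma as `2 sqrt(2 ln 2) sigma`.
#'
#' @param profile data frame with `position_um` and `intensity` (as from
#'   [extract_profile()]); at least 5 samples, non-constant.
#' @param direction optional label stored in the result.
#' @return A `bead_profile_fit`: list with `direction`, `mu`, `sigma`,
#'   `amplitude`, `offset`, `fwhm` (all in um where applicable) and `rss`.
#' @export
fit_gaussian <- function(profile, direction = NA_character_) {
  if (!is.data.frame(profile) ||
      !all(c("position_um", "intensity") %in% names(profile)))
    stop("`profile` must have columns position_um and intensity")
  x <- profile$position_um
  y <- profile$intensity
  if (length(x) < 5L) stop("need at least 5 profile samples")
  if (max(y) == min(y)) stop("constant profile cannot be fitted")
  b0 <- min(y)
  w <- pmax(y - b0, 0)
  mu0 <- sum(w * x) / sum(w)
  spacing <- min(diff(sort(unique(x))))
  # two starting widths: second moment (wide tails inflate it) and the
  # half-maximum width (robust for profiles much narrower than the window)
  s_mom <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  half_w <- sum(y - b0 >= 0.5 * (max(y) - b0)) * spacing
  s_hm <- max(half_w, spacing) / (2 * sqrt(2 * log(2)))
  starts <- unique(c(s_mom, s_hm, 2 * spacing))
  starts <- starts[is.finite(starts) & starts > 0]
  fit <- NULL
  for (s0 in starts) {
    cand <- minpack.lm::nls.lm(
      par = c(A = max(y) - b0, mu = mu0, s = s0, b = b0),
      fn = function(p) y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4]),
      lower = c(1e-12, -Inf, 1e-12, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    ok <- cand$info %in% 1:4 && all(is.finite(cand$par)) &&
      cand$par["s"] > 0.05 * spacing   # reject collapse onto one sample
    if (ok && (is.null(fit) || cand$deviance < fit$deviance)) fit <- cand
  }
  if (is.null(fit))
    stop("Gaussian fit did not converge on any start; profile may be ",
         "degenerate")
  cf <- fit$par
  structure(list(direction = direction, mu = unname(cf["mu"]),
                 sigma = abs(unname(cf["s"])), amplitude = unname(cf["A"]),
                 offset = unname(cf["b"]),
                 fwhm = FWHM_FACTOR * abs(unname(cf["s"])),
                 rss = fit$deviance),
            class = "bead_profile_fit")
}

#' @export
print.bead_profile_fit <- function(x, ...) {
  cat(sprintf("<bead_profile_fit> %s: FWHM %.4g um (sigma %.4g, offset %.3g, rss %.3g)\n",
              ifelse(is.na(x$direction), "profile", x$direction),
              x$fwhm, x$sigma, x$offset, x$rss))
  invisible(x)
}

#' Measure lateral and axial FWHM for every bead in a stack
#'
#' Convenience wrapper: extracts lateral and axial profiles through each
#' centre and fits them.
#'
#' @param stack an [image_stack].
#' @param centres n x 3 matrix of bead centres (1-based voxel coordinates).
#' @param half_length profile half length in voxels.
#' @param condition condition label attached to every row.
#' @return A data frame with `condition`, `bead`, `direction`, `fwhm`,
#'   `sigma`, `mu`, `rss`.
#' @export
measure_bead_fwhm <- function(stack, centres, half_length = 15,
                              condition = "condition") {
  centres <- matrix(as.numeric(as.matrix(centres)), ncol = 3)
  rows <- list()
  for (i in seq_len(nrow(centres))) {
    for (dir in c("lateral", "axial")) {
      pr <- extract_profile(stack, centres[i, ], dir, half_length)
      ft <- fit_gaussian(pr, dir)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = condition, bead = i, direction = dir,
                   fwhm = ft$fwhm, sigma = ft$sigma, mu = ft$mu, rss = ft$rss)
    }
  }
  do.call(rbind, rows)
}

#' Summarise FWHM by condition and direction
#'
#' Mean and sample standard deviation (n - 1 denominator) of the FWHM per
#' condition/direction group, and the percent difference of every other
#' condition relative to a declared reference:
#' `(mean_ref - mean_other) / mean_ref * 100` (positive = other condition
#' smaller, i.e. better resolution).
#'
#' @param fits data frame with columns `condition`, `direction`, `fwhm`
#'   (as from [measure_bead_fwhm()]).
#' @param reference reference condition label (condition A).
#' @return A list with `summary` (condition, direction, n, mean, sd) and
#'   `comparison` (direction, condition, percent_smaller).
#' @export
summarize_fwhm <- function(fits, reference) {
  if (!all(c("condition", "direction", "fwhm") %in% names(fits)))
    stop("`fits` must have columns condition, direction, fwhm")
  if (!reference %in% fits$condition)
    stop("unknown condition label: ", reference)
  grp <- split(fits, list(fits$condition, fits$direction), drop = TRUE)
  summary <- do.call(rbind, lapply(grp, function(g) {
    data.frame(condition = g$condition[1], direction = g$direction[1],
               n = nrow(g), mean = mean(g$fwhm),
               sd = if (nrow(g) > 1L) sd(g$fwhm) else 0)
  }))
  rownames(summary) <- NULL
  others <- setdiff(unique(fits$condition), reference)
  comparison <- do.call(rbind, lapply(unique(fits$direction), function(dir) {
    ref_mean <- summary$mean[summary$condition == reference &
                               summary$direction == dir]
    do.call(rbind, lapply(others, function(cond) {
      om <- summary$mean[summary$condition == cond & summary$direction == dir]
      if (length(ref_mean) != 1L || length(om) != 1L) return(NULL)
      data.frame(direction = dir, condition = cond,
                 percent_smaller = (ref_mean - om) / ref_mean * 100)
    }))
  }))
  list(summary = summary, comparison = comparison)
}
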