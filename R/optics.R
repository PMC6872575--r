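#' Optical configuration of the cuvette wall
#'
#' Refractive indices and geometry for the planar-slab refraction model of a
#' thin container wall in the detection path: a fluorophore at the inner
#' wall surface emits through the wall (index `n_wall`, thickness `d`) into
#' the chamber immersion medium (`n_bath`); `n_inside` is the medium
#' surrounding the specimen inside the cuvette. FEP foil has
#' `n_wall` of about 1.341-1.347.
#'
#' @param n_wall wall refractive index (default 1.344).
#' @param n_inside refractive index of the medium inside the cuvette.
#' @param n_bath refractive index of the chamber immersion medium.
#' @param d wall thickness in um (default 12.4, a vacuum-formed ultra-thin
#'   foil; rigid FEP cylinders are around 400).
#' @param aperture detection numerical aperture (default 0.3).
#' @return An `optics_config` (named list).
#' @export
optics_config <- function(n_wall = 1.344, n_inside = 1.33, n_bath = 1.33,
                          d = 12.4, aperture = 0.3) {
  if (n_wall < 1 || n_inside < 1 || n_bath < 1)
    stop("refractive indices must be >= 1")
  if (d < 0) stop("wall thickness d must be >= 0")
  if (aperture <= 0 || aperture >= n_bath)
    stop("aperture must satisfy 0 < NA < n_bath")
  structure(list(n_wall = n_wall, n_inside = n_inside, n_bath = n_bath,
                 d = d, aperture = aperture),
            class = "optics_config")
}

snell <- function(n_from, n_to, sin_in, interface) {
  s <- n_from * sin_in / n_to
  if (s > 1)
    stop("total internal reflection at the ", interface, " interface")
  s
}

#' Trace one ray through the cuvette wall
#'
#' A ray leaves a fluorophore at the inner wall surface with angle of
#' incidence `alpha1` (radians, in the inside medium), refracts at the
#' inside-to-wall and wall-to-bath planar interfaces of a slab of thickness
#' `d` (Snell's law), and is traced back from the bath side to its crossing
#' of the optical axis. The returned intercept is the apparent source depth
#' behind the outer wall surface: `d * tan(alpha_wall) / tan(alpha_bath)`.
#' With matched indices the intercept equals the geometric depth `d` at any
#' angle.
#'
#' @param config an [optics_config()].
#' @param alpha1 angle of incidence in radians (0 = on axis).
#' @return Apparent axial intercept in um.
#' @export
trace_ray <- function(config, alpha1) {
  stopifnot(inherits(config, "optics_config"))
  s1 <- sin(alpha1)
  s_wall <- snell(config$n_inside, config$n_wall, s1, "inside->wall")
  s_bath <- snell(config$n_wall, config$n_bath, s_wall, "wall->bath")
  if (s_bath == 0) return(config$d * config$n_bath / config$n_wall)
  t_wall <- s_wall / sqrt(1 - s_wall^2)
  t_bath <- s_bath / sqrt(1 - s_bath^2)
  config$d * t_wall / t_bath
}

#' Wall-induced focal shift and spherical aberration
#'
#' Paraxial and marginal behaviour of the slab model: the paraxial shift is
#' the difference between the geometric wall thickness and the paraxial
#' apparent depth, `d * (1 - n_bath / n_wall)` in closed form (positive =
#' actual focal position deeper than the nominal one); the marginal
#' intercept is the apparent depth for the marginal ray of the detection
#' aperture (`sin(alpha_bath) = NA / n_bath`); and the longitudinal
#' spherical aberration is the magnitude of the marginal-minus-paraxial
#' intercept difference. All three vanish for `d = 0` or matched indices,
#' and scale linearly (hence monotonically) with `d`.
#'
#' @param config an [optics_config()].
#' @return A `ray_trace_result`: list with `paraxial_intercept`,
#'   `paraxial_shift`, `marginal_intercept` and `lsa`, all in um.
#' @export
focal_shift <- function(config) {
  stopifnot(inherits(config, "optics_config"))
  paraxial <- trace_ray(config, 0)
  # marginal ray: aperture angle in the bath mapped back to the inside medium
  sin_a1 <- config$aperture / config$n_inside
  if (sin_a1 > 1) stop("aperture not reachable from the inside medium")
  marginal <- trace_ray(config, asin(sin_a1))
  structure(list(paraxial_intercept = paraxial,
                 paraxial_shift = config$d - paraxial,
                 marginal_intercept = marginal,
                 lsa = abs(marginal - paraxial)),
            class = "ray_trace_result")
}

#' @export
print.ray_trace_result <- function(x, ...) {
  cat(sprintf(
    "<ray_trace_result> paraxial shift %.5g um, marginal intercept %.5g um, LSA %.5g um\n",
    x$paraxial_shift, x$marginal_intercept, x$lsa))
  invisible(x)
}
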