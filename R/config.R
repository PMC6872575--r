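#' Pipeline configuration
#'
#' Holds every tunable parameter of the segmentation and morphometry chain.
#' The defaults are the published parameter set for DAPI-stained organoid
#' nuclei on the isotropic 0.654 um grid: rolling-ball radius 60, axial
#' rescale factor 4, median range 3, local-threshold range 10, seed-detector
#' range 8-12 voxels, marker dilation radius 3, volume gate (500, 18000)
#' voxels (both bounds strict), alpha 240, cell-graph edge threshold 60 and
#' outlier distance 55 voxels.
#'
#' @param ball_radius rolling-ball background radius, voxels.
#' @param z_rescale_factor axial rescale factor to isotropic voxels.
#' @param target_pitch isotropic voxel pitch after rescaling, micrometres.
#' @param median_range median filter range, voxels (window width
#'   `2 * floor(range / 2) + 1`, i.e. a 3x3x3 cube for range 3).
#' @param local_threshold_range local-mean threshold window radius, voxels.
#' @param log_range_min,log_range_max blob-diameter range of the multiscale
#'   Laplacian-of-Gaussian seed detector, voxels.
#' @param dilation_radius marker dilation radius (spherical element), voxels.
#' @param volume_min,volume_max strict volume gate bounds, voxels.
#' @param alpha alpha-shape parameter, voxels.
#' @param edge_threshold cell-graph edge distance threshold, voxels.
#' @param outlier_distance cell-graph maximal outlier distance, voxels.
#' @param projection_increment angular increment for rotational maximum
#'   intensity projections, degrees.
#' @param log_n_scales number of seed-detector scales across the range.
#' @param seed_response_threshold relative response threshold for seeds
#'   (fraction of the global maximum detector response).
#' @param random_seed integer seed for any stochastic step.
#'
#' @return A `pipeline_config` object (named list).
#' @export
pipeline_config <- function(ball_radius = 60,
                            z_rescale_factor = 4,
                            target_pitch = 0.654,
                            median_range = 3,
                            local_threshold_range = 10,
                            log_range_min = 8,
                            log_range_max = 12,
                            dilation_radius = 3,
                            volume_min = 500,
                            volume_max = 18000,
                            alpha = 240,
                            edge_threshold = 60,
                            outlier_distance = 55,
                            projection_increment = 10,
                            log_n_scales = 5,
                            seed_response_threshold = 0.1,
                            random_seed = 1L) {
  cfg <- list(
    ball_radius = ball_radius, z_rescale_factor = z_rescale_factor,
    target_pitch = target_pitch, median_range = median_range,
    local_threshold_range = local_threshold_range,
    log_range_min = log_range_min, log_range_max = log_range_max,
    dilation_radius = dilation_radius, volume_min = volume_min,
    volume_max = volume_max, alpha = alpha, edge_threshold = edge_threshold,
    outlier_distance = outlier_distance,
    projection_increment = projection_increment,
    log_n_scales = log_n_scales,
    seed_response_threshold = seed_response_threshold,
    random_seed = random_seed
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num1 <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config `", name, "` must be a single finite number")
    v
  }
  pos <- c("ball_radius", "z_rescale_factor", "target_pitch", "median_range",
           "local_threshold_range", "log_range_min", "log_range_max",
           "dilation_radius", "volume_min", "volume_max", "alpha",
           "edge_threshold", "outlier_distance", "projection_increment",
           "log_n_scales", "seed_response_threshold")
  for (nm in pos) if (num1(nm) <= 0) stop("config invariant violated: ",
                                          nm, " > 0")
  if (cfg$log_range_min >= cfg$log_range_max)
    stop("config invariant violated: log_range_min < log_range_max")
  if (cfg$volume_min >= cfg$volume_max)
    stop("config invariant violated: volume_min < volume_max")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Load a pipeline configuration from a YAML-style key:value file
#'
#' Keys missing from the file take the published defaults (see
#' [pipeline_config()]); unknown keys are an error.
#'
#' @param path path to a YAML (`key: value`) configuration file.
#' @return A `pipeline_config`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("ball_radius: 30", f)
#' load_config(f)$ball_radius
load_config <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain key: value pairs")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
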