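#' Per-nucleus feature records
#'
#' Builds the per-nucleus feature table from a label map: label id, centroid
#' (1-based voxel indices, intensity-unweighted mean of member voxel indices),
#' voxel volume, physical volume and mean intensity.
#'
#' @param labels integer 3D label array (0 = background).
#' @param intensity optional numeric array of the same shape; if `NULL`,
#'   `mean_intensity` is `NA`.
#' @param pitch_xy,pitch_z voxel pitch in micrometres used for
#'   `volume_um3 = volume * pitch_xy^2 * pitch_z`.
#' @return A data frame with one row per label, ordered by ascending label,
#'   columns `label`, `centroid_z`, `centroid_y`, `centroid_x`,
#'   `volume_voxels`, `volume_um3`, `mean_intensity`.
#' @export
nucleus_records <- function(labels, intensity = NULL, pitch_xy = 1,
                            pitch_z = pitch_xy) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      volume_voxels = integer(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0)))
  }
  d <- dim(labels)
  idx <- which(labels > 0)
  lab <- as.integer(labels[idx])
  iz <- ((idx - 1L) %% d[1]) + 1L
  iy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  vol <- as.integer(table(factor(lab, levels = ids)))
  cz <- tapply(iz, factor(lab, levels = ids), mean)
  cy <- tapply(iy, factor(lab, levels = ids), mean)
  cx <- tapply(ix, factor(lab, levels = ids), mean)
  mi <- if (is.null(intensity)) rep(NA_real_, length(ids)) else
    as.numeric(tapply(intensity[idx], factor(lab, levels = ids), mean))
  data.frame(label = ids,
             centroid_z = as.numeric(cz), centroid_y = as.numeric(cy),
             centroid_x = as.numeric(cx), volume_voxels = vol,
             volume_um3 = vol * pitch_xy^2 * pitch_z,
             mean_intensity = mi)
}

#' Write a nucleus feature table to CSV
#'
#' Writes one row per record ordered by ascending label; doubles are written
#' with 17 significant digits so that re-reading reproduces the values
#' exactly. An empty record set yields a header-only file.
#'
#' @param records data frame as produced by [nucleus_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  required <- c("label", "centroid_z", "centroid_y", "centroid_x",
                "volume_voxels", "volume_um3", "mean_intensity")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    stop("`records` must contain columns: ", paste(required, collapse = ", "))
  records <- records[order(records$label), required, drop = FALSE]
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  ok <- tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
                 error = function(e) stop("unwritable path: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read a nucleus feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A data frame with the standard feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- read.csv(path)
  df$label <- as.integer(df$label)
  df$volume_voxels <- as.integer(df$volume_voxels)
  df
}
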