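#' Tau spot table
#'
#' One row per tau deposit spot (a connected suprathreshold component of
#' the Gaussian-mean difference image): unique integer label,
#' intensity-weighted centroid in physical micrometres (z, y, x), total
#' Gaussian-mean difference intensity summed over the component, voxel
#' count, and physical volume in cubic micrometres.
#'
#' @param spots data.frame with columns `label`, `z_um`, `y_um`, `x_um`,
#'   `total_intensity`, `volume_vox`, `volume_um3`. May have zero rows.
#' @param sample_id identifier string attached as an attribute.
#' @return An object of class `spot_table` (a data.frame).
#' @export
spot_table <- function(spots = NULL, sample_id = "sample") {
  cols <- c("label", "z_um", "y_um", "x_um",
            "total_intensity", "volume_vox", "volume_um3")
  if (is.null(spots)) {
    spots <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  miss <- setdiff(cols, names(spots))
  if (length(miss))
    stop("spot table missing column(s): ", paste(miss, collapse = ", "))
  spots <- as.data.frame(spots)[, cols]
  if (nrow(spots)) {
    if (anyDuplicated(spots$label)) stop("spot labels must be unique")
    if (any(spots$volume_vox < 1)) stop("volume_vox must be >= 1")
    if (any(spots$total_intensity <= 0)) stop("total_intensity must be > 0")
  }
  structure(spots, class = c("spot_table", "data.frame"),
            sample_id = sample_id)
}

#' Write / read a spot table as CSV
#'
#' CSV columns are `label, z_um, y_um, x_um, total_intensity, volume_vox,
#' volume_um3`; values round-trip to better than 6 significant digits.
#'
#' @param table a [spot_table].
#' @param path CSV path.
#' @return `write_spot_table`: `path` invisibly. `read_spot_table`: a
#'   [spot_table].
#' @export
write_spot_table <- function(table, path) {
  stopifnot(inherits(table, "spot_table"))
  df <- as.data.frame(table)
  num <- setdiff(names(df), "label")
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @param sample_id identifier for the sample the table belongs to.
#' @export
read_spot_table <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("label", "z_um", "y_um", "x_um",
            "total_intensity", "volume_vox", "volume_um3")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("malformed spot CSV, missing column(s): ", paste(miss, collapse = ", "))
  spot_table(df, sample_id = sample_id)
}
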