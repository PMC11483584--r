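#' Brain atlas: label volume plus region metadata
#'
#' Pairs a 3D integer label grid (same shape and pitch as the sample
#' volume it annotates; 0 = background/outside brain) with a region
#' metadata table. Region rows carry the anatomical acronym, the
#' medium-sized group the region belongs to, the region volume in mm^3,
#' and an exclusion flag for regions left out of density analysis
#' (typically the ventricular systems and fibre tracts).
#'
#' @param labels integer 3D array of region labels, `[z, y, x]`.
#' @param regions data.frame with columns `region_id`, `acronym`,
#'   `medium_group_id`, `volume_mm3`, `excluded` (logical).
#' @param pitch_um per-axis voxel pitch in micrometres.
#' @return An object of class `atlas`.
#' @export
atlas <- function(labels, regions, pitch_um) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("non-3D data: atlas labels must be a 3D array")
  storage.mode(labels) <- "integer"
  need <- c("region_id", "acronym", "medium_group_id", "volume_mm3", "excluded")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("region table missing column(s): ", paste(miss, collapse = ", "))
  regions <- as.data.frame(regions)[, need]
  regions$region_id <- as.integer(regions$region_id)
  regions$excluded <- as.logical(regions$excluded)
  if (anyDuplicated(regions$region_id))
    stop("duplicate region_id in region table")
  if (any(!is.finite(regions$volume_mm3)) || any(regions$volume_mm3 <= 0))
    stop("volume_mm3 must be > 0 for every region")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(present, regions$region_id)
  if (length(unknown))
    stop("unknown label ", paste(unknown, collapse = ", "),
         " in atlas grid (no metadata row)")
  pitch_um <- as.numeric(pitch_um)
  if (length(pitch_um) == 1L) pitch_um <- rep(pitch_um, 3L)
  if (length(pitch_um) != 3L || any(pitch_um <= 0))
    stop("pitch_um must be 3 positive values")
  structure(list(labels = labels, regions = regions, pitch_um = pitch_um),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("atlas: %d x %d x %d voxels, %d regions (%d excluded)\n",
              d[1], d[2], d[3], nrow(x$regions), sum(x$regions$excluded)))
  invisible(x)
}

#' Read an atlas from a label volume and region table
#'
#' The label volume is an NRRD integer grid; the region table is a CSV
#' with columns `region_id`, `acronym`, `medium_group_id`, `volume_mm3`,
#' `excluded`. Labels present in the grid but absent from the table are
#' an error (listed by id), as are non-positive region volumes.
#'
#' @param label_path NRRD label volume.
#' @param region_table_path CSV region metadata.
#' @param pitch_override optional pitch (micrometres) overriding NRRD
#'   spacings.
#' @return An [atlas].
#' @export
read_atlas <- function(label_path, region_table_path, pitch_override = NULL) {
  parsed <- read_nrrd(label_path)
  pitch <- pitch_override %||% parsed$spacings
  if (is.null(pitch)) stop("no voxel pitch for atlas labels")
  regions <- utils::read.csv(region_table_path, stringsAsFactors = FALSE)
  atlas(parsed$data, regions, pitch)
}

#' Write an atlas to disk
#' @param atlas an [atlas].
#' @param label_path output NRRD path for the label grid.
#' @param region_table_path output CSV path for the region table.
#' @return invisibly, the two paths.
#' @export
write_atlas <- function(atlas, label_path, region_table_path) {
  stopifnot(inherits(atlas, "atlas"))
  write_nrrd(atlas$labels, label_path, spacings = atlas$pitch_um, type = "int32")
  utils::write.csv(atlas$regions, region_table_path, row.names = FALSE)
  invisible(c(label_path, region_table_path))
}
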