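#' 3D intensity volume
#'
#' Container for a 3D grayscale grid with physical voxel pitch. The axis
#' convention is fixed as (z, y, x): `data[z, y, x]`, with 1-based voxel
#' indices. The physical coordinate of voxel index `i` along an axis is
#' `(i - 0.5) * pitch` (voxel-center convention), so a single-voxel spot's
#' centroid sits at the voxel center.
#'
#' @param data numeric 3D array of non-negative, finite intensities,
#'   indexed `[z, y, x]`.
#' @param pitch_um per-axis voxel pitch in micrometres, length 3 in
#'   (z, y, x) order, or a single value recycled to all three axes.
#' @return An object of class `volume3d`: a list with elements `data`
#'   and `pitch_um`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), pitch_um = 8.3)
#' dim(v$data)
#' @export
volume3d <- function(data, pitch_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D data: 'data' must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L))
    stop("all volume dimensions must be >= 1")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  if (any(data < 0))
    stop("intensities must be >= 0")
  pitch_um <- as.numeric(pitch_um)
  if (length(pitch_um) == 1L) pitch_um <- rep(pitch_um, 3L)
  if (length(pitch_um) != 3L || any(!is.finite(pitch_um)) || any(pitch_um <= 0))
    stop("pitch_um must be 3 positive finite values (z, y, x)")
  structure(list(data = data, pitch_um = pitch_um), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels (z, y, x), pitch %s um\n",
              d[1], d[2], d[3], paste(signif(x$pitch_um, 6), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Is the volume isotropic at a given pitch?
#' @param volume a `volume3d`.
#' @param pitch_um target pitch in micrometres.
#' @param tol relative tolerance.
#' @return logical scalar.
#' @keywords internal
is_isotropic_at <- function(volume, pitch_um, tol = 1e-6) {
  all(abs(volume$pitch_um - pitch_um) <= tol * pitch_um)
}

#' Physical centroid coordinates of voxel indices
#'
#' Converts 1-based (z, y, x) voxel indices to physical micrometre
#' coordinates under the voxel-center convention.
#'
#' @param idx integer matrix with columns (z, y, x), one row per voxel.
#' @param pitch_um per-axis pitch, length 3.
#' @return numeric matrix of physical coordinates in micrometres.
#' @keywords internal
voxel_to_um <- function(idx, pitch_um) {
  sweep(idx - 0.5, 2L, pitch_um, `*`)
}
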