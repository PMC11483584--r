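#' Tau extraction parameters
#'
#' Bundles every tunable of the spot-extraction stage. Defaults follow
#' the published protocol: a small Gaussian of sigma 0.83 voxels (about
#' 16 um FWHM at the 8.3 um standard pitch) minus an 83-um mean filter;
#' a brain mask thresholded at 1.5 times the global mean intensity and
#' eroded ten times; and a spot threshold at twice the mean raw
#' intensity outside the brain mask.
#'
#' @param sigma_small_vox Gaussian sigma of the small filter, in voxels.
#' @param mean_extent_um edge length of the large mean (box) filter, in
#'   micrometres. An even voxel count is rounded up to the nearest odd
#'   kernel so the filter stays symmetric and shift-free.
#' @param mask_threshold_factor brain-mask threshold as a multiple of the
#'   global mean intensity.
#' @param erosion_iterations number of single-voxel erosions applied to
#'   the thresholded mask.
#' @param spot_threshold_factor spot threshold as a multiple of the mean
#'   raw intensity outside the brain mask.
#' @param target_pitch_um standard isotropic resampling pitch (um).
#' @param connectivity component adjacency rule: 6 (face) or 26
#'   (face/edge/corner).
#' @param erosion_element structuring element for mask erosion:
#'   `"cross"` (6-connected) or `"cube"` (26-connected).
#' @param centroid weighting for spot centroids: `"weighted"` (by
#'   difference intensity) or `"geometric"`.
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(sigma_small_vox = 0.83,
                              mean_extent_um = 83,
                              mask_threshold_factor = 1.5,
                              erosion_iterations = 10L,
                              spot_threshold_factor = 2.0,
                              target_pitch_um = 8.3,
                              connectivity = 6L,
                              erosion_element = c("cross", "cube"),
                              centroid = c("weighted", "geometric")) {
  erosion_element <- match.arg(erosion_element)
  centroid <- match.arg(centroid)
  stopifnot(sigma_small_vox > 0, mean_extent_um > 0,
            mask_threshold_factor > 0, spot_threshold_factor > 0,
            target_pitch_um > 0, erosion_iterations >= 0)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  structure(list(sigma_small_vox = sigma_small_vox,
                 mean_extent_um = mean_extent_um,
                 mask_threshold_factor = mask_threshold_factor,
                 erosion_iterations = as.integer(erosion_iterations),
                 spot_threshold_factor = spot_threshold_factor,
                 target_pitch_um = target_pitch_um,
                 connectivity = connectivity,
                 erosion_element = erosion_element,
                 centroid = centroid),
            class = "extraction_params")
}

#' Stage-tagged log line
#'
#' Writes `[stage] message` to stderr. Silenced with
#' `options(tauscape.quiet = TRUE)`.
#' @param stage short stage tag.
#' @param ... sprintf-style message parts.
#' @keywords internal
tau_log <- function(stage, ...) {
  if (isTRUE(getOption("tauscape.quiet", FALSE))) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible()
}
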