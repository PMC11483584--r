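#' Resample a volume to the standard isotropic pitch
#'
#' Trilinear resampling onto an isotropic grid at `target_pitch_um`,
#' matching the preprocessing step that brings every sample to the
#' standard 8.3 um resolution before filtering. A volume already at the
#' target pitch is returned unchanged. Output coordinates outside the
#' input voxel-center range are clamped to the nearest edge value.
#'
#' @param volume a [volume3d].
#' @param target_pitch_um target isotropic pitch in micrometres.
#' @return A [volume3d] at isotropic `target_pitch_um`.
#' @export
resample_to_standard <- function(volume, target_pitch_um = 8.3) {
  stopifnot(inherits(volume, "volume3d"), target_pitch_um > 0)
  if (is_isotropic_at(volume, target_pitch_um)) return(volume)
  d <- dim(volume$data)
  pin <- volume$pitch_um
  n_out <- pmax(1L, as.integer(round(d * pin / target_pitch_um)))
  # continuous 1-based input index of each output voxel center
  ax <- lapply(1:3, function(a) {
    cc <- (seq_len(n_out[a]) - 0.5) * target_pitch_um
    j <- cc / pin[a] + 0.5
    j <- pmin(pmax(j, 1), d[a])
    j0 <- pmin(floor(j), d[a] - ifelse(d[a] > 1L, 1L, 0L))
    list(lo = as.integer(j0), hi = as.integer(pmin(j0 + 1L, d[a])),
         f = j - j0)
  })
  out <- array(0, n_out)
  w1 <- function(a) ax[[a]]$f
  w0 <- function(a) 1 - ax[[a]]$f
  idx <- function(a, hi) if (hi) ax[[a]]$hi else ax[[a]]$lo
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- outer(outer(if (cz) w1(1) else w0(1),
                     if (cy) w1(2) else w0(2)),
               if (cx) w1(3) else w0(3))
    out <- out + volume$data[idx(1, cz), idx(2, cy), idx(3, cx), drop = FALSE] * w
  }
  volume3d(out, target_pitch_um)
}

# Symmetric (reflect) index fold: 0-based j maps into [0, n-1] with the
# pattern ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
reflect_index <- function(j, n) {
  m <- j %% (2L * n)
  ifelse(m < n, m, 2L * n - 1L - m) + 1L
}

# Convolve a 3D array along one axis with an odd-length kernel,
# symmetric boundary handling. Works by permuting the target axis first
# and accumulating shifted row blocks of the flattened matrix.
convolve_axis <- function(arr, kernel, axis) {
  K <- length(kernel)
  stopifnot(K %% 2L == 1L)
  r <- (K - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1]
  mat <- matrix(a, n)
  out <- matrix(0, n, ncol(mat))
  for (t in seq_len(K)) {
    off <- t - 1L - r
    rows <- reflect_index(seq_len(n) - 1L + off, n)
    out <- out + kernel[t] * mat[rows, , drop = FALSE]
  }
  aperm(array(out, da), order(perm))
}

#' Separable Gaussian filter kernel (1D)
#' @param sigma_vox sigma in voxels.
#' @param radius kernel half-width; default `ceiling(4 * sigma)`.
#' @return numeric kernel of odd length, normalised to sum 1.
#' @keywords internal
gaussian_kernel_1d <- function(sigma_vox, radius = ceiling(4 * sigma_vox)) {
  radius <- max(1L, as.integer(radius))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma_vox)
  k / sum(k)
}

#' Gaussian-mean difference band-pass
#'
#' The spot-enhancement operator: a small Gaussian filter (sigma
#' `sigma_small_vox` voxels) minus a large mean (box) filter of edge
#' `mean_extent_um`, both applied with symmetric boundary handling. The
#' difference amplifies punctate tau signal relative to the local
#' background; a constant input maps to an exactly zero difference. The
#' mean-filter edge in voxels is `round(mean_extent_um / pitch)`; an
#' even count is rounded up to the nearest odd kernel so the filter is
#' symmetric and introduces no half-voxel shift.
#'
#' @param volume a [volume3d], isotropic at `params$target_pitch_um`.
#' @param params an [extraction_params].
#' @return A list of class `difference_volume` with elements `data`
#'   (signed 3D array) and `params`.
#' @export
gaussian_mean_difference <- function(volume, params = extraction_params()) {
  stopifnot(inherits(volume, "volume3d"))
  if (!is_isotropic_at(volume, params$target_pitch_um))
    stop("volume must be isotropic at target_pitch_um; run resample_to_standard() first")
  pitch <- params$target_pitch_um
  w <- as.integer(round(params$mean_extent_um / pitch))
  if (w < 1L) stop("mean_extent_um smaller than one voxel")
  if (w %% 2L == 0L) w <- w + 1L
  gk <- gaussian_kernel_1d(params$sigma_small_vox)
  mk <- rep(1 / w, w)
  g <- volume$data
  m <- volume$data
  for (a in 1:3) {
    g <- convolve_axis(g, gk, a)
    m <- convolve_axis(m, mk, a)
  }
  structure(list(data = g - m, params = params, pitch_um = rep(pitch, 3L)),
            class = "difference_volume")
}

#' Gaussian full-width at half-maximum
#'
#' FWHM in micrometres of the small Gaussian filter:
#' `2 * sqrt(2 * log(2)) * sigma_vox * pitch_um`. At the defaults
#' (sigma 0.83 voxels, 8.3 um pitch) this is approximately 16 um.
#'
#' @param sigma_vox Gaussian sigma in voxels.
#' @param pitch_um voxel pitch in micrometres.
#' @return FWHM in micrometres.
#' @export
gaussian_fwhm_um <- function(sigma_vox = 0.83, pitch_um = 8.3) {
  2 * sqrt(2 * log(2)) * sigma_vox * pitch_um
}

# Shift a logical array by (dz, dy, dx), padding with FALSE.
shift_logical <- function(m, dz, dy, dx) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    by <- c(dz, dy, dx)[a]
    if (abs(by) >= d[a]) return(out)
    if (by >= 0) {
      dst[[a]] <- seq.int(1L + by, d[a])
      src[[a]] <- seq.int(1L, d[a] - by)
    } else {
      dst[[a]] <- seq.int(1L, d[a] + by)
      src[[a]] <- seq.int(1L - by, d[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
    # positive lexicographic half-space: each unordered pair once
    keep <- offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
      (offs$dx == 0 & offs$dy == 0 & offs$dz > 0)
    lapply(which(keep), function(i) as.integer(unlist(offs[i, ])))
  }
}

erode_mask_once <- function(m, element) {
  offs <- neighbour_offsets(if (element == "cross") 6L else 26L)
  out <- m
  for (o in offs) {
    out <- out & shift_logical(m, o[1], o[2], o[3]) &
      shift_logical(m, -o[1], -o[2], -o[3])
  }
  out
}

#' Compute the refined brain mask
#'
#' Thresholds the raw volume at `mask_threshold_factor` times the global
#' mean intensity over all voxels, then refines the mask by iterated
#' binary erosion (`erosion_iterations` passes with the configured
#' structuring element; voxels beyond the image border count as
#' background, so each pass peels one boundary layer). The refinement
#' restricts analysis to the brain interior and drops surface artefacts.
#'
#' @param volume a [volume3d] (raw intensities).
#' @param params an [extraction_params].
#' @return A list of class `brain_mask` with elements `mask` (logical 3D
#'   array), `n_voxels_inside` and `threshold`.
#' @export
compute_brain_mask <- function(volume, params = extraction_params()) {
  stopifnot(inherits(volume, "volume3d"))
  thr <- params$mask_threshold_factor * mean(volume$data)
  m <- volume$data > thr
  for (i in seq_len(params$erosion_iterations))
    m <- erode_mask_once(m, params$erosion_element)
  tau_log("mask", "threshold %.6g (%.3g x global mean), %d voxels after %d erosions",
          thr, params$mask_threshold_factor, sum(m), params$erosion_iterations)
  structure(list(mask = m, n_voxels_inside = sum(m), threshold = thr),
            class = "brain_mask")
}

#' Label connected foreground components
#'
#' Connected-component labelling of a 3D logical array under 6- or
#' 26-connectivity. Foreground voxels become vertices of an adjacency
#' graph (edges from shifted-index matching) whose connected components
#' are the spots; labels are assigned in order of each component's first
#' voxel in column-major scan order, so labelling is deterministic.
#'
#' @param fg logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer 3D array, 0 = background, components numbered from 1.
#' @export
label_components <- function(fg, connectivity = 6L) {
  stopifnot(is.array(fg), length(dim(fg)) == 3L)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(fg)
  lab <- array(0L, d)
  idx <- which(fg)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  vert <- match(idx, idx)  # 1..n in scan order
  edges <- integer(0)
  for (o in neighbour_offsets(connectivity)) {
    nb <- coord + matrix(o, nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- match(nb_lin, idx)
    src <- which(ok)[!is.na(hit)]
    if (length(src))
      edges <- c(edges, rbind(src, hit[!is.na(hit)]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- match(memb, unique(memb))
  lab
}

#' Extract tau deposit spots
#'
#' Thresholds the masked Gaussian-mean difference image at
#' `spot_threshold_factor` times the mean raw intensity outside the
#' brain mask, labels connected components of the candidate voxels, and
#' summarises each component as a spot: centroid in physical
#' micrometres (intensity-weighted by default), total difference
#' intensity, voxel count and physical volume.
#'
#' @param diff a `difference_volume` from [gaussian_mean_difference()].
#' @param raw the raw [volume3d] the difference was computed from.
#' @param mask a `brain_mask` from [compute_brain_mask()].
#' @param params an [extraction_params].
#' @param sample_id identifier attached to the returned table.
#' @return A [spot_table]. The attribute `n_candidate_voxels` records
#'   the suprathreshold voxel count (equal to the sum of `volume_vox`).
#' @export
extract_spots <- function(diff, raw, mask, params = extraction_params(),
                          sample_id = "sample") {
  stopifnot(inherits(diff, "difference_volume"), inherits(raw, "volume3d"),
            inherits(mask, "brain_mask"))
  if (!all(dim(diff$data) == dim(raw$data)) ||
      !all(dim(diff$data) == dim(mask$mask)))
    stop("difference, raw volume and mask shapes must match")
  outside <- !mask$mask
  if (!any(outside))
    stop("empty outside-mask set: spot threshold undefined")
  thr <- params$spot_threshold_factor * mean(raw$data[outside])
  tau_log("extract", "spot threshold %.6g (%.3g x mean outside-brain intensity)",
          thr, params$spot_threshold_factor)
  cand <- mask$mask & (diff$data > thr)
  lab <- label_components(cand, params$connectivity)
  idx <- which(lab > 0L)
  pitch <- raw$pitch_um
  vox_vol_um3 <- prod(pitch)
  if (!length(idx)) {
    tab <- spot_table(NULL, sample_id = sample_id)
    attr(tab, "n_candidate_voxels") <- 0L
    attr(tab, "spot_threshold") <- thr
    return(tab)
  }
  labs <- lab[idx]
  vals <- diff$data[idx]
  coord_um <- voxel_to_um(arrayInd(idx, dim(lab)), pitch)
  w <- if (params$centroid == "weighted") vals else rep(1, length(vals))
  sw <- as.vector(tapply(w, labs, sum))
  cz <- as.vector(tapply(w * coord_um[, 1], labs, sum)) / sw
  cy <- as.vector(tapply(w * coord_um[, 2], labs, sum)) / sw
  cx <- as.vector(tapply(w * coord_um[, 3], labs, sum)) / sw
  tot <- as.vector(tapply(vals, labs, sum))
  nv <- as.vector(tapply(vals, labs, length))
  ord <- order(as.integer(names(tapply(vals, labs, length))))
  df <- data.frame(label = seq_along(tot),
                   z_um = cz[ord], y_um = cy[ord], x_um = cx[ord],
                   total_intensity = tot[ord],
                   volume_vox = nv[ord],
                   volume_um3 = nv[ord] * vox_vol_um3)
  tab <- spot_table(df, sample_id = sample_id)
  attr(tab, "n_candidate_voxels") <- sum(cand)
  attr(tab, "spot_threshold") <- thr
  tab
}

#' Run the full spot-extraction stage on one volume
#'
#' Composes read, resample to the standard pitch, Gaussian-mean
#' difference, brain-mask refinement, spot extraction and CSV export.
#' Every threshold used is logged. A volume yielding no spots writes a
#' header-only CSV and warns.
#'
#' @param volume a [volume3d] or a path readable by [read_volume()].
#' @param out_csv optional CSV output path for the spot table.
#' @param params an [extraction_params].
#' @param pitch_override forwarded to [read_volume()] when `volume` is a
#'   path.
#' @param sample_id identifier attached to the spot table.
#' @return The [spot_table], invisibly when `out_csv` is given.
#' @export
run_extraction <- function(volume, out_csv = NULL,
                           params = extraction_params(),
                           pitch_override = NULL, sample_id = "sample") {
  if (is.character(volume))
    volume <- read_volume(volume, pitch_override = pitch_override)
  std <- resample_to_standard(volume, params$target_pitch_um)
  diff <- gaussian_mean_difference(std, params)
  mask <- compute_brain_mask(std, params)
  spots <- extract_spots(diff, std, mask, params, sample_id = sample_id)
  if (nrow(spots) == 0L)
    warning("no tau spots detected in sample '", sample_id, "'")
  tau_log("extract", "%d spots, %d candidate voxels", nrow(spots),
          attr(spots, "n_candidate_voxels"))
  if (!is.null(out_csv)) {
    write_spot_table(spots, out_csv)
    return(invisible(spots))
  }
  spots
}
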