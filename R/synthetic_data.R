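#' Build a toy brain atlas with known geometry
#'
#' Partitions an ellipsoidal "brain" inscribed in the given shape into
#' `n_regions` contiguous regions over a zero background. Two layouts
#' are available: `layered-boxes` slices the ellipsoid into equal-width
#' slabs along z; `nested-shells` cuts concentric ellipsoidal shells.
#' Region volumes in mm^3 are exact voxel counts times the voxel
#' volume, so downstream density arithmetic is checkable to machine
#' precision.
#'
#' @param shape (z, y, x) voxel dimensions.
#' @param pitch_um isotropic voxel pitch in micrometres.
#' @param n_regions number of regions (>= 1).
#' @param layout `"layered-boxes"` or `"nested-shells"`.
#' @param excluded_ids region ids flagged as excluded from analysis.
#' @param medium_groups number of medium-sized groups the regions are
#'   assigned to (round-robin by region id).
#' @return An [atlas].
#' @export
make_toy_atlas <- function(shape, pitch_um = 8.3, n_regions = 4L,
                           layout = c("layered-boxes", "nested-shells"),
                           excluded_ids = integer(0), medium_groups = NULL) {
  layout <- match.arg(layout)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L), n_regions >= 1L)
  d <- shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 0.5
  zz <- (seq_len(d[1]) - ctr[1]) / semi[1]
  yy <- (seq_len(d[2]) - ctr[2]) / semi[2]
  xx <- (seq_len(d[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(zz^2, yy^2, `+`), xx^2, `+`)
  brain <- r2 <= 1
  if (sum(brain) < n_regions)
    stop("n_regions larger than available brain voxels")
  lab <- array(0L, d)
  if (layout == "layered-boxes") {
    zs <- which(apply(brain, 1, any))
    cuts <- if (n_regions == 1L) rep(1L, length(zs))
            else as.integer(cut(zs, breaks = n_regions, labels = FALSE))
    band <- integer(d[1])
    band[zs] <- cuts
    lab[brain] <- band[arrayInd(which(brain), d)[, 1]]
  } else {
    edges <- seq(0, 1, length.out = n_regions + 1L)[-1]
    shell <- findInterval(sqrt(r2[brain]), edges, left.open = FALSE,
                          rightmost.closed = TRUE) + 1L
    shell[shell > n_regions] <- n_regions
    lab[brain] <- shell
  }
  # guarantee every id appears even for thin shells/slabs
  for (id in seq_len(n_regions)) {
    if (!any(lab == id)) {
      spare <- which(lab > 0L)
      lab[spare[id]] <- id
    }
  }
  counts <- tabulate(lab[lab > 0L], nbins = n_regions)
  vox_mm3 <- prod(rep(pitch_um, 3)) * 1e-9
  if (is.null(medium_groups)) medium_groups <- min(n_regions, 4L)
  regions <- data.frame(
    region_id = seq_len(n_regions),
    acronym = sprintf("R%02d", seq_len(n_regions)),
    medium_group_id = ((seq_len(n_regions) - 1L) %% medium_groups) + 1L,
    volume_mm3 = counts * vox_mm3,
    excluded = seq_len(n_regions) %in% excluded_ids
  )
  atlas(lab, regions, pitch_um)
}

#' Specification of one planted tau spot
#'
#' @param center_vox (z, y, x) 1-based voxel index of the blob center.
#' @param amplitude peak intensity above background (> 0).
#' @param sigma_vox Gaussian blob sigma in voxels.
#' @param region_id intended atlas region (bookkeeping only).
#' @return A list of class `planted_spot`.
#' @export
planted_spot <- function(center_vox, amplitude, sigma_vox = 1.6,
                         region_id = NA_integer_) {
  stopifnot(length(center_vox) == 3L, amplitude > 0, sigma_vox > 0)
  structure(list(center_vox = as.numeric(center_vox), amplitude = amplitude,
                 sigma_vox = sigma_vox, region_id = as.integer(region_id)),
            class = "planted_spot")
}

#' Synthesise a tau channel volume with planted blobs
#'
#' Emulates the phospho-tau channel of a cleared brain: a flat
#' `brain_background` inside the atlas brain mask, `outside_background`
#' outside it, Gaussian blobs at the planted centers, and i.i.d.
#' Gaussian noise clipped at zero. The returned ground-truth mask marks
#' voxels within `2 * sigma_vox` of any planted center, enabling exact
#' recall/precision scoring of the extraction stage.
#'
#' @param atlas an [atlas]; its nonzero labels define the brain.
#' @param spots list of [planted_spot]; centers must lie in brain voxels.
#' @param brain_background intensity inside the brain.
#' @param outside_background intensity outside the brain.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed RNG seed (explicit; generators never touch global seeds
#'   silently).
#' @return list with `volume` ([volume3d]), `truth_mask` (logical
#'   array), and `spots` (the specs, with planted totals recorded).
#' @export
make_tau_volume <- function(atlas, spots = list(), brain_background = 20,
                            outside_background = 2, noise_sd = 1,
                            seed = 1L) {
  stopifnot(inherits(atlas, "atlas"))
  d <- dim(atlas$labels)
  brain <- atlas$labels > 0L
  vol <- array(outside_background, d)
  vol[brain] <- brain_background
  truth <- array(FALSE, d)
  coord <- NULL
  for (s in spots) {
    c0 <- s$center_vox
    cl <- as.integer(round(c0))
    if (any(cl < 1L) || any(cl > d) || !brain[cl[1], cl[2], cl[3]])
      stop("planted spot center (", paste(c0, collapse = ","),
           ") outside the brain mask")
    r <- ceiling(3 * s$sigma_vox)
    zr <- max(1, cl[1] - r):min(d[1], cl[1] + r)
    yr <- max(1, cl[2] - r):min(d[2], cl[2] + r)
    xr <- max(1, cl[3] - r):min(d[3], cl[3] + r)
    dz2 <- (zr - c0[1])^2
    dy2 <- (yr - c0[2])^2
    dx2 <- (xr - c0[3])^2
    g <- exp(-outer(outer(dz2, dy2, `+`), dx2, `+`) / (2 * s$sigma_vox^2))
    vol[zr, yr, xr] <- vol[zr, yr, xr] + s$amplitude * g
    near <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= (2 * s$sigma_vox)^2
    truth[zr, yr, xr] <- truth[zr, yr, xr] | near
  }
  if (noise_sd > 0) {
    rng <- local({ set.seed(seed); stats::rnorm(prod(d), 0, noise_sd) })
    vol <- vol + array(rng, d)
  }
  vol[vol < 0] <- 0
  list(volume = volume3d(vol, atlas$pitch_um), truth_mask = truth,
       spots = spots)
}

#' Generate per-sample region rankings with a planted consensus
#'
#' Builds `k_samples` strict orderings of `n_regions` region ids. The
#' ids in `planted_sequence` keep their relative order in every sample
#' (inserted at uniformly random positions); all other ids are placed as
#' an independent uniform permutation per sample. Densities are
#' synthesised exp-spaced along each ordering so log10 densities are
#' linear and strictly decreasing — ties are impossible by construction.
#' By construction the maximal order-conserved sequence across samples
#' has length at least `length(planted_sequence)`.
#'
#' @param n_regions total number of regions.
#' @param k_samples number of samples.
#' @param planted_sequence ordered vector of distinct region ids to
#'   conserve (may be empty).
#' @param seed RNG seed.
#' @param log10_top log10 density of each sample's top-ranked region.
#' @param log10_step decrement in log10 density per rank.
#' @return A [ranking_set].
#' @export
make_ranking_set <- function(n_regions, k_samples = 3L,
                             planted_sequence = integer(0), seed = 1L,
                             log10_top = 3, log10_step = 0.05) {
  planted_sequence <- as.integer(planted_sequence)
  if (anyDuplicated(planted_sequence)) stop("planted ids must be distinct")
  if (length(planted_sequence) > n_regions)
    stop("planted_sequence longer than n_regions")
  ids <- seq_len(n_regions)
  if (!all(planted_sequence %in% ids))
    stop("planted ids must be in 1..n_regions")
  set.seed(seed)
  L <- length(planted_sequence)
  rest <- setdiff(ids, planted_sequence)
  orderings <- vector("list", k_samples)
  for (k in seq_len(k_samples)) {
    ord <- integer(n_regions)
    pos <- if (L) sort(sample.int(n_regions, L)) else integer(0)
    ord[pos] <- planted_sequence
    if (length(rest))
      ord[setdiff(seq_len(n_regions), pos)] <- sample(rest)
    orderings[[k]] <- ord
  }
  dens <- matrix(NA_real_, n_regions, k_samples,
                 dimnames = list(ids, paste0("sample", seq_len(k_samples))))
  for (k in seq_len(k_samples))
    dens[orderings[[k]], k] <- 10^(log10_top - log10_step * (ids - 1))
  ranking_set(orderings, densities = dens)
}

#' Calibrate planted-blob amplitude to the detection contract
#'
#' The ground-truth mask of a planted blob is the ball of radius
#' `2 * sigma_vox` around its center, while the extraction stage keeps
#' voxels whose Gaussian-mean difference exceeds the spot threshold.
#' The two footprints coincide when the blob's peak difference equals
#' `exp(2)` times the threshold: the Gaussian-filtered blob has peak
#' `A * (sigma^2 / (sigma^2 + sigma_g^2))^(3/2)` and falls to
#' `exp(-2)` of it at radius two (blob) sigma. This function runs the
#' brain-mask stage on a spotless volume to obtain the spot threshold
#' the scene will produce, and returns the amplitude `A` satisfying
#' that identity — the contrast at which voxel-level detection scoring
#' against the ground-truth ball is well posed.
#'
#' @param atlas an [atlas] defining the brain geometry.
#' @param sigma_vox planted blob sigma in voxels.
#' @param params an [extraction_params].
#' @param brain_background,outside_background,noise_sd,seed scene
#'   parameters, as in [make_tau_volume()].
#' @return the calibrated amplitude (scalar).
#' @export
calibrate_spot_amplitude <- function(atlas, sigma_vox = 1.6,
                                     params = extraction_params(),
                                     brain_background = 20,
                                     outside_background = 2,
                                     noise_sd = 1, seed = 1L) {
  sim0 <- make_tau_volume(atlas, list(), brain_background = brain_background,
                          outside_background = outside_background,
                          noise_sd = noise_sd, seed = seed)
  mask0 <- compute_brain_mask(sim0$volume, params)
  if (!any(!mask0$mask)) stop("degenerate scene: mask covers everything")
  thr <- params$spot_threshold_factor * mean(sim0$volume$data[!mask0$mask])
  gain <- (sigma_vox^2 / (sigma_vox^2 + params$sigma_small_vox^2))^1.5
  exp(2) * thr / gain
}

#' Default PET frame schedule
#'
#' Frame durations in minutes for the 60-min dynamic scan: 4 x 1 min,
#' 8 x 2 min, 8 x 5 min (20 frames).
#' @return numeric vector of 20 frame durations summing to 60.
#' @export
default_frame_schedule <- function() c(rep(1, 4), rep(2, 8), rep(5, 8))

#' Synthesise a target/reference time-activity curve pair
#'
#' Evaluates the two activity curves at the frame mid-times implied by
#' the frame schedule and wraps them as [tac] objects sharing dose and
#' body weight, ready for SUV/SUVR quantification.
#'
#' @param frames frame durations in minutes; must sum to 60.
#' @param target_curve,reference_curve positive activity curves: either
#'   numeric vectors of one value per frame or functions of time (min).
#' @param dose_kbq injected dose (kBq).
#' @param body_weight_g body weight (g).
#' @return list with elements `target` and `reference`, both [tac].
#' @export
make_tac_pair <- function(frames = default_frame_schedule(),
                          target_curve, reference_curve,
                          dose_kbq = 17200, body_weight_g = 25) {
  if (abs(sum(frames) - 60) > 1e-9)
    stop("frame schedule must sum to 60 min (got ", sum(frames), ")")
  mid <- cumsum(frames) - frames / 2
  eval_curve <- function(cv) {
    a <- if (is.function(cv)) cv(mid) else rep_len(as.numeric(cv), length(mid))
    if (any(a <= 0)) stop("activity curves must be positive")
    a
  }
  list(target = tac(mid, eval_curve(target_curve), dose_kbq, body_weight_g,
                    region = "target"),
       reference = tac(mid, eval_curve(reference_curve), dose_kbq,
                       body_weight_g, region = "reference"))
}
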