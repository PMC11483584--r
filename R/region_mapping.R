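#' Per-sample region rankings
#'
#' Holds `k` strict orderings of a shared region set by descending
#' log10 tau density, plus the density values behind them. Each
#' ordering must be a permutation of the common region ids.
#'
#' @param orderings list of k integer vectors (region ids, descending
#'   density).
#' @param densities optional numeric matrix (regions x samples) of
#'   densities, rownames = region ids.
#' @return An object of class `ranking_set`.
#' @export
ranking_set <- function(orderings, densities = NULL) {
  stopifnot(is.list(orderings), length(orderings) >= 1L)
  ids <- sort(orderings[[1]])
  for (o in orderings) {
    if (!identical(sort(as.integer(o)), as.integer(ids)))
      stop("each ordering must be a permutation of the common region set")
  }
  if (!is.null(densities)) {
    densities <- as.matrix(densities)
    if (nrow(densities) != length(ids))
      stop("densities must have one row per region")
    for (k in seq_along(orderings)) {
      v <- densities[as.character(orderings[[k]]), k]
      if (any(diff(v) >= 0))
        stop("densities must be strictly decreasing along each ordering")
    }
  }
  structure(list(region_ids = as.integer(ids),
                 orderings = lapply(orderings, as.integer),
                 densities = densities),
            class = "ranking_set")
}

#' @export
print.ranking_set <- function(x, ...) {
  cat(sprintf("ranking_set: %d regions x %d samples\n",
              length(x$region_ids), length(x$orderings)))
  invisible(x)
}

#' Assign spots to atlas regions by centroid voxel
#'
#' Each spot is assigned the atlas label at the voxel containing its
#' centroid. Spots landing on background (label 0) or in regions
#' flagged `excluded` (e.g. ventricular systems, fibre tracts) are
#' dropped and counted. Assignment is by centroid only, mirroring the
#' point-cloud registration of spot centroids to the reference atlas.
#'
#' @param spots a [spot_table].
#' @param atlas an [atlas] on the same grid as the source volume.
#' @return list with `assigned` (the spot table plus a `region_id`
#'   column, excluded/background spots removed), `n_dropped_background`,
#'   `n_dropped_excluded`.
#' @export
assign_spots <- function(spots, atlas) {
  stopifnot(inherits(spots, "spot_table"), inherits(atlas, "atlas"))
  d <- dim(atlas$labels)
  df <- as.data.frame(spots)
  if (nrow(df) == 0L) {
    df$region_id <- integer(0)
    return(list(assigned = df, n_dropped_background = 0L,
                n_dropped_excluded = 0L))
  }
  vox <- cbind(ceiling(df$z_um / atlas$pitch_um[1]),
               ceiling(df$y_um / atlas$pitch_um[2]),
               ceiling(df$x_um / atlas$pitch_um[3]))
  if (any(vox < 1L) || any(sweep(vox, 2, d, `>`)))
    stop("spot centroid outside the atlas grid")
  lab <- atlas$labels[vox]
  excl <- atlas$regions$region_id[atlas$regions$excluded]
  in_bg <- lab == 0L
  in_ex <- lab %in% excl
  keep <- !(in_bg | in_ex)
  tau_log("assign", "%d spots assigned, %d dropped (background %d, excluded %d)",
          sum(keep), sum(!keep), sum(in_bg), sum(in_ex))
  df$region_id <- lab
  list(assigned = df[keep, , drop = FALSE],
       n_dropped_background = sum(in_bg),
       n_dropped_excluded = sum(in_ex))
}

#' Regional tau density metrics
#'
#' For every non-excluded atlas region: the integrated spot intensity
#' (sum of total Gaussian-mean difference intensity of assigned spots),
#' the density per mm^3 (integrated intensity / region volume), the
#' volume ratio (summed spot volume / region volume), and the log10
#' density (NA where density is 0). Regions with no spots get density 0.
#'
#' @param assignment result of [assign_spots()].
#' @param atlas an [atlas].
#' @return data.frame with columns `region_id`, `acronym`,
#'   `medium_group_id`, `integrated_intensity`, `density_per_mm3`,
#'   `volume_ratio`, `log10_density`.
#' @export
regional_density <- function(assignment, atlas) {
  stopifnot(inherits(atlas, "atlas"))
  reg <- atlas$regions[!atlas$regions$excluded, , drop = FALSE]
  df <- assignment$assigned
  s_int <- tapply(df$total_intensity, factor(df$region_id, levels = reg$region_id), sum)
  s_vol <- tapply(df$volume_um3, factor(df$region_id, levels = reg$region_id), sum)
  s_int[is.na(s_int)] <- 0
  s_vol[is.na(s_vol)] <- 0
  dens <- as.vector(s_int) / reg$volume_mm3
  data.frame(region_id = reg$region_id,
             acronym = reg$acronym,
             medium_group_id = reg$medium_group_id,
             integrated_intensity = as.vector(s_int),
             density_per_mm3 = dens,
             volume_ratio = as.vector(s_vol) / (reg$volume_mm3 * 1e9),
             log10_density = ifelse(dens > 0, log10(dens), NA_real_))
}

#' Medium-group density profile across samples
#'
#' Pools subregion intensities into their medium-sized groups using
#' volume-weighted pooling (sum of group intensity / sum of group
#' volume) per sample, averages the group densities arithmetically
#' across samples, and reports the groups sorted by descending mean
#' density together with the across-group mean.
#'
#' @param density_list list of per-sample data.frames from
#'   [regional_density()].
#' @param atlas an [atlas].
#' @param pooling `"volume-weighted"` (default) or `"mean-of-members"`.
#' @return list with `profile` (data.frame `medium_group_id`,
#'   `mean_density`, sorted descending) and `group_mean` (the mean of
#'   `mean_density` across groups).
#' @export
medium_region_profile <- function(density_list, atlas,
                                  pooling = c("volume-weighted",
                                              "mean-of-members")) {
  pooling <- match.arg(pooling)
  stopifnot(length(density_list) >= 1L)
  per_sample <- lapply(density_list, function(d) {
    g <- factor(d$medium_group_id)
    if (pooling == "volume-weighted") {
      vols <- atlas$regions$volume_mm3[match(d$region_id,
                                             atlas$regions$region_id)]
      tapply(d$integrated_intensity, g, sum) / tapply(vols, g, sum)
    } else {
      tapply(d$density_per_mm3, g, mean)
    }
  })
  gm <- Reduce(`+`, per_sample) / length(per_sample)
  prof <- data.frame(medium_group_id = as.integer(names(gm)),
                     mean_density = as.vector(gm))
  prof <- prof[order(-prof$mean_density, prof$medium_group_id), ]
  rownames(prof) <- NULL
  list(profile = prof, group_mean = mean(prof$mean_density))
}

#' Select subregions of above-mean medium groups
#'
#' Returns all member subregions of medium groups whose averaged
#' density strictly exceeds the across-group mean. Groups tied with the
#' mean are excluded (strict inequality), so a single group — or any
#' profile of identical group densities — selects nothing.
#'
#' @param group_profile result of [medium_region_profile()].
#' @param atlas an [atlas].
#' @return integer vector of subregion ids, sorted.
#' @export
select_above_mean_subregions <- function(group_profile, atlas) {
  above <- group_profile$profile$medium_group_id[
    group_profile$profile$mean_density > group_profile$group_mean]
  reg <- atlas$regions
  sort(reg$region_id[!reg$excluded & reg$medium_group_id %in% above])
}

#' Build a ranking set from per-sample densities
#'
#' Orders a region subset by descending log10 density within each
#' sample. Regions with zero density in any sample are rejected (their
#' log10 density is undefined); pre-filter the subset instead. Ties
#' within a sample are broken deterministically by ascending region id
#' and reported with a warning.
#'
#' @param density_list list of per-sample data.frames from
#'   [regional_density()].
#' @param region_subset region ids to rank (default: all regions with
#'   positive density in every sample).
#' @return A [ranking_set].
#' @export
build_ranking_set <- function(density_list, region_subset = NULL) {
  stopifnot(length(density_list) >= 1L)
  if (is.null(region_subset)) {
    pos <- lapply(density_list, function(d) d$region_id[d$density_per_mm3 > 0])
    region_subset <- Reduce(intersect, pos)
  }
  region_subset <- sort(as.integer(region_subset))
  if (!length(region_subset)) stop("empty region subset")
  orderings <- vector("list", length(density_list))
  dens <- matrix(NA_real_, length(region_subset), length(density_list),
                 dimnames = list(region_subset,
                                 paste0("sample", seq_along(density_list))))
  tied <- FALSE
  for (k in seq_along(density_list)) {
    d <- density_list[[k]]
    i <- match(region_subset, d$region_id)
    if (anyNA(i))
      stop("sample ", k, " does not cover the region subset")
    v <- d$density_per_mm3[i]
    if (any(v <= 0))
      stop("zero density in sample ", k,
           " for region(s) in subset: log10 undefined")
    if (anyDuplicated(v)) tied <- TRUE
    ord <- order(-v, region_subset)
    orderings[[k]] <- region_subset[ord]
    dens[, k] <- v
  }
  if (tied)
    warning("tied densities broken by ascending region id")
  # the container checks strict decrease; ties were already warned about,
  # so perturb exact ties by an infinitesimal rank offset in the stored
  # densities only when present
  if (tied) {
    for (k in seq_len(ncol(dens))) {
      v <- dens[as.character(orderings[[k]]), k]
      eps <- cumsum(c(0, diff(v) == 0)) * .Machine$double.eps * abs(v[1])
      dens[as.character(orderings[[k]]), k] <- v - eps
    }
  }
  ranking_set(orderings, densities = dens)
}
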