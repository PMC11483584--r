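options(tauscape.quiet = TRUE)

# small deterministic atlas: 4 slabs, region 2 excluded in some tests
slab_atlas <- function(excluded = integer(0)) {
  make_toy_atlas(c(32, 32, 32), 8.3, 4, excluded_ids = excluded)
}

spot_at <- function(vox, intensity = 6, nvox = 3) {
  spot_table(data.frame(label = 1, z_um = (vox[1] - 0.5) * 8.3,
                        y_um = (vox[2] - 0.5) * 8.3,
                        x_um = (vox[3] - 0.5) * 8.3,
                        total_intensity = intensity, volume_vox = nvox,
                        volume_um3 = nvox * 8.3^3))
}

test_that("spots are assigned by centroid voxel; excluded/background dropped and counted", {
  a <- slab_atlas()
  # find a voxel in region 3
  v3 <- arrayInd(which(a$labels == 3L)[100], dim(a$labels))
  asg <- assign_spots(spot_at(v3), a)
  expect_equal(asg$assigned$region_id, 3L)
  expect_equal(asg$n_dropped_background + asg$n_dropped_excluded, 0L)

  ae <- slab_atlas(excluded = 3L)
  asg2 <- assign_spots(spot_at(v3), ae)
  expect_equal(nrow(asg2$assigned), 0L)
  expect_equal(asg2$n_dropped_excluded, 1L)

  v0 <- arrayInd(which(a$labels == 0L)[1], dim(a$labels))
  asg3 <- assign_spots(spot_at(v0), a)
  expect_equal(asg3$n_dropped_background, 1L)

  far <- spot_at(c(100, 100, 100))
  expect_error(assign_spots(far, a), "outside the atlas grid")
})

test_that("assignment conserves spot counts and intensities", {
  scene <- make_test_scene(n_blobs = 15L, seed = 21L)
  spots <- run_extraction(scene$sim$volume)
  asg <- assign_spots(spots, scene$atlas)
  expect_equal(nrow(asg$assigned) + asg$n_dropped_background +
                 asg$n_dropped_excluded, nrow(spots))
  dens <- regional_density(asg, scene$atlas)
  expect_equal(sum(dens$integrated_intensity),
               sum(asg$assigned$total_intensity))
})

test_that("regional density arithmetic and homogeneity", {
  lab <- array(1L, c(4, 4, 4))
  reg <- data.frame(region_id = 1L, acronym = "A", medium_group_id = 1L,
                    volume_mm3 = 2, excluded = FALSE)
  a <- atlas(lab, reg, 8.3)
  asg <- assign_spots(spot_at(c(2, 2, 2), intensity = 6), a)
  d <- regional_density(asg, a)
  expect_equal(d$density_per_mm3, 3)
  expect_equal(d$log10_density, log10(3))

  asg2 <- asg
  asg2$assigned$total_intensity <- 2 * asg2$assigned$total_intensity
  d2 <- regional_density(asg2, a)
  expect_equal(d2$density_per_mm3, 2 * d$density_per_mm3)
})

test_that("spotless regions get zero density and NA log10 density", {
  a <- slab_atlas()
  v1 <- arrayInd(which(a$labels == 1L)[10], dim(a$labels))
  d <- regional_density(assign_spots(spot_at(v1), a), a)
  expect_equal(d$density_per_mm3[d$region_id != 1L], rep(0, 3))
  expect_true(all(is.na(d$log10_density[d$region_id != 1L])))
})

test_that("medium-group pooling is volume-weighted and sorts descending", {
  # 4 regions in 2 groups; hand-build densities
  a <- make_toy_atlas(c(32, 32, 32), 8.3, 4, medium_groups = 2)
  expect_equal(a$regions$medium_group_id, c(1L, 2L, 1L, 2L))
  dens <- data.frame(region_id = 1:4, acronym = a$regions$acronym,
                     medium_group_id = a$regions$medium_group_id,
                     integrated_intensity = c(10, 0, 2, 0),
                     density_per_mm3 = NA, volume_ratio = 0,
                     log10_density = NA)
  prof <- medium_region_profile(list(dens), a)
  vols <- a$regions$volume_mm3
  expect_equal(prof$profile$mean_density[prof$profile$medium_group_id == 1],
               12 / (vols[1] + vols[3]))
  expect_equal(prof$profile$mean_density[prof$profile$medium_group_id == 2], 0)
  expect_true(all(diff(prof$profile$mean_density) <= 0))
  expect_equal(prof$group_mean, mean(prof$profile$mean_density))

  # single group containing everything: density = total / total volume
  a1 <- make_toy_atlas(c(32, 32, 32), 8.3, 4, medium_groups = 1)
  dens$medium_group_id <- 1L
  prof1 <- medium_region_profile(list(dens), a1)
  expect_equal(prof1$profile$mean_density, 12 / sum(a1$regions$volume_mm3))
})

test_that("above-mean selection is strict: equal groups select nothing", {
  a <- make_toy_atlas(c(32, 32, 32), 8.3, 4, medium_groups = 4)
  mk <- function(groups) list(profile = data.frame(
    medium_group_id = seq_along(groups), mean_density = groups),
    group_mean = mean(groups))
  # groups {10,2,0,0}: mean 3, only group 1 selected
  sel <- select_above_mean_subregions(mk(c(10, 2, 0, 0)), a)
  expect_equal(sel, a$regions$region_id[a$regions$medium_group_id == 1])
  expect_length(select_above_mean_subregions(mk(rep(5, 4)), a), 0L)
  a1 <- make_toy_atlas(c(32, 32, 32), 8.3, 4, medium_groups = 1)
  expect_length(select_above_mean_subregions(mk(5), a1), 0L)
})

test_that("ranking construction matches hand-ranked densities, warns on ties", {
  mk_dens <- function(v) data.frame(region_id = 1:5, acronym = letters[1:5],
                                    medium_group_id = 1L,
                                    integrated_intensity = v,
                                    density_per_mm3 = v, volume_ratio = 0,
                                    log10_density = log10(v))
  d1 <- mk_dens(c(50, 10, 30, 20, 40))
  d2 <- mk_dens(c(40, 20, 50, 10, 30))
  d3 <- mk_dens(c(30, 10, 50, 20, 40))
  rs <- build_ranking_set(list(d1, d2, d3))
  expect_equal(rs$orderings[[1]], c(1L, 5L, 3L, 4L, 2L))
  expect_equal(rs$orderings[[2]], c(3L, 1L, 5L, 2L, 4L))
  expect_equal(rs$orderings[[3]], c(3L, 5L, 1L, 4L, 2L))

  # identical densities -> identical orderings
  rs2 <- build_ranking_set(list(d1, d1))
  expect_identical(rs2$orderings[[1]], rs2$orderings[[2]])

  # tie within one sample: warning, still a permutation, id-ascending
  dt <- mk_dens(c(50, 40, 40, 20, 10))
  expect_warning(rst <- build_ranking_set(list(dt)), "tie")
  expect_equal(rst$orderings[[1]], c(1L, 2L, 3L, 4L, 5L))

  dz <- mk_dens(c(50, 40, 30, 20, 10)); dz$density_per_mm3[2] <- 0
  expect_error(build_ranking_set(list(dz), region_subset = 1:5), "zero density")
})

test_that("rankings are invariant under strictly monotone density transforms", {
  set.seed(8)
  base <- data.frame(region_id = 1:12, acronym = as.character(1:12),
                     medium_group_id = 1L,
                     integrated_intensity = NA, volume_ratio = 0,
                     log10_density = NA)
  mk <- function(v) { d <- base; d$density_per_mm3 <- v; d }
  for (i in 1:20) {
    v1 <- runif(12, 0.1, 100); v2 <- runif(12, 0.1, 100)
    rs <- build_ranking_set(list(mk(v1), mk(v2)))
    for (f in list(function(x) x^3, function(x) exp(x / 50),
                   function(x) 5 * x + 1)) {
      rs2 <- build_ranking_set(list(mk(f(v1)), mk(f(v2))))
      expect_identical(rs$orderings, rs2$orderings)
    }
  }
})

test_that("planted per-region intensities are recovered through the full stack", {
  scene <- make_test_scene(n_blobs = 12L, seed = 33L)
  spots <- run_extraction(scene$sim$volume)
  asg <- assign_spots(spots, scene$atlas)
  dens <- regional_density(asg, scene$atlas)
  # every planted center's region received signal
  planted_regions <- unique(scene$atlas$labels[scene$centers])
  expect_true(all(dens$density_per_mm3[dens$region_id %in% planted_regions] > 0))
  # gradient ordering: region with most planted blobs has highest density
  blob_regions <- scene$atlas$labels[scene$centers]
  top <- as.integer(names(which.max(table(blob_regions))))
  vols <- scene$atlas$regions$volume_mm3
  per_vol <- table(factor(blob_regions, levels = 1:4)) / vols
  expect_equal(dens$region_id[which.max(dens$density_per_mm3)],
               as.integer(names(which.max(per_vol))))
})
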