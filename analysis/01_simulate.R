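#!/usr/bin/env Rscript
# Stage 1: simulate a three-sample cohort of cleared-brain tau volumes
# with a planted regional density gradient.
#
# A shared toy atlas (ellipsoidal brain, 4 layered regions) receives
# the same blob centres in every sample; each region's blobs get a
# fixed amplitude multiplier, so every sample carries the same
# descending regional tau gradient, while per-sample noise differs.
# Volumes are written as NRRD under scratch/cohort/ (large, binary);
# the cohort description table goes to results/.

library(tauscape)
options(tauscape.quiet = TRUE)

out_data <- "scratch/cohort"
dir.create(out_data, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

shape <- c(64L, 64L, 64L)
atl <- make_toy_atlas(shape, pitch_um = 8.3, n_regions = 4L)
write_atlas(atl, file.path(out_data, "atlas_labels.nrrd"),
            file.path(out_data, "atlas_regions.csv"))

set.seed(20240207)
amp0 <- calibrate_spot_amplitude(atl, sigma_vox = 1.6,
                                 brain_background = 20,
                                 outside_background = 2, noise_sd = 0.5,
                                 seed = 20240207)

# blob centres deep inside the mask (safe against the 10 erosions)
ctr <- (shape + 1) / 2
centers <- matrix(NA_real_, 0, 3)
while (nrow(centers) < 12L) {
  cand <- round(ctr + runif(3, -0.3, 0.3) * shape)
  if (sqrt(sum(((cand - ctr) / (shape / 2 - 0.5))^2)) > 0.55) next
  if (nrow(centers) &&
      min(sqrt(rowSums(sweep(centers, 2, cand)^2))) < 10) next
  centers <- rbind(centers, cand)
}
region_of <- apply(centers, 1, function(c) atl$labels[c[1], c[2], c[3]])
# Planted per-region contrast gradient. Multipliers are kept mild and
# the blob count low so total spot intensity stays a small fraction of
# the image: the mask recipe thresholds at 1.5x the global mean, which
# assumes spots contribute negligibly to that mean (true in real
# whole-brain data, where spots occupy a tiny volume fraction).
mult <- c(1, 1.3, 1.7, 2.2)

samples <- sprintf("sample%02d", 1:3)
for (s in seq_along(samples)) {
  spots <- lapply(seq_len(nrow(centers)), function(j)
    planted_spot(centers[j, ], amplitude = amp0 * mult[region_of[j]],
                 sigma_vox = 1.6))
  sim <- make_tau_volume(atl, spots, brain_background = 20,
                         outside_background = 2, noise_sd = 0.5,
                         seed = 500 + s)
  write_volume(sim$volume, file.path(out_data,
                                     paste0(samples[s], ".nrrd")))
}

cohort <- data.frame(blob = seq_len(nrow(centers)),
                     z_vox = centers[, 1], y_vox = centers[, 2],
                     x_vox = centers[, 3], region_id = region_of,
                     amplitude = amp0 * mult[region_of])
write.csv(cohort, "results/01_cohort_blobs.csv", row.names = FALSE)
cat("wrote", length(samples), "volumes to", out_data,
    "| calibrated base amplitude:", round(amp0, 2), "\n")
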