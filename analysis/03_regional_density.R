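#!/usr/bin/env Rscript
# Stage 3: atlas assignment and regional tau density.
#
# Spot centroids are assigned to atlas regions; per-region tau density
# is summed spot intensity divided by region volume (per mm^3). One
# density table per sample under results/.

library(tauscape)
options(tauscape.quiet = TRUE)

atl <- read_atlas("scratch/cohort/atlas_labels.nrrd",
                  "scratch/cohort/atlas_regions.csv")
samples <- sprintf("sample%02d", 1:3)
for (s in samples) {
  spots <- read_spot_table(file.path("results",
                                     paste0("02_", s, "_spots.csv")))
  asg <- assign_spots(spots, atl)
  dens <- regional_density(asg, atl)
  write.csv(dens, file.path("results", paste0("03_", s, "_density.csv")),
            row.names = FALSE)
  cat(s, ": densities for ", nrow(dens), " regions\n", sep = "")
}
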