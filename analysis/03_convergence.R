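#!/usr/bin/env Rscript
# Step 3 — convergence of axon clouds in a shared target.
#
# The ET-like (from A2) and CT-like (from A3) types both innervate the
# subcortical block S2. This step rasterizes their axon clouds there,
# scores the pairwise overlap (scatter-matrix separability), estimates
# per-source KDE cloud volumes and mean axon densities, and clusters the
# target's composition of axonal lengths by contributing
# (cell type, source area).

suppressPackageStartupMessages(library(projectomer))

sc <- scenario_basic(n_per_type = 40)
pop <- generate_population(sc$atlas, sc$types, seed = 20260926)
atlas <- sc$atlas
reg <- atlas$regions
s2 <- reg$region_id[reg$area == "S2" & reg$hemisphere == "right"]

# pooled grid-interpolated cloud per source area
cloud_for <- function(source_area) {
  nrns <- Filter(function(n) n$metadata$source_area == source_area,
                 pop$neurons)
  pts <- lapply(nrns, axon_cloud_points, atlas = atlas, region_id = s2,
                hemisphere = "right", grid_spacing = 20)
  do.call(rbind, pts)
}
clouds <- list(A2 = cloud_for("A2"), A3 = cloud_for("A3"))
om <- overlap_matrix(clouds)
cat("overlap matrix of source-area axon clouds in S2:\n")
print(round(om$O, 3))
cat(sprintf("mean pairwise overlap %.2f +/- %.2f\n",
            om$summary$mean, om$summary$se))
write.table(om$O, "results/overlap_S2.tsv", sep = "\t", quote = FALSE)

# KDE volume and mean axon density per source cloud
arb <- filter_targets(decompose_population(pop$neurons, atlas))
for (src in names(clouds)) {
  kde <- kde_cloud(clouds[[src]], bandwidth = 0.3, voxel_size = 20)
  axl <- sum(arb$axon_length[arb$source_area == src & arb$region_id == s2])
  cv <- cloud_volume(kde, total_length = axl)
  cat(sprintf("%s cloud in S2: %.2g um^3 at 1%% density, %.2g um/um^3\n",
              src, cv$volume_um3, cv$mean_density))
}

# composition clustering: per target region, summed AxL by (type, source)
pass <- arb[arb$passes_filter, ]
rname <- paste(reg$area, reg$layer, reg$hemisphere)[match(pass$region_id,
                                                          reg$region_id)]
comp <- tapply(pass$axon_length,
               list(rname, paste(pass$cell_type, pass$source_area)), sum)
comp[is.na(comp)] <- 0
cc <- composition_cluster(comp)
cat("target similarity (cosine) by axonal composition:\n")
print(round(cc$target_similarity, 2))
write.table(cc$target_similarity, "results/target_similarity.tsv",
            sep = "\t", quote = FALSE)
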