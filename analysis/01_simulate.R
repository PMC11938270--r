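#!/usr/bin/env Rscript
# Simulate the study inputs: a retrograde-tracer count table over the 15
# vole-social-brain regions with three planted modules and a planted hub at
# the anterior hypothalamus (AH), plus one labeled synthetic slice image
# with known per-region cell counts. Ground truth is written as sidecar
# tables next to the data.

library(voleconnectome)

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260920

regions <- vsb_regions()
hub <- "AH"
spec <- synthetic_spec(
  n_regions = 15,
  hub_index = match(hub, regions),
  seed = seed
)
sim <- generate_count_matrix(spec)
write_counts(sim$counts, file.path(out_dir, "counts.csv"))
write.csv(data.frame(region = names(sim$truth$modules),
                     module = as.integer(sim$truth$modules),
                     hub = names(sim$truth$modules) == sim$truth$hub),
          file.path(out_dir, "counts_truth.csv"), row.names = FALSE)

cat(sprintf("count table: %d rows over %d ordered region pairs\n",
            nrow(sim$counts), nrow(unique(sim$counts[, 1:2]))))
cat(sprintf("planted hub: %s; planted modules: %s\n", sim$truth$hub,
            paste(table(sim$truth$modules), collapse = "/")))
cat(sprintf("contralateral share: %.3f (generator asks 0.15)\n",
            sum(sim$counts$count[sim$counts$side == "contra"]) /
              sum(sim$counts$count)))

# one synthetic slice: every region gets a known number of cells; VMH is
# rendered saturated to exercise the unreliable-count flagging
lm <- demo_label_map(regions, width = 360, height = 360)
cells <- setNames(rep(c(6L, 3L), c(15, 15)), lm$regions$code)  # ipsi 6, contra 3
sat_code <- lm$regions$code[lm$regions$name == "VMH" &
                              lm$regions$hemisphere == "ipsi"]
img <- generate_slice_image(image_spec(
  lm, cells, cell_radius_px = 3, cell_intensity = 30000,
  background_mean = 1000, background_sd = 200,
  saturated_regions = sat_code, seed = seed
))
write_label_map(lm, file.path(out_dir, "labels.tif"),
                file.path(out_dir, "regions.csv"))
write_slice_image(img$image, file.path(out_dir, "slice.tif"))
write.csv(img$truth, file.path(out_dir, "slice_truth.csv"),
          row.names = FALSE)
cat(sprintf("slice: %d x %d px, %d placed cells, region %d saturated\n",
            nrow(img$image), ncol(img$image), nrow(img$centers), sat_code))
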