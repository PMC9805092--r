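#!/usr/bin/env Rscript
# Generate the synthetic study: two-channel micrograph cohorts (an
# intracellular-control strain plus display strains across the realistic
# displayed-fraction range), a plate-reader calibration table, kinetic
# assays, and growth curves. Everything downstream (02-04) consumes the
# outputs of this script; ground truth travels alongside as JSON.

suppressMessages(library(surfquant))

seed <- 1L
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("Rendering micrograph cohorts (9 scenes x 25 cells per strain) ...")
strains <- list("intra-control" = 0, "display-16" = 0.16,
                "display-22" = 0.22, "display-50" = 0.5)
for (name in names(strains)) {
  for (i in 1:9) {
    sc <- generate_micrograph(scene_spec(
      n_cells = 25, image_shape = c(512, 512),
      surface_fraction_true = strains[[name]],
      seed = seed * 10000L + which(names(strains) == name) * 100L + i))
    write_scene(sc, file.path(outdir, name), sprintf("scene%02d", i))
  }
  message("  ", name, ": true displayed fraction ", strains[[name]])
}

message("Writing plate-reader calibration table (30 reference strains) ...")
tab <- generate_calibration_table(noise_sd = 0.05, seed = seed + 2L)
write.csv(tab, file.path(outdir, "calibration_table.csv"), row.names = FALSE)

message("Writing kinetic assay (12 substrate concentrations, triplicate) ...")
sp <- assay_spec(vmax_true = 1.58, km_true = 12, cell_density = 1e8,
                 seed = seed + 4L)
assay <- generate_kinetics_dataset(sp)
write.csv(assay, file.path(outdir, "kinetics_assay.csv"), row.names = FALSE)
jsonlite::write_json(unclass(sp), file.path(outdir, "kinetics_truth.json"),
                     auto_unbox = TRUE, digits = NA)

message("Writing growth curves (reference strain and a 5% defect) ...")
g <- generate_growth_curves(c(0.38, 0.40), od0 = 0.02, duration_h = 10,
                            noise_sd = 0.005, seed = seed + 5L)
write.csv(g, file.path(outdir, "growth_curves.csv"), row.names = FALSE)

message("Done: synthetic study written under ", outdir)
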