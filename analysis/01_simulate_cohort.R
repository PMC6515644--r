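#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a synthetic 2x2 cohort (APP/PS1 x apoA-I genotype, 5 animals per
# group, 3 sections each) under the default study conditions: wild-type
# groups carry no amyloid, the transgenic apoA-I-deficient group carries
# ~3.25x parenchymal and ~5x vascular amyloid and more reactive astrocytes
# than its hemizygous counterpart. Section images go to scratch/cohort/ as
# 8-bit PNGs with JSON ROIs; the design table and the ground-truth
# per-animal metric table go to results/.

suppressMessages(library(histoquant))

seed <- 20260923
outdir <- "scratch/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("generating cohort (seed ", seed, ") ...")
cohort <- generate_cohort(n_per_group = 5, sections_per_animal = 3,
                          seed = seed)

utils::write.csv(cohort$design, "results/design.csv", row.names = FALSE)
write_quant_csv(cohort$truth_records, "results/true_section_metrics.csv")
utils::write.csv(cohort$truth_table, "results/true_per_animal_metrics.csv",
                 row.names = FALSE)

manifest <- list()
for (aid in names(cohort$sections)) {
  for (sec in cohort$sections[[aid]]) {
    sid <- sec$images[[1]]$section_id
    entry <- list(section_id = sid, animal_id = aid, images = list())
    for (ch in names(sec$images)) {
      p <- file.path(outdir, paste0(sid, "_", ch, ".png"))
      write_channel_image(sec$images[[ch]], p)
      entry$images[[ch]] <- p
    }
    roi_p <- file.path(outdir, paste0(sid, "_rois.json"))
    write_roi(sec$rois, roi_p)
    entry$rois <- roi_p
    manifest[[length(manifest) + 1]] <- entry
  }
}
jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)

codes <- assign_blinding_codes(cohort$design, seed = seed)
utils::write.csv(data.frame(animal_id = names(codes), code = unname(codes)),
                 file.path(outdir, "blinding_codes.csv"), row.names = FALSE)

message("wrote ", length(manifest), " sections to ", outdir)
message("true per-animal metric table: results/true_per_animal_metrics.csv")
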