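#!/usr/bin/env Rscript

# Simulate the two-condition mislocalization experiment.
#
# Two synthetic conditions emulating the live-cell assay at its published
# scale (15 fields per condition, 3-4 cells per field, ~45 cells total,
# 512x512 EMCCD-like fields, 70% transfection efficiency):
#   active_extractase   theta = 0.05  (mislocalized reporter largely cleared)
#   inactive_extractase theta = 0.60  (reporter accumulates on mitochondria)
# Fields are written as multi-channel TIFFs under scratch/fields/ (bulky,
# regenerated at will); per-cell ground truth goes to results/tables/.

library(mitoloc)

seed <- 20260925L
out_img <- "scratch/fields"
out_tab <- "results/tables"
dir.create(out_img, recursive = TRUE, showWarnings = FALSE)
dir.create(out_tab, recursive = TRUE, showWarnings = FALSE)

conditions <- list(active_extractase = 0.05, inactive_extractase = 0.60)

for (k in seq_along(conditions)) {
  name <- names(conditions)[k]
  p <- synth_params(misloc_fraction = conditions[[k]],
                    seed = seed + 1000L * (k - 1L))
  cond <- generate_condition(p, name)
  for (f in cond$fields)
    write_field(f, file.path(out_img, paste0(f$field_id, ".tif")))
  write_truth_csv(cond$truths,
                  file.path(out_tab, paste0("truth_", name, ".csv")),
                  field_ids = vapply(cond$fields, `[[`, "", "field_id"))
  jsonlite::write_json(cond$manifest,
                       file.path(out_tab, paste0("manifest_", name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%-20s theta = %.2f   %d fields, %d cells\n", name,
              conditions[[k]], length(cond$fields),
              cond$manifest$n_cells_total))
}
cat("fields written to", out_img, "\n")
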