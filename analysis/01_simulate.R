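#!/usr/bin/env Rscript

# Stage 1: simulate a small synthetic cohort and export example data.
#
# Generates one healthy and one infarcted cine phantom, grades their image
# quality, degrades the stacks accordingly, and writes NIfTI volumes with
# JSON ground-truth sidecars plus a quality-score table to results/data/.
# The full study in 02_run_study.R regenerates its own cohort internally
# (deterministically, from the master seed); this script exists to make
# the raw data tangible and inspectable.

suppressMessages(library(cinefunc))

out_dir <- file.path("results", "data")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20240301L

healthy_cfg <- phantom_config(n_slices = 9, n_phases = 12, image_size = 96,
                              contraction_fraction = 0.37,
                              wall_thickness_px = 10,
                              empty_slice_margin = 1, seed = seed)
healthy <- generate_phantom_stack(healthy_cfg)

infarct_cfg <- phantom_config(n_slices = 9, n_phases = 12, image_size = 96,
                              contraction_fraction = 0.24,
                              wall_thickness_px = 10,
                              infarct = infarct_spec(20, 110, 0.4,
                                                     affected_slices = 4:6),
                              empty_slice_margin = 1, seed = seed + 1L)
infarct <- generate_phantom_stack(infarct_cfg)

quality <- list(healthy = quality_score(2, 1, 2),
                infarct = quality_score(3, 2, 3))
scans <- list(healthy = healthy, infarct = infarct)
rows <- list()
for (nm in names(scans)) {
  q <- quality[[nm]]
  scans[[nm]]$stack <- inject_degradation(scans[[nm]]$stack, q,
                                          seed = seed + match(nm, names(scans)))
  paths <- write_phantom_nifti(scans[[nm]], out_dir, nm)
  gt <- scans[[nm]]$ground_truth
  rows[[nm]] <- data.frame(
    scan = nm, artefacts = q$artefacts, noise = q$noise, general = q$general,
    total_quality = total_quality_score(q),
    analytic_edv_ml = gt$analytic_edv_ml,
    analytic_esv_ml = gt$analytic_esv_ml,
    analytic_ef_percent = gt$analytic_ef_percent,
    analytic_lv_mass_g = gt$analytic_lv_mass_g)
  cat(sprintf("wrote %s: %s\n", nm, paste(basename(paths), collapse = ", ")))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE)
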