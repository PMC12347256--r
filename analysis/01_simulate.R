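#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs: a texture phantom with ground-truth
# class labels (stands in for the chest CT) and a 21/51 two-group cohort
# with the published group statistics (stands in for the patient table).

library(fibroquant)

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 1

phantom <- generate_phantom(256, 256, layout_seed = seed, n_seeds = 12)
write_phantom_nifti(phantom, file.path(out, "phantom"))
fr_truth <- table(phantom$truth_labels[phantom$lung_mask])
cat("phantom: 256x256,", sum(phantom$lung_mask), "lung pixels;",
    "truth class counts:\n")
print(fr_truth)

templates <- generate_class_templates(size = 33, seed = seed + 1)
saveRDS(templates, file.path(out, "templates.rds"))

cohort <- generate_cohort(cohort_spec(seed = seed + 2))
write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
cat(sprintf("cohort: %d subjects (%d PH / %d non-PH)\n", nrow(cohort),
            sum(cohort$is_ph), sum(!cohort$is_ph)))
cat(sprintf("  diseased area: PH %.1f +/- %.1f %% vs non-PH %.1f +/- %.1f %%\n",
            mean(cohort$diseased_area[cohort$is_ph]),
            sd(cohort$diseased_area[cohort$is_ph]),
            mean(cohort$diseased_area[!cohort$is_ph]),
            sd(cohort$diseased_area[!cohort$is_ph])))
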