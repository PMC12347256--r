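#!/usr/bin/env Rscript
# Stage 4 — hemodynamic labelling: PVR from the catheterization variables,
# the wedge-pressure eligibility rule, and the PH definition
# (mPAP >= 20 mmHg and PVR >= 3 WU) applied to the simulated cohort.

library(fibroquant)

out <- "results"
cohort <- read.csv(file.path(out, "cohort.csv"))

cohort <- filter_cohort(cohort, pcwp_max = 15)
st <- classify_ph(cohort)
cohort$pvr_wu <- st$pvr_wu
cohort$pvr_dyn <- st$pvr_dyn
cohort$ph_hemodynamic <- st$is_ph

cat(sprintf("eligible subjects: %d (excluded %d with PCWP > 15 mmHg)\n",
            nrow(cohort), attr(cohort, "n_excluded")))
cat(sprintf("hemodynamic PH: %d/%d; agreement with simulated group labels: %s\n",
            sum(st$is_ph), nrow(cohort),
            ifelse(all(st$is_ph == cohort$is_ph), "exact", "IMPERFECT")))
cat(sprintf("PVR: PH %.1f +/- %.1f WU vs non-PH %.1f +/- %.1f WU\n",
            mean(cohort$pvr_wu[st$is_ph]), sd(cohort$pvr_wu[st$is_ph]),
            mean(cohort$pvr_wu[!st$is_ph]), sd(cohort$pvr_wu[!st$is_ph])))

write.csv(cohort, file.path(out, "cohort_labelled.csv"), row.names = FALSE)
cat("wrote cohort_labelled.csv\n")
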