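#!/usr/bin/env Rscript
# Stage 5 — diagnostic statistics on the labelled cohort: Mann-Whitney
# group comparison, per-marker ROC with DeLong intervals and Youden
# cutpoints, step-wise logistic augmentation (diseased area -> + RVESV ->
# + RV strain) with continuous NRI and IDI, and quadrant stratification
# by RV strain and diseased lung area.

library(fibroquant)

out <- "results"
seed <- 1
cohort <- read.csv(file.path(out, "cohort_labelled.csv"))

cmp <- compare_groups(cohort)
cat("group comparison (Mann-Whitney):\n")
print(cbind(cmp[, c("feature")],
            round(cmp[, c("mean_ph", "mean_nonph", "p")], 3)))
write.csv(cmp, file.path(out, "group_comparison.csv"), row.names = FALSE)

roc <- roc_table(cohort, directions = c(rv_strain = ">"))
cat("\nper-marker ROC:\n")
print(cbind(roc["feature"], round(roc[, c("auc", "ci_lo", "ci_hi",
                                          "threshold")], 3)))
write.csv(roc, file.path(out, "roc_table.csv"), row.names = FALSE)

sw <- stepwise_combination(cohort, "diseased_area", c("rvesv", "rv_strain"),
                           n_boot = 2000, seed = seed + 3)
cat("\nstep-wise model augmentation:\n")
print(cbind(sw["model"], round(sw[, c("auc", "nri", "nri_p", "idi",
                                      "idi_p")], 4)))
write.csv(sw, file.path(out, "model_comparison.csv"), row.names = FALSE)

thr_x <- roc$threshold[roc$feature == "rv_strain"]
thr_y <- roc$threshold[roc$feature == "diseased_area"]
quad <- quadrant_analysis(cohort$rv_strain, cohort$diseased_area,
                          cohort$is_ph, thr_x, thr_y)
cat(sprintf("\nquadrant analysis at strain >= %.1f%%, diseased area >= %.1f%%:\n",
            thr_x, thr_y))
print(quad)
jsonlite::write_json(list(thresholds = list(rv_strain = thr_x,
                                            diseased_area = thr_y),
                          quadrants = as.data.frame(quad)),
                     file.path(out, "quadrants.json"),
                     auto_unbox = TRUE, digits = NA)

ok <- tryCatch({
  grDevices::png(file.path(out, "quadrant_plot.png"), 700, 600)
  plot(cohort$rv_strain, cohort$diseased_area,
       col = ifelse(cohort$is_ph, "red", "blue"), pch = 19,
       xlab = "RV longitudinal strain (%)", ylab = "Diseased lung area (%)",
       main = "Quadrant stratification")
  abline(v = thr_x, lty = 2); abline(h = thr_y, lty = 2)
  grDevices::dev.off(); TRUE
}, error = function(e) FALSE)
cat("wrote group_comparison.csv, roc_table.csv, model_comparison.csv,",
    "quadrants.json", if (ok) "and quadrant_plot.png" else "", "\n")
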