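# End-to-end pipeline on synthetic data: simulate -> segment -> quantify
# -> cardiac metrics -> hemodynamic labels -> diagnostics, with a
# machine-readable run manifest. Stage failures abort with a stage-tagged
# message; deterministic outputs are bit-identical across reruns of the
# same configuration.

#' Default pipeline configuration
#'
#' One global seed is fanned out deterministically per stage
#' (seed + fixed offsets, kept below 2^31).
#'
#' @param out_dir output directory
#' @param seed global integer seed
#' @return nested configuration list (serializable to YAML losslessly)
#' @export
default_pipeline_config <- function(out_dir = tempfile("fibroquant_run_"),
                                    seed = 1) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(width = 160, height = 160, template_size = 33,
                   kernel = list(sigma = 3.75, window = 15),
                   histogram = list(hu_min = -1024, hu_max = 100,
                                    bin_width = 25),
                   histogram_diff = list(hu_min = 0, hu_max = 281.25,
                                         bin_width = 6.25)),
    cardiac = list(edv = 130, esv = 65, peak_strain = -15, phases = 20,
                   slice_thickness = 1),
    cohort = list(n_ph = 21, n_nonph = 51),
    hemodynamics = list(mpap_cutoff = 20, pvr_cutoff = 3, pcwp_max = 15),
    diagnostics = list(base = "diseased_area",
                       add = c("rvesv", "rv_strain"),
                       n_boot = 2000))
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file path
#' @return the configuration list
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' @rdname read_pipeline_config
#' @param config configuration list
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_msg <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                                  sprintf(...)))

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] stage failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' Simulates a phantom and a cohort, segments the phantom and quantifies
#' class fractions, computes cardiac measures on synthetic cine contours,
#' applies hemodynamic PH labelling and the wedge-pressure rule, and runs
#' the diagnostic pipeline (group comparison, per-marker ROC, step-wise
#' model augmentation with NRI/IDI, quadrant stratification). All tables
#' are written as CSV/JSON under `config$out_dir` together with a manifest
#' listing every output file with its MD5 checksum.
#'
#' @param config list as from [default_pipeline_config()] or
#'   [read_pipeline_config()]
#' @return invisibly, a list with all stage results and the manifest
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  # --- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    stage_msg("simulate", "phantom %dx%d, cohort %d/%d, seed %d",
              config$phantom$width, config$phantom$height,
              config$cohort$n_ph, config$cohort$n_nonph, seed)
    phantom <- generate_phantom(config$phantom$width, config$phantom$height,
                                layout_seed = seed)
    templates <- generate_class_templates(size = config$phantom$template_size,
                                          seed = seed + 1L)
    cohort <- generate_cohort(cohort_spec(n_ph = config$cohort$n_ph,
                                          n_nonph = config$cohort$n_nonph,
                                          seed = seed + 2L))
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    list(phantom = phantom, templates = templates, cohort = cohort)
  })

  # --- segment --------------------------------------------------------
  seg <- run_stage("segment", {
    kc <- config$phantom$kernel; hc <- config$phantom$histogram
    hd <- config$phantom$histogram_diff
    kernel <- gaussian_kernel_spec(kc$sigma, kc$window)
    hspec <- histogram_spec(hc$hu_min, hc$hu_max, hc$bin_width)
    hspec_diff <- histogram_spec(hd$hu_min, hd$hu_max, hd$bin_width)
    refs <- build_reference_histograms(sim$templates, kernel, hspec,
                                       hspec_diff)
    lm <- classify_image(sim$phantom$intensity, sim$phantom$lung_mask,
                         refs, kernel, hspec, hspec_diff)
    fr <- class_fractions(lm, sim$phantom$lung_mask,
                          sim$phantom$pixel_spacing,
                          sim$phantom$slice_thickness)
    acc <- phantom_accuracy(lm, sim$phantom,
                            border_erosion = (kernel$window - 1) / 2)
    stage_msg("segment", "pixel accuracy %.1f%%, diseased area %.1f%%",
              acc, fr$diseased_area)
    utils::write.csv(
      data.frame(class = names(fr$fractions), fraction = fr$fractions,
                 row.names = NULL),
      file.path(out_dir, "class_fractions.csv"), row.names = FALSE)
    ov <- render_overlay(sim$phantom$intensity, lm)
    png::writePNG(ov, file.path(out_dir, "overlay.png"))
    list(labelmap = lm, fractions = fr, accuracy = acc)
  })

  # --- cardiac --------------------------------------------------------
  card <- run_stage("cardiac", {
    cc <- config$cardiac
    vol_cine <- ellipsoid_cine(cc$edv, cc$esv, phases = cc$phases,
                               slice_thickness = cc$slice_thickness)
    str_cine <- shortening_cine(cc$peak_strain, phases = cc$phases)
    cm_vol <- cardiac_measures(vol_cine)
    cm_str <- cardiac_measures(str_cine)
    stage_msg("cardiac", "EDV %.1f mL, ESV %.1f mL, EF %.1f%%, peak strain %.1f%%",
              cm_vol$rvedv, cm_vol$rvesv, cm_vol$rvef,
              cm_str$peak_longitudinal_strain)
    utils::write.csv(
      data.frame(metric = c("rvedv_ml", "rvesv_ml", "rvef_pct",
                            "peak_strain_pct"),
                 value = c(cm_vol$rvedv, cm_vol$rvesv, cm_vol$rvef,
                           cm_str$peak_longitudinal_strain)),
      file.path(out_dir, "cardiac_measures.csv"), row.names = FALSE)
    list(volumes = cm_vol, strain = cm_str)
  })

  # --- hemodynamics ---------------------------------------------------
  hemo <- run_stage("hemodynamics", {
    hc <- config$hemodynamics
    cohort <- filter_cohort(sim$cohort, pcwp_max = hc$pcwp_max)
    st <- classify_ph(cohort, mpap_cutoff = hc$mpap_cutoff,
                      pvr_cutoff = hc$pvr_cutoff)
    cohort$pvr_wu <- st$pvr_wu
    cohort$ph_hemodynamic <- st$is_ph
    if (any(st$pvr_wu < 0))
      stage_msg("hemodynamics",
                "warning: negative transpulmonary gradient in %d subject(s)",
                sum(st$pvr_wu < 0))
    stage_msg("hemodynamics", "%d/%d classified PH",
              sum(st$is_ph), nrow(cohort))
    utils::write.csv(cohort, file.path(out_dir, "hemodynamics.csv"),
                     row.names = FALSE)
    cohort
  })

  # --- diagnostics ----------------------------------------------------
  diag <- run_stage("diagnostics", {
    dc <- config$diagnostics
    cmp <- compare_groups(hemo)
    roc <- roc_table(hemo, directions = c(rv_strain = ">"))
    step <- stepwise_combination(hemo, dc$base, dc$add,
                                 n_boot = dc$n_boot, seed = seed + 3L)
    thr_x <- roc$threshold[roc$feature == "rv_strain"]
    thr_y <- roc$threshold[roc$feature == "diseased_area"]
    quad <- quadrant_analysis(hemo$rv_strain, hemo$diseased_area,
                              hemo$is_ph, thr_x, thr_y)
    stage_msg("diagnostics",
              "AUC base %.3f -> +%s %.3f", step$auc[1], dc$add[1],
              step$auc[2])
    utils::write.csv(cmp, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(roc, file.path(out_dir, "roc_table.csv"),
                     row.names = FALSE)
    utils::write.csv(step, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = as.list(attr(quad, "thresholds")),
           quadrants = as.data.frame(quad)),
      file.path(out_dir, "quadrants.json"), auto_unbox = TRUE, digits = NA)
    list(comparison = cmp, roc = roc, stepwise = step, quadrants = quad)
  })

  # --- manifest -------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("fibroquant")),
    config = config[setdiff(names(config), "out_dir")],
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_msg("pipeline", "wrote %d files to %s", length(files) + 1L, out_dir)

  invisible(list(simulate = sim, segment = seg, cardiac = card,
                 hemodynamics = hemo, diagnostics = diag,
                 manifest = manifest, out_dir = out_dir))
}
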