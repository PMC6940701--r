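#' Analysis presets mirroring the study design
#'
#' Each preset names a tissue, the grouping variable or regression predictor,
#' its nuisance covariate list and the significance policy. Group contrasts
#' use FWE alpha = 0.001; regressions use FWE alpha = 0.05 with Bonferroni
#' adjustment over the 2 regressions sharing a tissue family (0.025).
#' Among the clinical variables, onset-type, D50, rD50, age, sex and total
#' intracranial volume act as nuisance covariates whenever they are not the
#' primary read-out; descriptor covariates/predictors enter natural-log
#' transformed.
#'
#' @return named list of preset definitions
#' @export
analysis_presets <- function() {
  list(
    als_vs_control = list(
      kind = "group", groups = c("control", "ALS"), tissue = c("GM", "WM"),
      nuisance = c("age", "sex", "tiv"), alpha = 0.001,
      direction = "decrease"),
    bulbar_vs_limb = list(
      kind = "group", groups = c("limb", "bulbar"), tissue = c("GM", "WM"),
      nuisance = c("log_d50", "log_rd50", "age", "sex", "tiv"),
      alpha = 0.001, direction = "decrease"),
    phaseI_vs_phaseII = list(
      kind = "group", groups = c("I", "II"), tissue = c("GM", "WM"),
      nuisance = c("onset_type", "age", "sex", "tiv", "log_d50"),
      alpha = 0.001, direction = "decrease"),
    high_vs_low_aggressiveness = list(
      kind = "group", groups = c("low", "high"), tissue = c("GM", "WM"),
      nuisance = c("onset_type", "age", "sex", "tiv", "log_rd50"),
      alpha = 0.001, direction = "decrease"),
    regression_rd50 = list(
      kind = "regression", predictor = "log_rd50", tissue = c("GM", "WM"),
      nuisance = c("tiv"), alpha = 0.05, bonferroni_family = 2,
      direction = "negative"),
    regression_cfs = list(
      kind = "regression", predictor = "log_cfs", tissue = c("GM", "WM"),
      nuisance = c("tiv"), alpha = 0.05, bonferroni_family = 2,
      direction = "positive"),
    regression_d50 = list(
      kind = "regression", predictor = "log_d50", tissue = "WM",
      nuisance = c("tiv"), alpha = 0.05, bonferroni_family = 2,
      direction = "positive"),
    regression_cfl = list(
      kind = "regression", predictor = "log_cfl", tissue = "WM",
      nuisance = c("tiv"), alpha = 0.05, bonferroni_family = 2,
      direction = "negative"))
}

# encode nuisance covariates as numeric design columns
nuisance_columns <- function(tab, nuisance) {
  cols <- lapply(nuisance, function(v) {
    x <- tab[[v]]
    if (v == "sex") as.numeric(x == "male")
    else if (v == "onset_type") as.numeric(x == "bulbar")
    else as.numeric(x)
  })
  names(cols) <- nuisance
  as.data.frame(cols)
}

#' Build the design matrix for a group preset
#'
#' Intercept + group indicator (second listed group coded 1) + nuisance
#' columns; the contrast tests density decrease in the second group
#' (indicator weight -1).
#'
#' @param tab cohort table rows for the subjects analysed, in subject order
#' @param preset a preset from \code{\link{analysis_presets}}
#' @param group_values the grouping value per subject
#' @return a \code{\link{vbm_design}}
#' @export
preset_design <- function(tab, preset, group_values) {
  ind <- as.numeric(group_values == preset$groups[2])
  df <- cbind(data.frame(intercept = 1, group = ind),
              nuisance_columns(tab, preset$nuisance))
  w <- rep(0, ncol(df)); names(w) <- names(df)
  w["group"] <- if (identical(preset$direction, "decrease")) -1 else 1
  vbm_design(df, w)
}

#' Pipeline configuration
#'
#' @param seed master seed; every random stage derives its stream from it
#' @param n_patients,n_controls cohort sizes
#' @param dim3 synthetic grid dimensions
#' @param voxel_size mm per voxel
#' @param fwhm_mm smoothing kernel FWHM in mm
#' @param mask_threshold absolute implicit-masking threshold
#' @param noise_sd voxel noise SD in density units
#' @param effect_size planted fractional density reduction per unit predictor
#' @param n_perm permutations per contrast
#' @param presets names of presets to run (subset of
#'   \code{\link{analysis_presets}})
#' @param noise_width ALSFRS-R visit noise half-width in points
#' @export
pipeline_config <- function(seed = 1, n_patients = 85, n_controls = 62,
                            dim3 = c(32, 32, 32), voxel_size = 4,
                            fwhm_mm = 8, mask_threshold = 0.2,
                            noise_sd = 0.05, effect_size = 0.1,
                            n_perm = 1000,
                            presets = c("als_vs_control",
                                        "high_vs_low_aggressiveness"),
                            noise_width = 2) {
  stopifnot(n_patients >= 1, n_perm >= 100,
            all(presets %in% names(analysis_presets())))
  as.list(environment())
}

plant_predictors <- function(tab_row, regions) {
  # planted biology: GM loss scales with disease covered (phase via rd50),
  # WM loss with aggressiveness (high = 1); controls carry no effect
  vapply(regions, function(r) {
    if (tab_row$group != "ALS") return(0)
    if (r$tissue == "GM") min(tab_row$rd50 / 0.5, 1.5)
    else as.numeric(tab_row$aggressiveness == "high")
  }, 0)
}

#' Generate smoothed subject volumes for a staged cohort
#'
#' One GM and one WM volume per subject: template times planted regional
#' effects plus voxel noise, then Gaussian smoothing. GM effects scale with
#' disease covered (rD50), WM effects with the high-aggressiveness
#' indicator; controls get the unmodified template plus noise.
#'
#' @param tab a \code{cohort_table}
#' @param config a \code{\link{pipeline_config}}
#' @param regions effect regions (default \code{default_effect_regions})
#' @return list with per-tissue volume lists and masks
#' @export
generate_study_volumes <- function(tab, config = pipeline_config(),
                                   regions = default_effect_regions(
                                     config$dim3, config$effect_size)) {
  templates <- list(
    GM = make_template("GM", config$dim3, config$voxel_size,
                       seed = config$seed),
    WM = make_template("WM", config$dim3, config$voxel_size,
                       seed = config$seed))
  out <- list()
  for (tissue in c("GM", "WM")) {
    vols <- lapply(seq_len(nrow(tab)), function(i) {
      pred <- plant_predictors(tab[i, ], regions)
      v <- generate_subject_volume(
        templates[[tissue]], pred, regions, noise_sd = config$noise_sd,
        seed = subject_seed(config$seed, i,
                            stream = if (tissue == "GM") 4L else 5L),
        subject_id = tab$patient_id[i])
      gaussian_smooth(v, fwhm_mm = config$fwhm_mm)
    })
    out[[tissue]] <- list(volumes = vols,
                          mask = implicit_mask(vols, config$mask_threshold),
                          template = templates[[tissue]])
  }
  out$regions <- regions
  out
}

run_one_preset <- function(name, preset, tab, study, config) {
  res <- list()
  for (tissue in preset$tissue) {
    Y <- stack_volumes(study[[tissue]]$volumes)
    mask <- study[[tissue]]$mask
    if (preset$kind == "group") {
      gv <- switch(name,
                   als_vs_control = tab$group,
                   bulbar_vs_limb = tab$onset_type,
                   phaseI_vs_phaseII = tab$phase,
                   high_vs_low_aggressiveness = tab$aggressiveness)
      sel <- which(gv %in% preset$groups &
                     (tab$group == "control" | tab$converged %in% TRUE))
      design <- preset_design(tab[sel, ], preset, gv[sel])
      alpha <- preset$alpha
      r <- permutation_fwe(Y[sel, , drop = FALSE], design, mask,
                           n_perm = config$n_perm,
                           seed = subject_seed(config$seed,
                                               match(name, names(analysis_presets())),
                                               stream = 6L),
                           alpha = alpha)
    } else {
      sel <- which(tab$group == "ALS" & tab$converged %in% TRUE)
      alpha <- bonferroni_threshold(preset$alpha, preset$bonferroni_family)
      r <- masked_regression(
        Y[sel, , drop = FALSE], tab[[preset$predictor]][sel],
        covariates = nuisance_columns(tab[sel, ], preset$nuisance),
        restrict_mask = mask, n_perm = config$n_perm,
        seed = subject_seed(config$seed,
                            match(name, names(analysis_presets())),
                            stream = 6L),
        alpha = alpha, negative = identical(preset$direction, "negative"))
    }
    res[[tissue]] <- list(result = r, alpha = alpha,
                          clusters = extract_clusters(r, alpha))
  }
  res
}

#' Run the full synthetic pipeline
#'
#' Simulate a cohort, fit the D50 model per patient, stage the cohort,
#' generate synthetic GM/WM volumes with planted effects, run the configured
#' analysis presets and write all outputs to a run directory: the clinical
#' CSV, the cohort table, per-contrast cluster CSVs, NIfTI statistic maps, a
#' JSON config snapshot and a run log. Identical config and seed give
#' identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir run directory (created; default a tempdir subdirectory)
#' @param write_nifti_maps write t/TFCE/FWE-p maps as NIfTI (default TRUE)
#' @return invisibly, a list with the cohort table, study volumes, per-preset
#'   results and the run directory
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = file.path(tempdir(),
                                             paste0("d50vbm_run_",
                                                    config$seed)),
                         write_nifti_maps = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("d50vbm pipeline run, seed %d", config$seed))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("simulate", sample_cohort(config$n_patients,
                                            config$n_controls, config$seed))
  series <- stage("simulate",
                  simulate_cohort_series(cohort, config$noise_width,
                                         config$seed))
  write_alsfrs_csv(series, file.path(out_dir, "alsfrs.csv"))
  fitres <- stage("fit", fit_cohort(series))
  tab <- stage("stage", build_cohort_table(fitres$fits,
                                           controls = cohort$controls))
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  study <- stage("volumes", generate_study_volumes(tab, config))
  results <- list()
  for (name in config$presets) {
    preset <- analysis_presets()[[name]]
    results[[name]] <- stage(name, run_one_preset(name, preset, tab, study,
                                                  config))
    for (tissue in names(results[[name]])) {
      slot <- results[[name]][[tissue]]
      utils::write.csv(slot$clusters,
                       file.path(out_dir, sprintf("clusters_%s_%s.csv",
                                                  name, tissue)),
                       row.names = FALSE)
      if (write_nifti_maps) {
        write_nifti(slot$result$t_map,
                    file.path(out_dir, sprintf("tmap_%s_%s.nii.gz",
                                               name, tissue)),
                    config$voxel_size)
        write_nifti(slot$result$tfce_map,
                    file.path(out_dir, sprintf("tfce_%s_%s.nii.gz",
                                               name, tissue)),
                    config$voxel_size)
        write_nifti(slot$result$fwe_p_map,
                    file.path(out_dir, sprintf("fwep_%s_%s.nii.gz",
                                               name, tissue)),
                    config$voxel_size)
      }
      log_lines <- c(log_lines,
                     sprintf("%s/%s: alpha = %g, %d significant cluster(s)",
                             name, tissue, slot$alpha, nrow(slot$clusters)))
    }
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(table = tab, study = study, results = results,
                 out_dir = out_dir, config = config))
}
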