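# Pipeline orchestration: configuration, simulate / analyze / report
# stages, and the run manifest. A thin command-line wrapper over these
# functions ships in `inst/cli/redoxflim.R`.

#' Run configuration
#'
#' @param seed Integer master seed.
#' @param output_dir Output directory (created if missing).
#' @param preset_file Optional YAML preset file; `NULL` calibrates the
#'   defaults.
#' @param stages Named logical toggles: `cohort`, `spectra`, `flim`.
#' @param n_spectra Spectra TSVs written per group (0 = none).
#' @param n_flim_images FLIM TIFFs written per group.
#' @param f_mod Modulation frequency in Hz.
#' @param peak_window Peak read half-width in nm.
#' @param cv_repeats,cv_folds Cross-validation plan.
#' @param model Reporting model from the zoo.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = "redoxflim_run",
                       preset_file = NULL,
                       stages = c(cohort = TRUE, spectra = TRUE, flim = TRUE),
                       n_spectra = 3, n_flim_images = 1,
                       f_mod = 1e7, peak_window = 2,
                       cv_repeats = 50, cv_folds = 5, model = "svc") {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 preset_file = preset_file, stages = stages,
                 n_spectra = n_spectra, n_flim_images = n_flim_images,
                 f_mod = f_mod, peak_window = peak_window,
                 cv_repeats = cv_repeats, cv_folds = cv_folds,
                 model = model),
            class = "run_config")
}

config_presets <- function(config) {
  if (!is.null(config$preset_file)) read_presets_yaml(config$preset_file)
  else default_presets()
}

write_manifest <- function(dir, files, config, stage) {
  manifest <- list(stage = stage, seed = config$seed,
                   files = as.list(files))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Simulate stage: cohort CSV, spectra TSVs and FLIM TIFFs
#'
#' Generates the calibrated synthetic cohort, writes it as CSV, and (per
#' stage toggles) writes per-sample emission-spectrum TSVs and per-group
#' FLIM images, plus a manifest JSON listing every file and the seed. The
#' artifact tree is deterministic under the configured seed.
#'
#' @param config A [run_config()].
#' @return Invisible list with the cohort and the manifest path.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- config_presets(config)
  components <- attr(presets, "components")
  endpoints <- attr(presets, "abundance_endpoints")
  files <- character(0)

  cohort <- generate_cohort(presets, seed = config$seed)
  if (isTRUE(config$stages[["cohort"]])) {
    f <- file.path(config$output_dir, "cohort.csv")
    write_cohort_csv(cohort, f)
    files <- c(files, f)
  }
  if (isTRUE(config$stages[["spectra"]]) && config$n_spectra > 0) {
    set.seed(derive_seed(config$seed, 2L))
    sp_dir <- file.path(config$output_dir, "spectra")
    dir.create(sp_dir, showWarnings = FALSE)
    for (gr in names(presets)) {
      p <- presets[[gr]]
      st <- sample_metabolic_state(p, config$n_spectra, endpoints)
      for (i in seq_len(config$n_spectra)) {
        sp <- emission_spectrum(components, st$abundances[i, ] *
                                  p$amplitude_total)
        f <- file.path(sp_dir, sprintf("%s_%03d_roi1.tsv", gr, i))
        write_spectrum_tsv(sp, f)
        files <- c(files, f)
      }
    }
  }
  if (isTRUE(config$stages[["flim"]]) && config$n_flim_images > 0) {
    set.seed(derive_seed(config$seed, 3L))
    im_dir <- file.path(config$output_dir, "flim")
    dir.create(im_dir, showWarnings = FALSE)
    for (gr in names(presets)) {
      med_tau <- presets[[gr]]$marginals$tau_ns$m
      for (i in seq_len(config$n_flim_images)) {
        img <- generate_flim_image(med_tau, n_pixels = 64)
        f <- file.path(im_dir, sprintf("%s_%03d.tif", gr, i))
        write_flim_tiff(img, f)
        files <- c(files, f)
      }
    }
  }
  manifest <- write_manifest(config$output_dir, files, config, "simulate")
  invisible(list(cohort = cohort, files = files, manifest = manifest))
}

#' Analyze stage: statistics battery, regression and classification
#'
#' Runs the descriptive/inferential battery, the R_flavin-vs-redox-ratio
#' regression and the repeated-CV classification protocol on a cohort, and
#' writes the battery CSV, a regression JSON, the aggregated confusion
#' counts CSV and a metrics JSON (per-class SE/SP, macro F).
#'
#' @param config A [run_config()].
#' @param cohort Cohort `data.frame` or path to a cohort CSV; defaults to
#'   `cohort.csv` inside the output directory.
#' @return Invisible list with battery, regression, confusion and manifest
#'   path.
#' @export
cmd_analyze <- function(config = run_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- file.path(config$output_dir, "cohort.csv")
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  battery <- hypothesis_battery(cohort)
  f_battery <- file.path(config$output_dir, "battery.csv")
  utils::write.csv(battery_table(battery), f_battery, row.names = FALSE)
  files <- c(files, f_battery)

  reg <- metric_regression(cohort$r_flavin, cohort$redox_ratio)
  f_reg <- file.path(config$output_dir, "regression.json")
  jsonlite::write_json(reg, f_reg, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_reg)

  ft <- feature_table(cohort)
  preds <- repeated_stratified_cv(ft$features, ft$labels, ft$ids,
                                  model = config$model,
                                  n_folds = config$cv_folds,
                                  n_repeats = config$cv_repeats,
                                  seed = derive_seed(config$seed, 4L))
  confusion <- aggregate_confusion(preds)
  f_counts <- file.path(config$output_dir, "confusion_counts.csv")
  utils::write.csv(as.data.frame(confusion$counts), f_counts,
                   row.names = TRUE)
  f_metrics <- file.path(config$output_dir, "classification.json")
  jsonlite::write_json(
    list(model = config$model,
         n_models = attr(preds, "n_models"),
         n_predictions = nrow(preds),
         macro_f = macro_f_score(preds),
         se_percent = as.list(confusion$se_percent),
         sp_percent = as.list(confusion$sp_percent)),
    f_metrics, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_counts, f_metrics)

  manifest <- write_manifest(config$output_dir, files, config, "analyze")
  invisible(list(battery = battery, regression = reg,
                 confusion = confusion, predictions = preds,
                 files = files, manifest = manifest))
}

#' Report stage: plot-ready summaries
#'
#' Writes violin summaries (kernel-density points, medians and
#' significance stars per group and metric), the normalized group-average
#' spectra table, and row-normalized confusion-figure data as JSON/CSV.
#'
#' @param config A [run_config()].
#' @param analysis Output of [cmd_analyze()]; re-run if `NULL`.
#' @param cohort Cohort used for the violin summaries (data.frame or CSV
#'   path).
#' @return Invisible list of written files and the manifest path.
#' @export
cmd_report <- function(config = run_config(), analysis = NULL, cohort = NULL) {
  if (is.null(cohort)) cohort <- file.path(config$output_dir, "cohort.csv")
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (is.null(analysis)) analysis <- cmd_analyze(config, cohort)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  battery <- analysis$battery
  violins <- lapply(METRIC_NAMES, function(me) {
    per_group <- lapply(intersect(GROUP_LEVELS, unique(as.character(cohort$group))),
                        function(gr) {
      v <- cohort[[me]][cohort$group == gr]
      d <- stats::density(v, n = 64)
      b <- battery[battery$metric == me & battery$group == gr, ]
      list(group = gr, median = unname(stats::median(v)),
           p_value = if (is.na(b$p_value)) NULL else b$p_value,
           stars = b$stars, x = d$x, y = d$y)
    })
    list(metric = me, groups = per_group)
  })
  f_violin <- file.path(config$output_dir, "violin_summary.json")
  jsonlite::write_json(violins, f_violin, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_violin)

  presets <- config_presets(config)
  spectra <- group_central_spectra(presets)
  tab <- data.frame(wavelength_nm = spectra[[1]]$wavelengths)
  for (gr in names(spectra)) tab[[gr]] <- spectra[[gr]]$intensities
  f_spec <- file.path(config$output_dir, "average_spectra.csv")
  utils::write.csv(tab, f_spec, row.names = FALSE)
  files <- c(files, f_spec)

  conf <- analysis$confusion
  f_conf <- file.path(config$output_dir, "confusion_figure.json")
  jsonlite::write_json(
    list(classes = rownames(conf$counts),
         detection_prob = apply(conf$detection_prob, 1, as.list),
         counts = apply(conf$counts, 1, as.list),
         se_percent = as.list(conf$se_percent),
         sp_percent = as.list(conf$sp_percent)),
    f_conf, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_conf)

  manifest <- write_manifest(config$output_dir, files, config, "report")
  invisible(list(files = files, manifest = manifest))
}
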