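## End-to-end driver: simulate -> perturb/extract -> robustness -> select ->
## classify, writing all artefacts to a run directory.

#' Run the full robustness-and-classification workflow
#'
#' Generates (or loads) a cohort, extracts the 93 features for every mask
#' variant under the requested settings, builds per-setting robustness
#' tables, selects excellently robust then non-redundant features, and runs
#' the calcium-only / radiomics-only / integrated classifier comparison for
#' each setting. All tables are written as CSV/JSON under `outDir` together
#' with a run log.
#'
#' @param config a [phantomConfig()] (ignored when `manifest` is given).
#' @param settings list of [SettingSpec-class]; default: original and
#'   resegmented schemes at fixed bin width 25 for the config's mode.
#' @param outDir output directory.
#' @param manifest optional cohort manifest CSV to load instead of
#'   simulating.
#' @param spec classifier specification (default elastic net).
#' @param minVoxels ROI size guard.
#' @param cvSeed fold shuffle seed.
#' @return invisibly, a list with the cohort, feature store, per-setting
#'   robustness tables, selected features and comparison reports.
#' @export
runPipeline <- function(config = phantomConfig(), settings = NULL,
                        outDir = tempfile("radicc_run_"), manifest = NULL,
                        spec = modelZoo()$elastic_net, minVoxels = 10,
                        cvSeed = 42) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outDir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  step <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }
  cohort <- step("simulate", {
    if (is.null(manifest)) {
      logmsg("simulating cohort: %d patients, %s, texture effect %.2f, seed %d",
             config$nPatients, config$mode, config$textureEffect,
             config$seed)
      generateCohort(config)
    } else {
      logmsg("loading cohort from %s", manifest)
      readCohort(manifest)
    }
  })
  utils::write.csv(cohortManifest(cohort),
                   file.path(outDir, "cohort_manifest.csv"),
                   row.names = FALSE)
  mode <- if (dim(cohort[[1]]@image)[3] == 1) "single_slice"
          else "multi_slice"
  if (is.null(settings))
    settings <- list(
      settingSpec("original", "fixed_bin_width", 25, mode),
      settingSpec("resegmented", "fixed_bin_width", 25, mode))
  se <- step("extract", {
    logmsg("extracting %d features x %d settings", 93L, length(settings))
    extractFeatures(cohort, settings, minVoxels = minVoxels)
  })
  results <- list()
  for (setting in settings) {
    sid <- setting@id
    rt <- step("robustness", robustnessTable(se, sid))
    utils::write.csv(rt, file.path(outDir, paste0("robustness_", sid,
                                                  ".csv")),
                     row.names = FALSE)
    utils::write.csv(robustnessSummary(rt),
                     file.path(outDir, paste0("robustness_summary_", sid,
                                              ".csv")),
                     row.names = FALSE)
    excellent <- rt$feature[rt$category == "excellent"]
    logmsg("%s: %d excellent / %d moderate / %d poor", sid,
           sum(rt$category == "excellent"), sum(rt$category == "moderate"),
           sum(rt$category %in% c("poor", "undefined")))
    if (length(excellent) < 2) {
      logmsg("%s: too few robust features for classification; skipped", sid)
      results[[sid]] <- list(robustness = rt, selected = excellent)
      next
    }
    tab <- featureTable(se, sid)
    selected <- step("select",
                     redundancyFilter(tab[, excellent, drop = FALSE],
                                      tab$label))
    logmsg("%s: %d non-redundant robust features", sid, length(selected))
    cmp <- step("classify",
                compareModels(tab, selected, spec = spec, seed = cvSeed))
    if (!is.null(cmp$integrated$coefficients))
      utils::write.csv(cmp$integrated$coefficients,
                       file.path(outDir, paste0("coefficients_", sid,
                                                ".csv")))
    summary_row <- data.frame(
      setting = sid,
      auc_calcium = cmp$calcium$mean_auc,
      auc_radiomics = cmp$radiomics$mean_auc,
      auc_integrated = cmp$integrated$mean_auc,
      p_wilcoxon_int_vs_cal = cmp$wilcoxon_integrated_vs_calcium,
      p_delong_int_vs_cal = cmp$delong_integrated_vs_calcium$p)
    jsonlite::write_json(
      list(setting = sid, selected = selected,
           calcium = cmp$calcium[c("mean_auc", "sd_auc", "mean_accuracy")],
           radiomics = cmp$radiomics[c("mean_auc", "sd_auc",
                                       "mean_accuracy")],
           integrated = cmp$integrated[c("mean_auc", "sd_auc",
                                         "mean_accuracy")]),
      file.path(outDir, paste0("cv_", sid, ".json")), auto_unbox = TRUE)
    logmsg("%s: mean AUC calcium %.3f, radiomics %.3f, integrated %.3f", sid,
           cmp$calcium$mean_auc, cmp$radiomics$mean_auc,
           cmp$integrated$mean_auc)
    results[[sid]] <- list(robustness = rt, selected = selected,
                           comparison = cmp, summary = summary_row)
  }
  summ <- do.call(rbind, lapply(results, function(r)
    if (!is.null(r$summary)) r$summary))
  if (!is.null(summ))
    utils::write.csv(summ, file.path(outDir, "classification_summary.csv"),
                     row.names = FALSE)
  logmsg("pipeline complete: %s", outDir)
  invisible(list(cohort = cohort, features = se, settings = settings,
                 results = results, outDir = outDir))
}
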