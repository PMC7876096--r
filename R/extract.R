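## Cohort-level feature extraction into a SummarizedExperiment: rows are the
## 93 features (class in rowData), columns are (artery, mask variant,
## setting) triples with covariates in colData.

#' Extract features for a cohort across variants and settings
#'
#' For each artery, generates the perturbation variant ladder dictated by
#' each setting's scheme/mode (resegmented schemes never erode) and computes
#' the 93 features per variant. Arteries whose mandated variants fail the
#' minimum-size guard are excluded with a message.
#'
#' @param cohort list of [ArterySample-class].
#' @param settings list of [SettingSpec-class].
#' @param minVoxels minimum ROI voxels for eroded/resegmented variants.
#' @param perturb logical; FALSE extracts the original mask only.
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assay "features" (93 x n columns) and colData sample_id,
#'   patient_id, side, label, calcium_score, variant, setting_id.
#' @export
extractFeatures <- function(cohort, settings, minVoxels = 10,
                            perturb = TRUE) {
  if (is(settings, "SettingSpec")) settings <- list(settings)
  reg <- featureRegistry()
  cols <- list(); vals <- list()
  for (s in cohort) {
    sid <- paste(s@patientId, s@label, sep = "_")
    for (setting in settings) {
      policy <- if (setting@scheme == "resegmented") "resegmented"
                else setting@mode
      variants <- if (perturb) {
        tryCatch(generateVariants(s@mask, policy, minVoxels = minVoxels),
                 error = function(e) NULL)
      } else list(original = s@mask)
      if (is.null(variants)) {
        message(sprintf("extractFeatures: %s excluded under %s (%s)",
                        sid, setting@id, "variant below size guard"))
        next
      }
      for (vn in names(variants)) {
        fv <- tryCatch(
          extractAll(s@image, variants[[vn]], setting,
                     minVoxels = minVoxels),
          error = function(e) NULL)
        if (is.null(fv)) {
          message(sprintf("extractFeatures: %s/%s excluded under %s",
                          sid, vn, setting@id))
          next
        }
        vals[[length(vals) + 1L]] <- fv
        cols[[length(cols) + 1L]] <- data.frame(
          sample_id = sid, patient_id = s@patientId, side = s@side,
          label = s@label, calcium_score = s@calciumScore, variant = vn,
          setting_id = setting@id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(vals) == 0) stop("extractFeatures: nothing extracted")
  m <- do.call(cbind, vals)
  rownames(m) <- reg$feature
  cd <- do.call(rbind, cols)
  colnames(m) <- paste(cd$sample_id, cd$variant, cd$setting_id, sep = ".")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(class = reg$class, row.names = reg$feature),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(m)))
}

#' Feature table for classification (original masks, one setting)
#'
#' Builds the arteries x features table used by the classifiers from an
#' extraction result, keeping only the "original" variant of the given
#' setting, with labels and the calcium covariate attached.
#'
#' @param se result of [extractFeatures()].
#' @param settingId setting to use.
#' @param features optional character vector restricting the columns.
#' @return data.frame with patient_id, label (factor culprit/non_culprit),
#'   calcium_score and one column per feature.
#' @export
featureTable <- function(se, settingId, features = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- cd$setting_id == settingId & cd$variant == "original"
  if (!any(keep)) stop("featureTable: no columns for setting ", settingId)
  a <- t(SummarizedExperiment::assay(se)[, keep, drop = FALSE])
  cd <- cd[keep, , drop = FALSE]
  if (!is.null(features)) a <- a[, features, drop = FALSE]
  out <- data.frame(patient_id = cd$patient_id,
                    label = factor(cd$label,
                                   levels = c("non_culprit", "culprit")),
                    calcium_score = cd$calcium_score,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(a, check.names = FALSE))
}
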