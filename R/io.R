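## NIfTI round-trip for volumes/masks and CSV manifests.

#' Write a volume or mask as NIfTI
#'
#' Depth-1 (single-slice) volumes are written with an explicit third
#' dimension so that slice thickness survives the round-trip.
#'
#' @param x a [CTVolume-class] or [VoxelMask-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  v <- voxelData(x)
  nim <- oro.nifti::nifti(v, datatype = 64, bitpix = 64)
  nim@pixdim <- c(1, voxelSpacing(x), rep(0, 4))
  gz <- grepl("\\.gz$", path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(nim, stem, gzipped = gz)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param mask logical; return a [VoxelMask-class] instead of a
#'   [CTVolume-class].
#' @return a [CTVolume-class] or [VoxelMask-class].
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("readVolume: no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, 3))[1:3]          # depth-1 volumes read back as 2D
  v <- array(as.numeric(img), dim = dim(img))
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (mask) voxelMask(v, sp) else ctVolume(v, sp)
}

#' Write a cohort to disk (NIfTI volumes + manifest CSV)
#'
#' @param cohort list of [ArterySample-class].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    stem <- paste(s@patientId, s@label, sep = "_")
    ipath <- file.path(dir, paste0(stem, "_image.nii.gz"))
    mpath <- file.path(dir, paste0(stem, "_mask.nii.gz"))
    writeVolume(s@image, ipath)
    writeVolume(s@mask, mpath)
    data.frame(patient_id = s@patientId, side = s@side, label = s@label,
               calcium_score = s@calciumScore, image_path = ipath,
               mask_path = mpath, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest and its volumes
#'
#' Validates the pairing invariant (one culprit and one non-culprit per
#' patient) before loading.
#'
#' @param path manifest CSV written by [writeCohort()].
#' @return list of [ArterySample-class].
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("readCohort: no such file: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "side", "label", "calcium_score", "image_path",
            "mask_path")
  if (nrow(mf) == 0) stop("readCohort: empty manifest")
  if (!all(need %in% names(mf)))
    stop("readCohort: manifest must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(mf[, c("patient_id", "label")]))
    stop("readCohort: duplicated (patient, label) pair in manifest")
  cohort <- lapply(seq_len(nrow(mf)), function(i) {
    new("ArterySample", patientId = mf$patient_id[i], side = mf$side[i],
        label = mf$label[i], image = readVolume(mf$image_path[i]),
        mask = readVolume(mf$mask_path[i], mask = TRUE),
        calciumScore = mf$calcium_score[i])
  })
  validateCohort(cohort)
  cohort
}
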