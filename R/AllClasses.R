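#' @import methods
#' @importFrom stats median quantile rnorm runif rlnorm sd var cor rbinom
#'   pnorm setNames aggregate predict coef
NULL

#' CTVolume: a 3D scalar image in Hounsfield units
#'
#' Container for a calibrated CT volume: a 3D array of Hounsfield-unit (HU)
#' values plus the physical voxel spacing and origin in millimetres.
#' Single-slice acquisitions are stored as depth-1 arrays.
#'
#' @slot values 3D numeric array of HU values (finite).
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), position of the first voxel centre in mm.
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0))
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite reals (mm)")
  if (length(msg)) msg else TRUE
})

#' VoxelMask: a binary segmentation mask on a voxel grid
#'
#' Binary region/volume of interest aligned with a [CTVolume-class]. Values
#' are stored as a 3D 0/1 array; the mask must contain at least one
#' foreground voxel and share the grid of its paired image.
#'
#' @slot values 3D array of 0/1.
#' @slot spacing numeric(3), voxel spacing in mm (must equal the image's).
#' @export
setClass("VoxelMask",
  representation(values = "array", spacing = "numeric")
)

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(object@values %in% c(0, 1)))
    msg <- c(msg, "mask values must be binary (0/1)")
  if (sum(object@values) < 1)
    msg <- c(msg, "mask must contain at least one foreground voxel")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive reals (mm)")
  if (length(msg)) msg else TRUE
})

#' ArterySample: one carotid artery with image, mask and covariates
#'
#' @slot patientId character scalar.
#' @slot side "left" or "right".
#' @slot label "culprit" or "non_culprit".
#' @slot image a [CTVolume-class].
#' @slot mask a [VoxelMask-class] on the same grid.
#' @slot calciumScore non-negative real (arbitrary units, Agatston-like).
#' @export
setClass("ArterySample",
  representation(patientId = "character", side = "character",
                 label = "character", image = "CTVolume",
                 mask = "VoxelMask", calciumScore = "numeric")
)

setValidity("ArterySample", function(object) {
  msg <- character()
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (!object@label %in% c("culprit", "non_culprit"))
    msg <- c(msg, "label must be 'culprit' or 'non_culprit'")
  if (!identical(dim(object@image@values), dim(object@mask@values)))
    msg <- c(msg, "image and mask must share the same grid")
  if (max(abs(object@image@spacing - object@mask@spacing)) > 1e-9)
    msg <- c(msg, "image and mask must share the same spacing")
  if (length(object@calciumScore) != 1L || is.na(object@calciumScore) ||
      object@calciumScore < 0)
    msg <- c(msg, "calciumScore must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' SettingSpec: one cell of the pre-processing / quantisation grid
#'
#' A setting combines a pre-processing scheme (original, normalised,
#' resegmented), a grey-level quantisation method (fixed bin width or fixed
#' bin number) with its value, the analysis mode (single- or multi-slice)
#' and, for multi-slice, the image interpolator used for isotropic
#' resampling.
#'
#' @slot id character identifier, stable across runs.
#' @slot scheme one of "original", "normalised", "resegmented".
#' @slot quantMethod "fixed_bin_width" or "fixed_bin_number".
#' @slot quantValue positive number (bin width in HU, or bin count).
#' @slot mode "single_slice" or "multi_slice".
#' @slot interpolation "bspline" or "linear" (multi-slice only; ignored in
#'   single-slice mode).
#' @slot resegRange numeric(2) HU window, inclusive, used when
#'   scheme == "resegmented".
#' @export
setClass("SettingSpec",
  representation(id = "character", scheme = "character",
                 quantMethod = "character", quantValue = "numeric",
                 mode = "character", interpolation = "character",
                 resegRange = "numeric"),
  prototype(interpolation = "bspline", resegRange = c(0, 200))
)

setValidity("SettingSpec", function(object) {
  msg <- character()
  if (!object@scheme %in% c("original", "normalised", "resegmented"))
    msg <- c(msg, "unknown scheme")
  if (!object@quantMethod %in% c("fixed_bin_width", "fixed_bin_number"))
    msg <- c(msg, "unknown quantisation method")
  if (object@quantValue <= 0)
    msg <- c(msg, "quantValue must be positive")
  if (!object@mode %in% c("single_slice", "multi_slice"))
    msg <- c(msg, "unknown mode")
  if (!object@interpolation %in% c("bspline", "linear"))
    msg <- c(msg, "unknown interpolation")
  if (object@scheme == "normalised" && object@quantMethod != "fixed_bin_number")
    msg <- c(msg, "normalised scheme requires fixed_bin_number quantisation")
  if (object@scheme == "resegmented" &&
      !(object@quantMethod == "fixed_bin_width" && object@quantValue == 25))
    msg <- c(msg, "resegmented scheme uses fixed bin width 25 only")
  if (length(msg)) msg else TRUE
})

#' QuantisedROI: discretised grey levels inside a mask
#'
#' Grey levels are held on the ROI bounding-box grid with NA outside the
#' mask, so that texture matrices can honour spatial adjacency; the
#' pre-quantisation HU values of the same voxels feed the first-order
#' statistics.
#'
#' @slot levels 3D integer array over the ROI bounding box; NA outside the
#'   mask, values in 1..Ng inside.
#' @slot Ng number of grey levels (top occupied level).
#' @slot rawValues numeric vector of in-mask pre-quantisation intensities,
#'   in the same voxel order as `which(!is.na(levels))`.
#' @slot voxelVolume voxel volume in mm^3 (used by total energy).
#' @export
setClass("QuantisedROI",
  representation(levels = "array", Ng = "integer", rawValues = "numeric",
                 voxelVolume = "numeric"),
  prototype(voxelVolume = 1)
)

setValidity("QuantisedROI", function(object) {
  msg <- character()
  lv <- object@levels[!is.na(object@levels)]
  if (length(lv) == 0L) msg <- c(msg, "no in-mask voxel")
  else {
    if (min(lv) < 1L) msg <- c(msg, "levels must be >= 1")
    if (max(lv) != object@Ng) msg <- c(msg, "Ng must equal the top level")
    if (length(object@rawValues) != length(lv))
      msg <- c(msg, "rawValues length must match in-mask voxel count")
  }
  if (length(msg)) msg else TRUE
})

## ---- constructors ----------------------------------------------------------

#' Create a CTVolume
#'
#' @param values numeric array (2D arrays are promoted to depth-1 3D).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) origin in mm.
#' @return A [CTVolume-class].
#' @export
ctVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a VoxelMask
#'
#' @param values logical/numeric array of 0/1 (2D promoted to depth-1 3D).
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A [VoxelMask-class].
#' @export
voxelMask <- function(values, spacing = c(1, 1, 1)) {
  values <- (values != 0) * 1
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  new("VoxelMask", values = values, spacing = as.numeric(spacing))
}

## ---- accessors and show ----------------------------------------------------

#' Voxel values of an image or mask
#' @param x a [CTVolume-class] or [VoxelMask-class].
#' @return The underlying 3D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "CTVolume", function(x) x@values)

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelMask", function(x) x@values)

#' Voxel spacing in millimetres
#' @param x a [CTVolume-class] or [VoxelMask-class].
#' @return numeric(3).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VoxelMask", function(x) x@spacing)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@values))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume %d x %d x %d, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelMask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], as.integer(sum(object@values))))
})

setMethod("show", "ArterySample", function(object) {
  cat(sprintf("ArterySample %s/%s [%s], calcium %.1f, %d mask voxels\n",
              object@patientId, object@side, object@label,
              object@calciumScore, as.integer(sum(object@mask@values))))
})

setMethod("show", "SettingSpec", function(object) {
  cat(sprintf("SettingSpec <%s>: %s, %s = %g, %s%s\n",
              object@id, object@scheme, object@quantMethod,
              object@quantValue, object@mode,
              if (object@mode == "multi_slice")
                paste0(", ", object@interpolation) else ""))
})

#' Identifier of a setting
#' @param x a [SettingSpec-class].
#' @return character scalar id.
#' @export
settingId <- function(x) x@id
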