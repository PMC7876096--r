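## Pre-processing schemes, grey-level quantisation and isotropic resampling.

#' Construct a SettingSpec
#'
#' @param scheme "original", "normalised" or "resegmented".
#' @param quantMethod "fixed_bin_width" or "fixed_bin_number".
#' @param quantValue bin width in HU, or number of bins.
#' @param mode "single_slice" or "multi_slice".
#' @param interpolation "bspline" or "linear" (multi-slice resampling).
#' @param resegRange inclusive HU window for the resegmented scheme.
#' @param id optional identifier; derived from the fields when missing.
#' @return A [SettingSpec-class].
#' @export
settingSpec <- function(scheme, quantMethod, quantValue,
                        mode = "single_slice", interpolation = "bspline",
                        resegRange = c(0, 200), id = NULL) {
  if (is.null(id)) {
    tag <- if (quantMethod == "fixed_bin_width") "bw" else "bn"
    id <- sprintf("%s_%s_%s%g", mode, scheme, tag, quantValue)
    if (mode == "multi_slice") id <- paste0(id, "_", interpolation)
  }
  new("SettingSpec", id = id, scheme = scheme, quantMethod = quantMethod,
      quantValue = as.numeric(quantValue), mode = mode,
      interpolation = interpolation, resegRange = as.numeric(resegRange))
}

#' Enumerate the 19-setting pre-processing/quantisation grid
#'
#' The grid combines: original images with six fixed bin widths (10, 15, 20,
#' 25, 30, 35 HU) and six fixed bin numbers (8, 16, 32, 64, 128, 256);
#' normalised images with the six bin numbers only (fixed bin widths on
#' z-scored intensities leave too few grey levels); and resegmentation to
#' [0, 200] HU with fixed bin width 25 only. Ordering is stable.
#'
#' @param mode "single_slice" or "multi_slice".
#' @param interpolation interpolator recorded for multi-slice settings.
#' @return list of 19 [SettingSpec-class] objects.
#' @export
#' @examples
#' length(enumerateSettings("single_slice"))
enumerateSettings <- function(mode = c("single_slice", "multi_slice"),
                              interpolation = "bspline") {
  mode <- match.arg(mode)
  bws <- seq(10, 35, by = 5)
  bns <- 2^(3:8)
  out <- c(
    lapply(bws, function(b) settingSpec("original", "fixed_bin_width", b,
                                        mode, interpolation)),
    lapply(bns, function(b) settingSpec("original", "fixed_bin_number", b,
                                        mode, interpolation)),
    lapply(bns, function(b) settingSpec("normalised", "fixed_bin_number", b,
                                        mode, interpolation)),
    list(settingSpec("resegmented", "fixed_bin_width", 25, mode,
                     interpolation))
  )
  out
}

#' Summarise a settings list as a data.frame
#' @param settings list of [SettingSpec-class].
#' @return data.frame, one row per setting.
#' @export
settingsTable <- function(settings) {
  do.call(rbind, lapply(settings, function(s) {
    data.frame(id = s@id, scheme = s@scheme, quant_method = s@quantMethod,
               quant_value = s@quantValue, mode = s@mode,
               interpolation = s@interpolation, stringsAsFactors = FALSE)
  }))
}

#' Z-score an image volume
#'
#' Normalises the whole image so that its voxel values have mean 0 and
#' standard deviation 1 (population SD). Geometry is unchanged. Intended for
#' the "normalised" pre-processing scheme; no rescaling constant is applied.
#'
#' @param img a [CTVolume-class] with more than one distinct value.
#' @return A normalised [CTVolume-class].
#' @export
normaliseImage <- function(img) {
  v <- img@values
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0)
    stop("normaliseImage: constant image has no defined z-score")
  ctVolume((v - mean(v)) / s, img@spacing, img@origin)
}

#' Restrict a mask to an HU window (resegmentation)
#'
#' Keeps only mask voxels whose image intensity lies inside `[lo, hi]`,
#' bounds inclusive. This excludes perivascular fat (< 0 HU) and dense
#' calcium or luminal contrast (> 200 HU) from feature computation.
#'
#' @param img a [CTVolume-class].
#' @param mask a [VoxelMask-class] on the same grid.
#' @param lo,hi inclusive HU bounds (defaults 0 and 200).
#' @param minVoxels minimum surviving foreground voxels.
#' @return A resegmented [VoxelMask-class].
#' @export
resegmentMask <- function(img, mask, lo = 0, hi = 200, minVoxels = 1) {
  stopifnot(identical(dim(img@values), dim(mask@values)))
  keep <- mask@values == 1 & img@values >= lo & img@values <= hi
  if (sum(keep) < minVoxels)
    stop(sprintf("resegmentMask: only %d voxels in [%g, %g], need >= %d",
                 sum(keep), lo, hi, minVoxels))
  voxelMask(keep * 1, mask@spacing)
}

## ---- cubic B-spline prefilter (recursive, mirror boundary) -----------------

.bspline_prefilter_1d <- function(v) {
  n <- length(v)
  if (n == 1L) return(v)
  z <- sqrt(3) - 2
  c0 <- v * 6
  ## causal init over the mirror-extended signal; exact (full period) for
  ## short axes, truncated at machine tolerance otherwise
  horizon <- ceiling(log(1e-15) / log(abs(z)))
  cp <- numeric(n)
  if (horizon >= 2L * n - 2L) {
    k <- 0:(2L * n - 3L)
    cp[1] <- sum(c0[.mirror_idx(k + 1L, n)] * z^k) / (1 - z^(2L * n - 2L))
  } else {
    k <- 0:(horizon - 1L)
    cp[1] <- sum(c0[.mirror_idx(k + 1L, n)] * z^k)
  }
  for (i in 2:n) cp[i] <- c0[i] + z * cp[i - 1]
  cm <- numeric(n)
  cm[n] <- (z / (z * z - 1)) * (cp[n] + z * cp[n - 1])
  for (i in (n - 1):1) cm[i] <- z * (cm[i + 1] - cp[i])
  cm
}

.mirror_idx <- function(i, n) {
  ## reflect indices (1-based) into 1..n, period 2n-2
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j[j < 0] <- j[j < 0] + p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

.bspline_kernel <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 2 / 3 - at^2 + at^3 / 2,
         ifelse(at < 2, ((2 - at)^3) / 6, 0))
}

## Interpolate along one axis of a 3D array at fractional index positions
## `pos` (1-based). method "linear" or "bspline".
.interp_axis <- function(arr, axis, pos, method) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)               # axis first
  m <- matrix(a, nrow = n)            # columns are lines along the axis
  if (method == "bspline" && n > 1L) {
    m <- apply(m, 2, .bspline_prefilter_1d)
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
  }
  if (method == "linear") {
    i0 <- floor(pos); f <- pos - i0
    idx0 <- .mirror_idx(as.integer(i0), n)
    idx1 <- .mirror_idx(as.integer(i0) + 1L, n)
    out <- m[idx0, , drop = FALSE] * (1 - f) + m[idx1, , drop = FALSE] * f
  } else {
    i0 <- floor(pos)
    out <- 0
    for (k in -1:2) {
      w <- .bspline_kernel(pos - (i0 + k))
      out <- out + m[.mirror_idx(as.integer(i0) + k, n), , drop = FALSE] * w
    }
  }
  a2 <- array(out, dim = c(length(pos), d[perm[2]], d[perm[3]]))
  aperm(a2, order(perm))
}

.resample_array <- function(arr, spacing, target, method) {
  d <- dim(arr)
  out <- arr
  for (axis in 1:3) {
    n_out <- max(1L, as.integer(round(d[axis] * spacing[axis] / target[axis])))
    if (n_out == d[axis] && abs(spacing[axis] - target[axis]) < 1e-12) next
    ## output voxel centres in input index coordinates (centre-aligned grids)
    pos <- ((seq_len(n_out) - 0.5) * target[axis] / spacing[axis]) + 0.5
    out <- .interp_axis(out, axis, pos, method)
  }
  out
}

#' Resample an image and mask to an isotropic grid
#'
#' Resamples a multi-slice volume (typically 3 mm slice thickness) to an
#' isotropic target spacing, by separable cubic B-spline interpolation (with
#' recursive prefiltering, so grid points are reproduced exactly) or
#' trilinear interpolation. The mask is always resampled by nearest
#' neighbour so it remains strictly binary.
#'
#' @param img a [CTVolume-class].
#' @param mask a [VoxelMask-class] on the same grid.
#' @param target isotropic target spacing in mm (default 1).
#' @param method "bspline" (cubic, order 3) or "linear" (order 1).
#' @return list with elements `image` and `mask`.
#' @export
resampleIsotropic <- function(img, mask, target = 1,
                              method = c("bspline", "linear")) {
  method <- match.arg(method)
  stopifnot(identical(dim(img@values), dim(mask@values)))
  tgt <- rep(target, 3)
  vi <- .resample_array(img@values, img@spacing, tgt, method)
  ## nearest neighbour for the mask: round positions to nearest input voxel
  d <- dim(mask@values)
  vm <- mask@values
  for (axis in 1:3) {
    n_out <- max(1L, as.integer(round(d[axis] * mask@spacing[axis] /
                                        tgt[axis])))
    if (n_out == d[axis] && abs(mask@spacing[axis] - tgt[axis]) < 1e-12) next
    pos <- ((seq_len(n_out) - 0.5) * tgt[axis] / mask@spacing[axis]) + 0.5
    idx <- .mirror_idx(as.integer(round(pos)), d[axis])
    vm <- switch(axis,
                 vm[idx, , , drop = FALSE],
                 vm[, idx, , drop = FALSE],
                 vm[, , idx, drop = FALSE])
  }
  if (sum(vm) == 0)
    stop("resampleIsotropic: mask empty after resampling")
  list(image = ctVolume(vi, tgt, img@origin),
       mask = voxelMask(vm, tgt))
}

## ---- quantisation ----------------------------------------------------------

#' Fixed-bin-width grey-level quantisation
#'
#' Discretises intensities into bins of constant width anchored at the ROI
#' minimum: `level(v) = floor((v - min) / bw) + 1`. A value exactly at the
#' top edge opens the next bin (so the maximum defines Ng). Constant input
#' yields a single level.
#'
#' @param values numeric vector of ROI intensities.
#' @param bw positive bin width (HU).
#' @return list with integer `levels` and `Ng`.
#' @export
quantiseFixedBinWidth <- function(values, bw) {
  stopifnot(bw > 0, length(values) >= 1)
  lev <- as.integer(floor((values - min(values)) / bw)) + 1L
  list(levels = lev, Ng = max(lev))
}

#' Fixed-bin-number grey-level quantisation
#'
#' Discretises intensities into `nb` equal-width bins spanning the ROI
#' [min, max]; the maximum value is assigned to level `nb` (closed upper
#' edge). Constant input yields a single level with a warning.
#'
#' @param values numeric vector of ROI intensities.
#' @param nb integer number of bins (>= 2).
#' @return list with integer `levels` and `Ng` (= max occupied level).
#' @export
quantiseFixedBinNumber <- function(values, nb) {
  stopifnot(nb >= 2, length(values) >= 1)
  rng <- max(values) - min(values)
  if (rng == 0) {
    warning("quantiseFixedBinNumber: constant ROI, single grey level")
    return(list(levels = rep(1L, length(values)), Ng = 1L))
  }
  lev <- as.integer(floor((values - min(values)) / rng * nb)) + 1L
  lev[lev > nb] <- as.integer(nb)
  list(levels = lev, Ng = max(lev))
}

#' Quantise the in-mask voxels of an image
#'
#' Applies the setting's quantisation to the image intensities inside the
#' mask and returns a [QuantisedROI-class] holding the level array on the
#' ROI bounding box (NA outside the mask). Minimum and maximum are ROI
#' statistics, never whole-image statistics.
#'
#' @param img a [CTVolume-class].
#' @param mask a [VoxelMask-class] on the same grid.
#' @param method "fixed_bin_width" or "fixed_bin_number".
#' @param value bin width or bin number.
#' @return A [QuantisedROI-class].
#' @export
quantiseROI <- function(img, mask, method, value) {
  stopifnot(identical(dim(img@values), dim(mask@values)))
  inmask <- mask@values == 1
  ## crop to bounding box
  idx <- which(inmask, arr.ind = TRUE)
  rg <- apply(idx, 2, range)
  sub <- function(a) a[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2],
                       rg[1, 3]:rg[2, 3], drop = FALSE]
  vals <- sub(img@values)
  msk <- sub(inmask)
  raw <- vals[msk]
  q <- if (method == "fixed_bin_width") quantiseFixedBinWidth(raw, value)
       else quantiseFixedBinNumber(raw, value)
  lev <- array(NA_integer_, dim = dim(vals))
  lev[msk] <- q$levels
  new("QuantisedROI", levels = lev, Ng = as.integer(q$Ng), rawValues = raw,
      voxelVolume = prod(img@spacing))
}

#' Apply a setting's full pre-processing chain
#'
#' Runs, in order: isotropic resampling (multi-slice only, using the
#' setting's interpolator), the pre-processing scheme (normalisation or
#' resegmentation) and grey-level quantisation.
#'
#' @param img a [CTVolume-class].
#' @param mask a [VoxelMask-class].
#' @param setting a [SettingSpec-class].
#' @param minVoxels minimum ROI size after resegmentation.
#' @return A [QuantisedROI-class].
#' @export
preprocessROI <- function(img, mask, setting, minVoxels = 10) {
  if (setting@mode == "multi_slice") {
    rs <- resampleIsotropic(img, mask, 1, setting@interpolation)
    img <- rs$image; mask <- rs$mask
  }
  if (setting@scheme == "normalised") {
    img <- normaliseImage(img)
  } else if (setting@scheme == "resegmented") {
    mask <- resegmentMask(img, mask, setting@resegRange[1],
                          setting@resegRange[2], minVoxels = minVoxels)
  }
  quantiseROI(img, mask, setting@quantMethod, setting@quantValue)
}
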