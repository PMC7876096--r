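## The 93 radiomic feature definitions. Higher-order features are computed
## per texture matrix (per direction for GLCM/GLRLM, then averaged over
## directions); first-order statistics use the pre-quantisation intensities
## except entropy/uniformity which use the discretised histogram.

.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order intensity statistics (18 features)
#'
#' Location/spread/shape statistics of the raw in-mask intensities plus
#' histogram entropy and uniformity of the discretised levels. Percentiles
#' use linear interpolation; variance, skewness and kurtosis are population
#' moments (kurtosis is not excess-corrected, a normal sample is near 3).
#'
#' @param roi a [QuantisedROI-class].
#' @return named numeric(18).
#' @export
firstOrderFeatures <- function(roi) {
  x <- roi@rawValues
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  sub <- x[x >= p10 & x <= p90]
  hist_p <- tabulate(roi@levels[!is.na(roi@levels)], nbins = roi@Ng) / n
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = roi@voxelVolume * sum(x^2),
    Entropy = -sum(.xlog2(hist_p)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = unname(quantile(x, 0.75, type = 7) -
                                  quantile(x, 0.25, type = 7)),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(hist_p^2)
  )
  out
}

## features of one normalised symmetric co-occurrence matrix
.glcm_one <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  ## p_{x+y} over k = 2..2Ng and p_{x-y} over k = 0..Ng-1
  psum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  ks <- sort(unique(as.vector(i + j)))
  pdiff0 <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  kd <- sort(unique(as.vector(abs(i - j))))
  pdiff <- numeric(Ng); pdiff[kd + 1] <- pdiff0; kd <- 0:(Ng - 1)
  HXY <- -sum(.xlog2(P))
  HX <- -sum(.xlog2(px)); HY <- -sum(.xlog2(py))
  pij_ind <- outer(px, py)
  HXY1 <- -sum(P[P > 0] * log2(pij_ind[P > 0]))
  HXY2 <- -sum(.xlog2(pij_ind))
  da <- sum(kd * pdiff)
  corr <- if (sigx * sigy > 0)
    (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  ## MCC on occupied levels
  occ <- which(px > 0)
  mcc <- if (length(occ) <= 1) 1 else {
    Pp <- P[occ, occ, drop = FALSE]
    A <- Pp / px[occ]
    B <- sweep(Pp, 2, py[occ], "/")
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(.xlog2(pdiff)),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(.xlog2(psum)),
    SumSquares = sum((i - mux)^2 * P)
  )
}

#' GLCM features (24), averaged over directions
#'
#' @param roi a [QuantisedROI-class].
#' @param mode "2d" or "3d".
#' @return named numeric(24); all NA (with a warning) when no voxel pair
#'   exists in any direction (e.g. a single-voxel ROI).
#' @export
glcmFeatures <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  mats <- glcmMatrices(roi, mode)
  if (length(mats) == 0) {
    warning("glcmFeatures: no voxel pairs; features undefined")
    return(setNames(rep(NA_real_, length(.glcm_names)), .glcm_names))
  }
  rowMeans(vapply(mats, .glcm_one, numeric(length(.glcm_names))))
}

.rlm_one <- function(M, Np) {
  Nr <- sum(M)
  g <- row(M); l <- col(M)
  p <- M / Nr
  mug <- sum(g * p); mul <- sum(l * p)
  c(
    GrayLevelNonUniformity = sum(rowSums(M)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(M)^2) / Nr^2,
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelRunEmphasis = sum(M * g^2) / Nr,
    LongRunEmphasis = sum(M * l^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(M * g^2 * l^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(M * l^2 / g^2) / Nr,
    LowGrayLevelRunEmphasis = sum(M / g^2) / Nr,
    RunEntropy = -sum(.xlog2(p)),
    RunLengthNonUniformity = sum(colSums(M)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(M)^2) / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = sum((l - mul)^2 * p),
    ShortRunEmphasis = sum(M / l^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(M * g^2 / l^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(M / (g^2 * l^2)) / Nr
  )
}

#' GLRLM features (16), averaged over directions
#'
#' @inheritParams glcmFeatures
#' @return named numeric(16).
#' @export
glrlmFeatures <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  Np <- sum(!is.na(roi@levels))
  mats <- glrlmMatrices(roi, mode)
  if (length(mats) == 0) {
    warning("glrlmFeatures: no runs; features undefined")
    return(setNames(rep(NA_real_, length(.glrlm_names)), .glrlm_names))
  }
  rowMeans(vapply(mats, .rlm_one, numeric(length(.glrlm_names)), Np = Np))
}

#' GLSZM features (16)
#'
#' @inheritParams glcmFeatures
#' @return named numeric(16).
#' @export
glszmFeatures <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  z <- glszmZones(roi, mode)
  Np <- sum(!is.na(roi@levels))
  Nz <- nrow(z)
  g <- z$level; s <- z$size
  p <- rep(1 / Nz, Nz)
  mug <- sum(g * p); mus <- sum(s * p)
  ## counts aggregated by level / by size for the non-uniformity terms
  ng <- tapply(rep(1, Nz), g, sum)
  ns <- tapply(rep(1, Nz), s, sum)
  pz <- as.vector(table(paste(g, s))) / Nz
  c(
    GrayLevelNonUniformity = sum(ng^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(ng^2) / Nz^2,
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelZoneEmphasis = sum(g^2) / Nz,
    LargeAreaEmphasis = sum(s^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(s^2 * g^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / g^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(1 / g^2) / Nz,
    SizeZoneNonUniformity = sum(ns^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(ns^2) / Nz^2,
    SmallAreaEmphasis = sum(1 / s^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(g^2 / s^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (s^2 * g^2)) / Nz,
    ZoneEntropy = -sum(.xlog2(pz)),
    ZonePercentage = Nz / Np,
    ZoneVariance = sum((s - mus)^2 * p)
  )
}

#' GLDM features (14)
#'
#' Dependence size j counts the centre voxel plus its neighbours within
#' chessboard distance 1 whose level difference is at most alpha (default 0).
#'
#' @inheritParams glcmFeatures
#' @param alpha dependence tolerance (default 0).
#' @return named numeric(14).
#' @export
gldmFeatures <- function(roi, mode = c("2d", "3d"), alpha = 0) {
  mode <- match.arg(mode)
  M <- gldmMatrix(roi, mode, alpha)
  Nz <- sum(M)
  g <- row(M); j <- col(M)
  p <- M / Nz
  mug <- sum(g * p); muj <- sum(j * p)
  c(
    DependenceEntropy = -sum(.xlog2(p)),
    DependenceNonUniformity = sum(colSums(M)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / Nz^2,
    DependenceVariance = sum((j - muj)^2 * p),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / Nz,
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelEmphasis = sum(M * g^2) / Nz,
    LargeDependenceEmphasis = sum(M * j^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(M * j^2 * g^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(M * j^2 / g^2) / Nz,
    LowGrayLevelEmphasis = sum(M / g^2) / Nz,
    SmallDependenceEmphasis = sum(M / j^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(M * g^2 / j^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(M / (j^2 * g^2)) / Nz
  )
}

#' NGTDM features (5)
#'
#' @inheritParams glcmFeatures
#' @return named numeric(5). Coarseness returns 1e6 when the busyness sum is
#'   zero (flat ROI); Contrast is 0 with a single occupied level.
#' @export
ngtdmFeatures <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  v <- ngtdmVector(roi, mode)
  Nvp <- sum(v$n)
  if (Nvp == 0) {
    warning("ngtdmFeatures: no voxel with neighbours; features undefined")
    return(setNames(rep(NA_real_, 5), .ngtdm_names))
  }
  pres <- v$n > 0
  pi_ <- v$n / Nvp
  i <- v$level
  Ngp <- sum(pres)
  num_bus <- sum(pi_ * v$s)
  ## pairwise sums over present levels
  ip <- i[pres]; pp <- pi_[pres]; sp <- v$s[pres]
  contrast <- if (Ngp > 1) {
    sum(outer(pp, pp) * outer(ip, ip, "-")^2) / (Ngp * (Ngp - 1)) *
      sum(v$s) / Nvp
  } else 0
  den_bus <- sum(abs(outer(ip * pp, ip * pp, "-")))
  busy <- if (den_bus > 0) num_bus / den_bus else 0
  cmplx <- sum(abs(outer(ip, ip, "-")) *
                 (outer(pp * sp, rep(1, Ngp)) + outer(rep(1, Ngp), pp * sp)) /
                 (outer(pp, rep(1, Ngp)) + outer(rep(1, Ngp), pp))) / Nvp
  strength <- if (sum(v$s) > 0)
    sum((outer(pp, rep(1, Ngp)) + outer(rep(1, Ngp), pp)) *
          outer(ip, ip, "-")^2) / sum(v$s) else 0
  c(Coarseness = if (num_bus > 0) 1 / num_bus else 1e6,
    Contrast = contrast,
    Busyness = busy,
    Complexity = cmplx,
    Strength = strength)
}

#' Extract all 93 features for one artery under one setting
#'
#' Applies the setting's pre-processing chain (isotropic resampling for
#' multi-slice, normalisation or resegmentation, quantisation) and computes
#' the six feature classes. Single-slice mode uses strictly in-plane (2D)
#' neighbourhoods; multi-slice mode uses 3D neighbourhoods after resampling.
#'
#' @param img a [CTVolume-class].
#' @param mask a [VoxelMask-class].
#' @param setting a [SettingSpec-class].
#' @param minVoxels minimum ROI size after pre-processing.
#' @return named numeric(93), names as in [featureRegistry()].
#' @export
extractAll <- function(img, mask, setting, minVoxels = 10) {
  roi <- preprocessROI(img, mask, setting, minVoxels = minVoxels)
  texmode <- if (setting@mode == "single_slice") "2d" else "3d"
  featuresFromROI(roi, texmode)
}

#' Compute the 93 features from an already-quantised ROI
#'
#' @param roi a [QuantisedROI-class].
#' @param texmode "2d" or "3d" neighbourhoods.
#' @return named numeric(93).
#' @export
featuresFromROI <- function(roi, texmode = c("2d", "3d")) {
  texmode <- match.arg(texmode)
  out <- c(
    setNames(firstOrderFeatures(roi),
             paste0("firstorder_", .firstorder_names)),
    setNames(glcmFeatures(roi, texmode), paste0("glcm_", .glcm_names)),
    setNames(glrlmFeatures(roi, texmode), paste0("glrlm_", .glrlm_names)),
    setNames(glszmFeatures(roi, texmode), paste0("glszm_", .glszm_names)),
    setNames(gldmFeatures(roi, texmode), paste0("gldm_", .gldm_names)),
    setNames(ngtdmFeatures(roi, texmode), paste0("ngtdm_", .ngtdm_names))
  )
  stopifnot(length(out) == 93L)
  out[featureRegistry()$feature]
}
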