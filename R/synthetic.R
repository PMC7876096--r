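## Synthetic carotid CTA phantom cohorts. Each artery is a concentric
## structure per axial slice: contrast-filled lumen (> 200 HU), an annular
## vessel wall carrying a correlated Gaussian texture in roughly 0-130 HU,
## up to three calcific blobs (> 300 HU) and a perivascular fat ring
## (< 0 HU). The segmentation mask encompasses the whole vessel (wall +
## lumen + calcium) with a one-voxel margin into the fat ring, so that
## dilation/erosion perturbations genuinely change fat and contrast content.

#' Phantom cohort configuration
#'
#' Defaults encode the acquisition geometry of the emulated study: paired
#' culprit/non-culprit arteries for 41 patients; single-slice mode as a
#' depth-1 grid at 0.4 x 0.4 mm in-plane and 0.625 mm slice thickness;
#' multi-slice mode as 14 slices at 3 mm thickness. The calcium covariate is
#' drawn per class from heavily overlapping lognormal laws calibrated to
#' median (IQR) 263 (95-701) for culprit and 387 (63-659) for non-culprit
#' arteries, so calcium alone is a weak predictor. `textureEffect` scales
#' the correlation length and variance of the culprit wall texture.
#'
#' @param nPatients number of patients (>= 2); each contributes one culprit
#'   and one non-culprit artery.
#' @param mode "single_slice" or "multi_slice".
#' @param voxelSpacing numeric(3) spacing in mm.
#' @param nSlices slices in multi-slice mode (>= 4).
#' @param gridSize in-plane grid side in voxels.
#' @param wallHuMean,wallHuSd wall texture mean and SD in HU (within one
#'   artery).
#' @param wallHuMeanSd between-artery SD of the wall mean attenuation (HU);
#'   real cohorts vary substantially between patients, and this
#'   between-subject variance is what feature robustness (ICC) is measured
#'   against.
#' @param lumenHu luminal contrast attenuation (> 200 HU).
#' @param calciumHu calcification attenuation (> 300 HU).
#' @param fatHu perivascular fat attenuation (< 0 HU).
#' @param noiseHuSd acquisition noise SD added everywhere (HU).
#' @param textureEffect class effect size >= 0; 0 means culprit and
#'   non-culprit walls are identical in law.
#' @param calciumLognormal list with per-class `meanlog`/`sdlog` pairs.
#' @param observerJitter boundary flip rate of the simulated second reader.
#' @param seed integer master seed.
#' @return list of class "phantomConfig".
#' @export
phantomConfig <- function(nPatients = 41,
                          mode = c("single_slice", "multi_slice"),
                          voxelSpacing = NULL,
                          nSlices = 14,
                          gridSize = 40,
                          wallHuMean = 65, wallHuSd = 25,
                          wallHuMeanSd = 15,
                          lumenHu = 400, calciumHu = 600, fatHu = -80,
                          noiseHuSd = 8,
                          textureEffect = 0.4,
                          calciumLognormal = list(
                            culprit = c(meanlog = log(263), sdlog = 1.5),
                            non_culprit = c(meanlog = log(387), sdlog = 1.6)),
                          observerJitter = 0.1,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(voxelSpacing))
    voxelSpacing <- if (mode == "single_slice") c(0.4, 0.4, 0.625)
                    else c(0.4, 0.4, 3)
  if (nPatients < 2) stop("phantomConfig: nPatients must be >= 2")
  if (mode == "multi_slice" && nSlices < 4)
    stop("phantomConfig: multi-slice requires >= 4 slices")
  if (any(voxelSpacing <= 0)) stop("phantomConfig: spacing must be positive")
  if (textureEffect < 0) stop("phantomConfig: textureEffect must be >= 0")
  if (observerJitter < 0) stop("phantomConfig: observerJitter must be >= 0")
  structure(list(nPatients = as.integer(nPatients), mode = mode,
                 voxelSpacing = voxelSpacing,
                 nSlices = if (mode == "single_slice") 1L
                           else as.integer(nSlices),
                 gridSize = as.integer(gridSize),
                 wallHuMean = wallHuMean, wallHuSd = wallHuSd,
                 wallHuMeanSd = wallHuMeanSd,
                 lumenHu = lumenHu, calciumHu = calciumHu, fatHu = fatHu,
                 noiseHuSd = noiseHuSd, textureEffect = textureEffect,
                 calciumLognormal = calciumLognormal,
                 observerJitter = observerJitter, seed = as.integer(seed)),
            class = "phantomConfig")
}

## separable Gaussian smoothing of a 2D matrix (reflect padding via filter)
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.smooth2d <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(x, n) x[c(pmin(pmax(seq_len(nrow(x) + 2 * n) - n, 1),
                                 nrow(x))), , drop = FALSE]
  ## rows
  mp <- pad(m, r)
  m1 <- apply(mp, 2, function(col) as.vector(stats::filter(col, k,
                                                           sides = 2)))
  m1 <- m1[(r + 1):(r + nrow(m)), , drop = FALSE]
  ## columns
  mp <- t(pad(t(m1), r))
  m2 <- t(apply(mp, 1, function(rw) as.vector(stats::filter(rw, k,
                                                            sides = 2))))
  m2[, (r + 1):(r + ncol(m)), drop = FALSE]
}

## correlated Gaussian random field, unit variance, correlation length sigma
.texture_field <- function(nr, nc, sigma) {
  f <- .smooth2d(matrix(rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / sd(as.vector(f))
}

#' Generate one synthetic vessel volume and its mask
#'
#' Builds the concentric lumen/wall/calcium/fat structure per axial slice.
#' The wall texture is a Gaussian random field obtained by spatial smoothing
#' of white noise; `textureScale` multiplies both the smoothing kernel width
#' and the texture SD (the class-dependent effect).
#'
#' @param config a [phantomConfig()] list.
#' @param textureScale multiplier (1 + effect) applied to the wall texture.
#' @param nCalcium number of calcific blobs (0-3).
#' @return list with `image` ([CTVolume-class]) and `mask`
#'   ([VoxelMask-class]).
#' @export
makeVesselVolume <- function(config, textureScale = 1, nCalcium = 2) {
  n <- config$gridSize
  nz <- config$nSlices
  sp <- config$voxelSpacing
  cx <- n / 2 + runif(1, -1, 1)
  cy <- n / 2 + runif(1, -1, 1)
  ## per-artery anatomy and attenuation: stenosis, vessel calibre, wall
  ## density and texture grain all vary between patients
  r_lumen <- n * 0.15 * runif(1, 0.7, 1.25)
  r_wall <- n * 0.30 * runif(1, 0.85, 1.15)
  r_fat <- n * 0.45
  wall_mu <- config$wallHuMean + rnorm(1, 0, config$wallHuMeanSd)
  wall_sd <- config$wallHuSd * runif(1, 0.7, 1.4)
  ## contrast bolus density differs between acquisitions
  lumen_hu <- config$lumenHu * runif(1, 0.75, 1.25)
  ## perivascular compartment: predominantly fatty but heterogeneous mixed
  ## tissue (fat, fascia, muscle) with a per-artery character
  fat_mu <- config$fatHu + rnorm(1, 0, 25)
  fat_sd <- 25 * runif(1, 0.7, 1.3)
  ## fraction of the perivascular compartment occupied by muscle-like
  ## soft tissue (~45 HU): neck ROIs border sternocleidomastoid and fascia
  muscle_frac <- runif(1, 0.1, 0.4)
  ## calcification burden spans nearly plaque-free to heavily calcified
  cal_radius <- runif(max(1, nCalcium), 1, 3.5)
  if (r_wall <= r_lumen + 1)
    stop("makeVesselVolume: geometry leaves an empty wall")
  img <- array(0, c(n, n, nz))
  msk <- array(0, c(n, n, nz))
  base_sigma <- 1.2 * runif(1, 0.85, 1.2)
  ## wall/perivascular textures evolve smoothly along the artery: AR(1)
  ## mixing across slices keeps the marginal law identical per slice while
  ## giving the z-continuity real vessels have
  rho_z <- 0.8
  tex <- ftex <- mtex <- NULL
  for (z in seq_len(nz)) {
    ## mild slice-to-slice drift of the centre in multi-slice mode
    czx <- cx + if (nz > 1) runif(1, -0.5, 0.5) else 0
    czy <- cy + if (nz > 1) runif(1, -0.5, 0.5) else 0
    dist <- sqrt(outer((seq_len(n) - czx)^2, (seq_len(n) - czy)^2, "+"))
    lumen <- dist <= r_lumen
    wall <- dist > r_lumen & dist <= r_wall
    fat <- dist > r_wall & dist <= r_fat
    if (!any(wall)) stop("makeVesselVolume: geometry leaves an empty wall")
    sl <- matrix(0, n, n)
    mix <- function(prev, sigma) {
      g <- .texture_field(n, n, sigma)
      if (is.null(prev)) g else rho_z * prev + sqrt(1 - rho_z^2) * g
    }
    tex <- mix(tex, base_sigma * textureScale)
    ftex <- mix(ftex, 2.5)
    mtex <- mix(mtex, 3)
    sl[wall] <- wall_mu + wall_sd * textureScale * tex[wall]
    sl[lumen] <- lumen_hu
    sl[fat] <- fat_mu + fat_sd * ftex[fat]
    if (any(fat)) {
      thr <- quantile(mtex[fat], 1 - muscle_frac)
      muscle <- fat & mtex > thr
      sl[muscle] <- 45 + 20 * ftex[muscle]
    }
    ## calcific blobs embedded in the wall
    if (nCalcium > 0) {
      for (b in seq_len(nCalcium)) {
        ang <- runif(1, 0, 2 * pi)
        rlo <- min(r_lumen + 1, r_wall - 0.5)
        rad <- runif(1, rlo, r_wall - 0.5)
        bx <- czx + rad * cos(ang); by <- czy + rad * sin(ang)
        bd <- sqrt(outer((seq_len(n) - bx)^2, (seq_len(n) - by)^2, "+"))
        blob <- bd <= cal_radius[b] & (wall | fat)
        sl[blob] <- config$calciumHu
      }
    }
    sl <- sl + rnorm(n * n, 0, config$noiseHuSd)
    img[, , z] <- sl
    ## mask: whole vessel incl. one-voxel margin overlapping the fat ring
    msk[, , z] <- (dist <= r_wall + 1) * 1
  }
  list(image = ctVolume(img, sp), mask = voxelMask(msk, sp))
}

## deterministic per-sample substream: cohort size changes never reshuffle
## earlier samples
.sample_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' Generate a paired culprit/non-culprit phantom cohort
#'
#' Every patient contributes exactly one culprit and one non-culprit artery
#' (sides assigned at random). The culprit wall texture differs from the
#' non-culprit one by the configured `textureEffect` (scaling correlation
#' length and variance); the calcium covariate is drawn per class from the
#' configured lognormal laws, independently of the image. Fully reproducible
#' from the config seed; per-sample substreams are derived by counter.
#'
#' @param config a [phantomConfig()] list.
#' @return list of 2 * nPatients [ArterySample-class] objects.
#' @export
#' @examples
#' co <- generateCohort(phantomConfig(nPatients = 2, gridSize = 24))
#' length(co)
generateCohort <- function(config) {
  if (!inherits(config, "phantomConfig"))
    stop("generateCohort: config must come from phantomConfig()")
  out <- vector("list", 2L * config$nPatients)
  counter <- 0L
  for (p in seq_len(config$nPatients)) {
    pid <- sprintf("P%03d", p)
    set.seed(.sample_seed(config$seed, counter)); counter <- counter + 1L
    culprit_side <- sample(c("left", "right"), 1)
    for (label in c("culprit", "non_culprit")) {
      set.seed(.sample_seed(config$seed, counter)); counter <- counter + 1L
      scale <- if (label == "culprit") 1 + config$textureEffect else 1
      nCal <- sample(0:3, 1)
      vol <- makeVesselVolume(config, textureScale = scale, nCalcium = nCal)
      lp <- config$calciumLognormal[[label]]
      calcium <- rlnorm(1, lp[["meanlog"]], lp[["sdlog"]])
      side <- if (label == "culprit") culprit_side
              else setdiff(c("left", "right"), culprit_side)
      out[[2L * (p - 1L) + (label == "non_culprit") + 1L]] <-
        new("ArterySample", patientId = pid, side = side, label = label,
            image = vol$image, mask = vol$mask, calciumScore = calcium)
    }
  }
  validateCohort(out)
  out
}

#' Check the pairing invariant of a cohort
#'
#' Each patient must contribute exactly one culprit and one non-culprit
#' artery.
#'
#' @param cohort list of [ArterySample-class].
#' @return invisibly TRUE; error on violation.
#' @export
validateCohort <- function(cohort) {
  if (length(cohort) == 0) stop("validateCohort: empty cohort")
  df <- cohortManifest(cohort)
  tab <- table(df$patient_id, df$label)
  if (!all(dim(tab) == c(length(unique(df$patient_id)), 2)) ||
      !all(tab == 1))
    stop("validateCohort: each patient needs exactly one culprit and one ",
         "non-culprit sample")
  invisible(TRUE)
}

#' Cohort manifest as a data.frame
#'
#' @param cohort list of [ArterySample-class].
#' @return data.frame with patient_id, side, label, calcium_score and mask
#'   voxel count.
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(patient_id = s@patientId, side = s@side, label = s@label,
               calcium_score = s@calciumScore,
               n_voxels = as.integer(sum(s@mask@values)),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a second independent reader
#'
#' Flips boundary voxels of the mask (both inner boundary voxels, which may
#' be dropped, and outer background voxels adjacent to the mask, which may
#' be added) independently with probability `jitter`.
#'
#' @param mask a [VoxelMask-class].
#' @param jitter flip probability in [0, 1].
#' @return a perturbed, non-empty [VoxelMask-class].
#' @export
simulateSecondObserver <- function(mask, jitter) {
  if (jitter < 0) stop("simulateSecondObserver: jitter must be >= 0")
  if (jitter == 0) return(mask)
  v <- mask@values
  dil <- .morph(v, structuringElement(if (dim(v)[3] == 1) 2 else 3),
                "dilate")
  ero <- .morph(v, structuringElement(if (dim(v)[3] == 1) 2 else 3),
                "erode")
  boundary <- which((dil - ero) == 1)   # inner + outer boundary shell
  flip <- boundary[runif(length(boundary)) < jitter]
  v[flip] <- 1 - v[flip]
  if (sum(v) == 0)
    stop("simulateSecondObserver: jitter emptied the mask")
  voxelMask(v, mask@spacing)
}
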