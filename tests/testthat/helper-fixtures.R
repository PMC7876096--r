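# Programmatic fixtures shared across test files.

# random small quantised ROI (dims <= 6 x 6 x 3) with optional mask holes
random_roi <- function(dims = c(4, 4, 1), Ng = 4, hole_frac = 0.2,
                       voxvol = 1) {
  raw <- array(runif(prod(dims), 0, 100), dims)
  msk <- array(runif(prod(dims)) > hole_frac, dims)
  if (sum(msk) < 2) msk[sample(which(!msk), 2 - sum(msk))] <- TRUE
  vals <- raw[msk]
  q <- quantiseFixedBinNumber(vals, Ng)
  lev <- array(NA_integer_, dims)
  lev[msk] <- q$levels
  new("QuantisedROI", levels = lev, Ng = as.integer(q$Ng),
      rawValues = vals, voxelVolume = voxvol)
}

# quantised ROI directly from an integer level array (NA = outside mask)
roi_from_levels <- function(lev, raw = NULL, voxvol = 1) {
  lev <- as.array(lev)
  if (length(dim(lev)) == 2) dim(lev) <- c(dim(lev), 1)
  storage.mode(lev) <- "integer"
  inm <- !is.na(lev)
  if (is.null(raw)) raw <- as.numeric(lev[inm])
  new("QuantisedROI", levels = lev, Ng = as.integer(max(lev, na.rm = TRUE)),
      rawValues = raw, voxelVolume = voxvol)
}

# small image/mask pair with known composition
toy_volume <- function(values, spacing = c(1, 1, 1)) {
  v <- as.array(values)
  if (length(dim(v)) == 2) dim(v) <- c(dim(v), 1)
  ctVolume(v, spacing)
}

small_cohort <- function(n = 6, seed = 7, mode = "single_slice", ...) {
  generateCohort(phantomConfig(nPatients = n, mode = mode, gridSize = 32,
                               seed = seed, ...))
}
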