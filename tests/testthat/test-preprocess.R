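test_that("the setting grid has exactly 19 cells with the stated
           composition", {
  for (mode in c("single_slice", "multi_slice")) {
    st <- enumerateSettings(mode)
    expect_length(st, 19)
    tb <- settingsTable(st)
    expect_equal(sum(tb$scheme == "original" &
                       tb$quant_method == "fixed_bin_width"), 6)
    expect_equal(tb$quant_value[tb$scheme == "original" &
                                  tb$quant_method == "fixed_bin_width"],
                 seq(10, 35, 5))
    expect_equal(tb$quant_value[tb$scheme == "original" &
                                  tb$quant_method == "fixed_bin_number"],
                 2^(3:8))
    expect_equal(tb$quant_value[tb$scheme == "normalised"], 2^(3:8))
    ## normalised intensities never use a fixed bin width
    expect_false(any(tb$scheme == "normalised" &
                       tb$quant_method == "fixed_bin_width"))
    reseg <- tb[tb$scheme == "resegmented", ]
    expect_equal(nrow(reseg), 1)
    expect_equal(reseg$quant_method, "fixed_bin_width")
    expect_equal(reseg$quant_value, 25)
    expect_false(anyDuplicated(tb$id) > 0)
  }
  expect_error(settingSpec("normalised", "fixed_bin_width", 25), "bin_number")
  expect_error(settingSpec("resegmented", "fixed_bin_width", 10), "25")
})

test_that("normalisation z-scores the whole image", {
  v <- toy_volume(matrix(c(0, 10, 0, 10), 2))
  nz <- voxelData(normaliseImage(v))
  expect_equal(sort(unique(as.vector(nz))), c(-1, 1))
  co <- small_cohort(n = 2, seed = 2)
  img <- normaliseImage(co[[1]]@image)
  expect_lt(abs(mean(voxelData(img))), 1e-9)
  expect_lt(abs(sqrt(mean(voxelData(img)^2)) - 1), 1e-9)
  expect_equal(voxelSpacing(img), voxelSpacing(co[[1]]@image))
  expect_error(normaliseImage(toy_volume(matrix(5, 3, 3))), "constant")
})

test_that("resegmentation keeps the [0, 200] HU window inclusively", {
  img <- toy_volume(matrix(c(-30, 0, 100, 200, 201, 50), 2, 3))
  msk <- voxelMask(matrix(1, 2, 3))
  out <- resegmentMask(img, msk)
  kept <- voxelData(out) == 1
  expect_equal(as.vector(kept),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  ## identity when all voxels already lie inside the window
  img2 <- toy_volume(matrix(c(0, 50, 100, 200), 2, 2))
  msk2 <- voxelMask(matrix(1, 2, 2))
  expect_equal(voxelData(resegmentMask(img2, msk2)), voxelData(msk2))
  expect_error(resegmentMask(img, msk, minVoxels = 10), "insufficient|need")
})

test_that("fixed-bin-width quantisation follows the floor convention", {
  q <- quantiseFixedBinWidth(c(0, 10, 20, 30), 25)
  expect_equal(q$levels, c(1L, 1L, 1L, 2L))
  expect_equal(q$Ng, 2L)
  expect_equal(quantiseFixedBinWidth(rep(3.5, 5), 10)$Ng, 1L)
  expect_equal(quantiseFixedBinWidth(c(1, 2, 3), 100)$Ng, 1L)
})

test_that("fixed-bin-number quantisation closes the upper edge", {
  q <- quantiseFixedBinNumber(1:8, 8)
  expect_equal(q$levels, 1:8)
  expect_equal(max(q$levels), 8L)   # max value lands in bin nb, not nb + 1
  expect_warning(q0 <- quantiseFixedBinNumber(rep(2, 4), 16), "constant")
  expect_equal(q0$Ng, 1L)
})

test_that("uniform values fill fixed-number bins binomially", {
  set.seed(4)
  n <- 1e5; nb <- 16
  q <- quantiseFixedBinNumber(runif(n), nb)
  occ <- tabulate(q$levels, nb)
  sdv <- sqrt(n * (1 / nb) * (1 - 1 / nb))
  expect_true(all(abs(occ - n / nb) <= 3 * sdv))
})

test_that("quantisation is monotone and equal-width binning is affine
           invariant", {
  set.seed(8)
  for (r in 1:20) {
    v <- rnorm(50, sd = 40)
    for (q in list(quantiseFixedBinWidth(v, 15),
                   quantiseFixedBinNumber(v, 8))) {
      o <- order(v)
      expect_true(all(diff(q$levels[o]) >= 0))
    }
    a <- runif(1, 0.5, 3); b <- runif(1, -50, 50)
    expect_equal(quantiseFixedBinNumber(a * v + b, 8)$levels,
                 quantiseFixedBinNumber(v, 8)$levels)
  }
  ## hence normalising first leaves fixed-bin-number levels unchanged
  co <- small_cohort(n = 2, seed = 21)
  img <- co[[1]]@image; msk <- co[[1]]@mask
  q_raw <- quantiseROI(img, msk, "fixed_bin_number", 32)
  q_norm <- quantiseROI(normaliseImage(img), msk, "fixed_bin_number", 32)
  expect_equal(q_raw@levels, q_norm@levels)
})

test_that("adding a constant shifts bin origins with the ROI minimum", {
  set.seed(5)
  v <- runif(40, 0, 120)
  expect_equal(quantiseFixedBinWidth(v + 77, 25)$levels,
               quantiseFixedBinWidth(v, 25)$levels)
})

test_that("trilinear resampling interpolates linearly and preserves grids", {
  ## two voxels 1.5 mm apart resampled to 1 mm: the middle output sample
  ## falls exactly halfway between the input centres
  img <- ctVolume(array(c(0, 100), c(2, 1, 1)), c(1.5, 1, 1))
  msk <- voxelMask(array(1, c(2, 1, 1)), c(1.5, 1, 1))
  out <- resampleIsotropic(img, msk, 1, "linear")
  expect_equal(dim(out$image), c(3L, 1L, 1L))
  expect_equal(voxelData(out$image)[2, 1, 1], 50)
  ## identity when the input is already isotropic at the target
  iso <- ctVolume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1))
  mi <- voxelMask(array(1, c(3, 3, 3)), c(1, 1, 1))
  for (meth in c("linear", "bspline")) {
    o2 <- resampleIsotropic(iso, mi, 1, meth)
    expect_equal(voxelData(o2$image), voxelData(iso), tolerance = 1e-8)
  }
})

test_that("the B-spline interpolant passes through the input samples", {
  ## prefiltered cubic B-spline evaluation at integer positions must
  ## reproduce the data (that is the point of the prefilter)
  set.seed(3)
  for (n in c(4, 7, 20)) {
    a <- array(rnorm(n * 3 * 2, 50, 30), c(n, 3, 2))
    got <- radicc:::.interp_axis(a, 1, seq_len(n), "bspline")
    expect_equal(got, a, tolerance = 1e-8)
  }
  ## and midway samples interpolate smoothly between neighbours
  a1 <- array(c(0, 100, 0, 100, 0, 100), c(6, 1, 1))
  mid <- radicc:::.interp_axis(a1, 1, 3.5, "bspline")
  expect_equal(as.numeric(mid), 50, tolerance = 1e-6)
})

test_that("interpolators agree closely on smooth volumes", {
  co <- generateCohort(phantomConfig(nPatients = 2, mode = "multi_slice",
                                     gridSize = 32, seed = 8))
  s <- co[[1]]
  vb <- voxelData(resampleIsotropic(s@image, s@mask, 1, "bspline")$image)
  vl <- voxelData(resampleIsotropic(s@image, s@mask, 1, "linear")$image)
  expect_gt(cor(as.vector(vb), as.vector(vl)), 0.99)
})

test_that("mask resampling stays binary and bounding boxes are preserved", {
  co <- generateCohort(phantomConfig(nPatients = 2, mode = "multi_slice",
                                     gridSize = 32, seed = 6))
  img <- co[[1]]@image; msk <- co[[1]]@mask
  for (meth in c("bspline", "linear")) {
    o <- resampleIsotropic(img, msk, 1, meth)
    expect_true(all(voxelData(o$mask) %in% c(0, 1)))
    expect_gt(sum(voxelData(o$mask)), 0)
    in_extent <- dim(img) * voxelSpacing(img)
    out_extent <- dim(o$image) * voxelSpacing(o$image)
    expect_true(all(abs(in_extent - out_extent) <= 1))
  }
})

test_that("quantised ROI statistics are mask-local", {
  img <- toy_volume(matrix(c(500, 10, 20, 30), 2, 2))
  msk <- voxelMask(matrix(c(0, 1, 1, 1), 2, 2))
  roi <- quantiseROI(img, msk, "fixed_bin_width", 25)
  ## the 500 HU voxel is outside the mask: ROI minimum is 10
  expect_equal(roi@Ng, 1L)
  expect_equal(sort(roi@rawValues), c(10, 20, 30))
})
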