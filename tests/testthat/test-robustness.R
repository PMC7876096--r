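test_that("Dice coefficient follows its definition", {
  a <- array(0, c(4, 4, 1)); a[1:2, 1:4, 1] <- 1      # |X| = 8
  b <- a
  expect_equal(diceCoefficient(voxelMask(a), voxelMask(b)), 1)
  d <- array(0, c(4, 4, 1)); d[4, 1:3, 1] <- 1
  expect_equal(diceCoefficient(voxelMask(a), voxelMask(d)), 0)
  x <- array(0, c(4, 4, 1)); x[1, 1:4, 1] <- 1        # |X| = 4
  y <- array(0, c(4, 4, 1)); y[1, 1:3, 1] <- 1; y[2, 1:3, 1] <- 1
  expect_equal(diceCoefficient(voxelMask(x), voxelMask(y)), 0.6)
  expect_equal(diceCoefficient(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))),
               1)                                     # both-empty convention
  expect_error(diceCoefficient(voxelMask(a), voxelMask(array(1, c(2, 2, 1)))),
               "grid")
  ## symmetry
  expect_equal(diceCoefficient(voxelMask(x), voxelMask(y)),
               diceCoefficient(voxelMask(y), voxelMask(x)))
})

test_that("ICC degenerate cases behave as defined", {
  m <- matrix(rep(c(1, 5, 9), 3), 3, 3)   # identical raters, varying rows
  icc <- iccTwoWay(m)
  expect_equal(icc$icc_consistency, 1)
  expect_equal(icc$icc_agreement, 1)
  flat <- iccTwoWay(matrix(4, 3, 3))
  expect_false(flat$defined)
  expect_true(is.na(flat$icc_agreement))
  expect_error(iccTwoWay(matrix(1:3, 3, 1)), "raters")
  expect_error(iccTwoWay(matrix(1:4, 1, 4)), "subjects")
})

test_that("both ICC forms match the two-way ANOVA oracle", {
  set.seed(14)
  for (r in 1:30) {
    n <- sample(4:10, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k) +
      outer(rnorm(n, sd = runif(1, 0, 2)), rep(1, k)) +
      outer(rep(1, n), rnorm(k, sd = runif(1, 0, 1)))
    got <- iccTwoWay(m)
    want <- o_icc(m)
    expect_equal(got$icc_consistency, want$icc31, tolerance = 1e-10)
    expect_equal(got$icc_agreement, want$icc21, tolerance = 1e-10)
  }
})

test_that("per-rater offsets separate consistency from agreement", {
  set.seed(15)
  base <- outer(rnorm(8, sd = 5), rep(1, 4)) + matrix(rnorm(8 * 4), 8, 4)
  shifted <- sweep(base, 2, c(0, 2, 4, 6), "+")
  i0 <- iccTwoWay(base)
  i1 <- iccTwoWay(shifted)
  expect_equal(i1$icc_consistency, i0$icc_consistency, tolerance = 1e-10)
  expect_lt(i1$icc_agreement, i1$icc_consistency)
  ## ICC(3,1) >= ICC(2,1) whenever the rater mean square dominates error
  if (i1$ms_cols >= i1$ms_error)
    expect_gte(i1$icc_consistency, i1$icc_agreement)
})

test_that("robustness categories use the 0.5/0.9 thresholds", {
  expect_equal(categoriseICC(c(0.92, 0.9, 0.5, 0.49, -0.3, NA)),
               c("excellent", "excellent", "moderate", "poor", "poor",
                 "undefined"))
})

test_that("robustness tables categorise stable and noisy features
           correctly", {
  ## build a feature store by hand: 2 features, 10 subjects, 3 variants
  set.seed(16)
  ns <- 10; nv <- 3
  subj <- rep(sprintf("S%02d", 1:ns), each = nv)
  variant <- rep(c("original", "dilate1", "dilate2"), ns)
  stable <- rep(rnorm(ns, sd = 5), each = nv)          # no variant effect
  noisy <- rnorm(ns * nv)                              # pure noise
  reg <- featureRegistry()
  m <- matrix(0, nrow = 93, ncol = ns * nv,
              dimnames = list(reg$feature, NULL))
  m[1, ] <- stable; m[2, ] <- noisy
  m[3:93, ] <- rep(rnorm(ns, sd = 3), each = nv)
  cd <- S4Vectors::DataFrame(sample_id = subj, variant = variant,
                             setting_id = "s1")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m), colData = cd)
  rt <- robustnessTable(se, "s1")
  expect_equal(rt$category[1], "excellent")
  expect_equal(rt$icc_agreement[1], 1)
  expect_equal(rt$category[2], "poor")
  summ <- robustnessSummary(rt)
  tot <- summ[summ$class == "Total", ]
  expect_equal(tot$excellent + tot$moderate + tot$poor, 93)
  expect_equal(tot$excellent_pct + tot$moderate_pct + tot$poor_pct, 100)
})

test_that("a pure-noise feature is rarely classified better than poor", {
  set.seed(18)
  hits <- 0; n_mc <- 50
  for (r in seq_len(n_mc)) {
    m <- matrix(rnorm(41 * 4), 41, 4)
    icc <- iccTwoWay(m)
    hits <- hits + (categoriseICC(icc$icc_agreement) == "poor")
  }
  expect_gte(hits / n_mc, 0.95)
})

test_that("interpolation comparison separates shifts from noise", {
  set.seed(19)
  reg <- featureRegistry()
  base <- matrix(rnorm(93 * 12, sd = 4), 93, 12,
                 dimnames = list(reg$feature, sprintf("a%02d", 1:12)))
  same <- compareInterpolation(base, base)
  expect_true(all(same$icc_agreement == 1))
  expect_true(all(same$icc_consistency == 1))
  shifted <- base + 5
  dimnames(shifted) <- dimnames(base)
  cmp <- compareInterpolation(base, shifted)
  expect_true(all(abs(cmp$icc_consistency - 1) < 1e-9))
  expect_true(all(cmp$icc_agreement < 1))
  expect_error(compareInterpolation(base, base[, 1:6]), "paired")
})

test_that("interpolation agreement matches the ANOVA oracle on random
           pairs", {
  set.seed(24)
  reg <- featureRegistry()
  a <- matrix(rnorm(93 * 10, sd = 2), 93, 10,
              dimnames = list(reg$feature, sprintf("a%02d", 1:10)))
  b <- a + matrix(rnorm(93 * 10, sd = 0.3), 93, 10)
  dimnames(b) <- dimnames(a)
  cmp <- compareInterpolation(a, b)
  for (f in c(1, 40, 93)) {
    want <- o_icc(cbind(a[f, ], b[f, ]))
    expect_equal(cmp$icc_agreement[f], want$icc21, tolerance = 1e-10)
    expect_equal(cmp$icc_consistency[f], want$icc31, tolerance = 1e-10)
  }
})

test_that("observer agreement report orders perturbation severities", {
  co <- small_cohort(n = 3, seed = 25)
  masks <- lapply(co, function(s) s@mask)
  set.seed(1)
  rep_ <- observerAgreementReport(list(
    original = masks,
    observer2 = lapply(masks, simulateSecondObserver, jitter = 0.1),
    dilate1 = lapply(masks, dilateMask, iterations = 1),
    dilate2 = lapply(masks, dilateMask, iterations = 2)))
  s <- rep_$summary
  expect_gt(s$median[s$source == "dilate1"],
            s$median[s$source == "dilate2"])
  expect_true(all(rep_$pairs$dice >= 0 & rep_$pairs$dice <= 1))
  ident <- observerAgreementReport(list(original = masks, same = masks))
  expect_true(all(ident$pairs$dice == 1))
  ## heavier observer jitter lowers agreement
  set.seed(2)
  hi <- observerAgreementReport(list(
    original = masks,
    obs = lapply(masks, simulateSecondObserver, jitter = 0.05)))
  set.seed(2)
  lo <- observerAgreementReport(list(
    original = masks,
    obs = lapply(masks, simulateSecondObserver, jitter = 0.25)))
  expect_gt(median(hi$pairs$dice), median(lo$pairs$dice))
})
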