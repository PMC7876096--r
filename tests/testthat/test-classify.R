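make_labels <- function(n1, n0)
  factor(rep(c("culprit", "non_culprit"), c(n1, n0)),
         levels = c("non_culprit", "culprit"))

test_that("univariate AUC matches ranks, ties and the trapezoidal oracle", {
  y <- make_labels(3, 3)
  expect_equal(univariateAUC(c(10, 9, 8, 3, 2, 1), y), 1)
  expect_equal(univariateAUC(rep(1, 6), y), 0.5)
  expect_equal(univariateAUC(c(1, 2, 3, 8, 9, 10), y), 0)   # never flipped
  expect_error(univariateAUC(1:3, factor(rep("culprit", 3),
                                         levels = c("non_culprit",
                                                    "culprit"))),
               "classes")
  set.seed(26)
  for (r in 1:20) {
    yy <- make_labels(41, 41)
    x <- rnorm(82) + 0.4 * (as.integer(yy) - 1)
    if (r %% 2 == 0) x <- round(x)    # force ties
    expect_equal(univariateAUC(x, yy),
                 o_auc_trapezoid(x, as.integer(yy) - 1), tolerance = 1e-12)
  }
})

test_that("redundancy filter keeps the best of each correlated cluster", {
  set.seed(27)
  y <- make_labels(20, 20)
  good <- rnorm(40) + (as.integer(y) - 1) * 2
  weak <- rnorm(40) + (as.integer(y) - 1) * 0.5
  x <- cbind(a_good = good, b_twin = good, c_weak = weak)
  kept <- redundancyFilter(x, y)
  expect_true("c_weak" %in% kept)
  expect_equal(sum(c("a_good", "b_twin") %in% kept), 1)
  ## below-threshold pairs are both retained
  x2 <- cbind(u = good, v = good + rnorm(40, sd = 2))
  stopifnot(abs(cor(x2, method = "spearman")[1, 2]) < 0.95)
  expect_equal(sort(redundancyFilter(x2, y)), c("u", "v"))
})

test_that("redundancy chains resolve greedily to the strongest feature", {
  ## A = B = C up to monotone copies -> all pairwise |rho| = 1; univariate
  ## AUCs ordered A > B > C, so only A survives
  set.seed(28)
  y <- make_labels(15, 15)
  base <- rnorm(30) + (as.integer(y) - 1) * 1.5
  ## monotone copies share ranks, hence |rho| = 1 and equal rank AUCs
  x <- cbind(A = base, B = rank(base), C = exp(base))
  kept <- redundancyFilter(x, y)
  expect_equal(kept, "A")   # AUC ties break to the first name
})

test_that("the model zoo pins the published configuration", {
  zoo <- modelZoo()
  expect_length(zoo, 6)
  expect_equal(zoo$elastic_net$params$alpha, 0.5)
  expect_true(all(vapply(zoo, function(m) m$seed, 0L) == 42L))
  expect_setequal(names(zoo), c("decision_tree", "random_forest", "lasso",
                                "elastic_net", "neural_net", "xgboost"))
})

test_that("cross-validation is stratified, deterministic and finds
           separable structure", {
  set.seed(29)
  y <- make_labels(20, 20)
  tab <- data.frame(label = y,
                    calcium_score = runif(40),
                    f1 = (as.integer(y) - 1) * 10 + rnorm(40, sd = 0.1),
                    f2 = rnorm(40))
  cv <- runCV(tab, modelZoo()$elastic_net, c("f1", "f2"), k = 5, seed = 42)
  expect_equal(cv$mean_auc, 1)
  expect_equal(nrow(cv$folds), 5)
  ## every artery in exactly one test fold, both classes per fold
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(cv$fold_assignment == f & y == "culprit"), 4)
    expect_equal(sum(cv$fold_assignment == f & y == "non_culprit"), 4)
  }
  cv2 <- runCV(tab, modelZoo()$elastic_net, c("f1", "f2"), k = 5, seed = 42)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$scores, cv2$scores)
  ## coefficient matrix covers each fold and only the requested predictors
  expect_equal(dim(cv$coefficients), c(2L, 5L))
  ## all six models run on the same table
  for (m in modelZoo()) {
    r <- runCV(tab, m, c("f1", "f2"), k = 5, seed = 42)
    expect_true(is.finite(r$mean_auc))
    expect_gt(r$mean_auc, 0.9)   # trivially separable for any learner
  }
})

test_that("permuted labels centre the cross-validated AUC at chance", {
  set.seed(33)
  aucs <- replicate(200, {
    y <- make_labels(20, 20)[sample(40)]
    tab <- data.frame(label = y, f1 = rnorm(40), f2 = rnorm(40))
    runCV(tab, modelZoo()$elastic_net, c("f1", "f2"), k = 5,
          seed = sample.int(1e6, 1))$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("DeLong test matches its defining identities", {
  set.seed(34)
  y <- make_labels(20, 20)
  a <- rnorm(40) + 0.8 * (as.integer(y) - 1)
  same <- delongTest(y, a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  b <- rnorm(40)
  dl <- delongTest(y, a, b)
  ## placement identity: AUC equals the Mann-Whitney statistic
  expect_equal(dl$auc_a, univariateAUC(a, y), tolerance = 1e-12)
  expect_equal(dl$auc_b, univariateAUC(b, y), tolerance = 1e-12)
  expect_true(dl$p >= 0 && dl$p <= 1)
})

test_that("DeLong agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (r in 1:10) {
    y <- make_labels(15, 25)
    a <- rnorm(40) + 0.6 * (as.integer(y) - 1)
    b <- rnorm(40) + 0.3 * (as.integer(y) - 1)
    got <- delongTest(y, a, b)
    ref <- pROC::roc.test(pROC::roc(as.integer(y) - 1, a, quiet = TRUE,
                                    direction = "<"),
                          pROC::roc(as.integer(y) - 1, b, quiet = TRUE,
                                    direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Wilcoxon signed-rank p-values follow the normal approximation
           without continuity correction", {
  ## five paired differences all of one sign: W = 0, mu = 7.5,
  ## sigma = sqrt(13.75), z = -2.0226 -> two-sided p = 0.0431
  a <- c(0.70, 0.72, 0.68, 0.75, 0.71)
  b <- a - c(0.05, 0.04, 0.06, 0.03, 0.07)
  p <- wilcoxonSignedRankAUC(b, a)
  expect_equal(p, 2 * pnorm(-7.5 / sqrt(13.75)), tolerance = 1e-12)
  expect_equal(round(p, 3), 0.043)
  expect_equal(wilcoxonSignedRankAUC(a, a), 1)
  ## sign symmetry
  expect_equal(wilcoxonSignedRankAUC(a, b), p)
  ## exact mode uses the signed-rank distribution
  expect_equal(wilcoxonSignedRankAUC(b, a, exact = TRUE),
               2 * psignrank(0, 5))
})

test_that("model comparison wires the three predictor sets correctly", {
  set.seed(36)
  y <- make_labels(20, 20)
  tab <- data.frame(label = y,
                    calcium_score = rnorm(40),
                    f1 = (as.integer(y) - 1) * 3 + rnorm(40),
                    f2 = rnorm(40))
  cmp <- compareModels(tab, c("f1", "f2"))
  expect_gt(cmp$radiomics$mean_auc, cmp$calcium$mean_auc)
  expect_equal(rownames(cmp$integrated$coefficients),
               c("f1", "f2", "calcium_score"))
  expect_equal(rownames(cmp$radiomics$coefficients), c("f1", "f2"))
  expect_true(all(c("delong_integrated_vs_calcium",
                    "wilcoxon_integrated_vs_calcium") %in% names(cmp)))
  expect_true(cmp$wilcoxon_integrated_vs_calcium >= 0 &&
                cmp$wilcoxon_integrated_vs_calcium <= 1)
})
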