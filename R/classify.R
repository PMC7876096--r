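## Redundancy pruning, the six-classifier zoo under stratified five-fold CV,
## and the statistical comparisons between correlated classifiers (DeLong on
## paired scores, Wilcoxon signed-rank on fold AUCs).

#' Rank-based AUC of a single feature (univariate logistic score)
#'
#' Because the logistic link is monotone, the AUC of a single-feature
#' logistic regression equals the rank AUC of the raw feature, computed via
#' the Mann-Whitney relation with midranks for ties. Not flipped below 0.5.
#'
#' @param feature numeric vector.
#' @param labels binary vector/factor; the second level (or 1) is positive.
#' @return AUC in [0, 1].
#' @export
univariateAUC <- function(feature, labels) {
  y <- .as01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("univariateAUC: both classes required")
  r <- rank(feature)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as01 <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else as.integer(labels == max(labels))
}

#' Spearman redundancy filter
#'
#' Among pairs of features with |Spearman rho| >= `threshold`, keeps the one
#' with the higher univariate AUC and drops the other. Pairs are processed
#' in descending |rho|; pairs with an already-dropped member are skipped.
#' Equal AUCs break ties to the lexicographically first name.
#'
#' @param x numeric matrix/data.frame, samples x features.
#' @param labels binary labels for the univariate AUC ranking.
#' @param threshold absolute Spearman correlation cut-off (default 0.95).
#' @return character vector of retained feature names (original order).
#' @export
redundancyFilter <- function(x, labels, threshold = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(colnames(x))
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[is.na(rho)] <- 1   # constant columns are mutually redundant
  auc <- apply(x, 2, univariateAUC, labels = labels)
  pr <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  if (nrow(pr) > 0) {
    ord <- order(-abs(rho[pr]), pr[, 1], pr[, 2])
    pr <- pr[ord, , drop = FALSE]
  }
  dropped <- rep(FALSE, ncol(x))
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (dropped[i] || dropped[j]) next
    if (auc[i] > auc[j]) dropped[j] <- TRUE
    else if (auc[j] > auc[i]) dropped[i] <- TRUE
    else {
      loser <- if (colnames(x)[i] <= colnames(x)[j]) j else i
      dropped[loser] <- TRUE
    }
  }
  colnames(x)[!dropped]
}

#' The six-classifier model zoo
#'
#' Specifications of the classifiers compared in the pipeline, with their
#' configurations pinned explicitly: decision tree (impurity splitting,
#' unlimited depth), random forest (100 trees), L1-penalised (LASSO)
#' logistic regression, elastic-net logistic regression with mixing 0.5
#' (both at a fixed penalty of 1/n, no tuning), a one-hidden-layer
#' perceptron and gradient-boosted trees. All stochastic fits are seeded
#' with random state 42.
#'
#' @return named list of six model specification lists (name, params, seed).
#' @export
modelZoo <- function() {
  list(
    decision_tree = list(name = "decision_tree",
                         params = list(cp = 0, minsplit = 2, minbucket = 1),
                         seed = 42L),
    random_forest = list(name = "random_forest",
                         params = list(ntree = 100), seed = 42L),
    lasso = list(name = "lasso", params = list(alpha = 1), seed = 42L),
    elastic_net = list(name = "elastic_net", params = list(alpha = 0.5),
                       seed = 42L),
    neural_net = list(name = "neural_net",
                      params = list(size = 8, decay = 1e-4, maxit = 200),
                      seed = 42L),
    xgboost = list(name = "xgboost",
                   params = list(nrounds = 100, max_depth = 6, eta = 0.3),
                   seed = 42L)
  )
}

## fit one model on standardised training data, return P(culprit) on test;
## seeds the fit with the spec's random state without disturbing the
## caller's RNG stream
.fit_predict <- function(spec, xtr, ytr, xte) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  nm <- spec$name
  if (nm %in% c("lasso", "elastic_net")) {
    fit <- .fit_glmnet(spec, xtr, ytr)
    as.numeric(predict(fit, .pad1(xte), type = "response"))
  } else if (nm == "decision_tree") {
    df <- data.frame(y = factor(ytr), xtr, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = spec$params$cp,
                          minsplit = spec$params$minsplit,
                          minbucket = spec$params$minbucket, xval = 0))
    predict(fit, data.frame(xte, check.names = FALSE), type = "prob")[, "1"]
  } else if (nm == "random_forest") {
    fit <- randomForest::randomForest(xtr, factor(ytr),
                                      ntree = spec$params$ntree)
    predict(fit, xte, type = "prob")[, "1"]
  } else if (nm == "neural_net") {
    capture.output(fit <- nnet::nnet(xtr, ytr, size = spec$params$size,
                                     decay = spec$params$decay,
                                     maxit = spec$params$maxit,
                                     entropy = TRUE, trace = FALSE))
    as.numeric(predict(fit, xte))
  } else if (nm == "xgboost") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$params$max_depth,
                    eta = spec$params$eta, nthread = 1,
                    seed = spec$seed),
      data = dtr, nrounds = spec$params$nrounds, verbose = 0)
    predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
  } else stop("unknown model: ", nm)
}

## glmnet requires >= 2 columns; pad single-predictor designs with an
## all-zero dummy whose coefficient is necessarily zero
.pad1 <- function(x) {
  if (ncol(x) >= 2) x else cbind(x, `.dummy` = 0)
}

.fit_glmnet <- function(spec, xtr, ytr) {
  ## glmnet warns about small class counts on every small training fold;
  ## fold sizes are part of the study design, so silence that one warning
  withCallingHandlers(
    glmnet::glmnet(.pad1(xtr), ytr, family = "binomial",
                   alpha = spec$params$alpha, lambda = 1 / nrow(xtr),
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

## stratified k-fold assignment after a seeded shuffle; restores the
## caller's RNG stream
.stratified_folds <- function(y, k, seed) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  idx <- sample(seq_along(y))        # single seeded shuffle
  fold <- integer(length(y))
  for (cl in unique(y[idx])) {
    cls <- idx[y[idx] == cl]
    fold[cls] <- rep(seq_len(k), length.out = length(cls))
  }
  fold
}

#' Stratified five-fold cross-validation of one classifier
#'
#' Shuffles the arteries with the given seed, assigns label-stratified
#' folds, and per fold standardises the predictors (mean 0, variance 1;
#' statistics from the training folds only by default), fits the model and
#' scores the held-out fold. Accuracy uses the 0.5 probability threshold.
#'
#' @param table data.frame from [featureTable()] (label column plus numeric
#'   predictors).
#' @param spec one element of [modelZoo()].
#' @param predictors character vector of predictor column names.
#' @param k number of folds (default 5).
#' @param seed shuffle seed (default 42).
#' @param scaleMode "infold" (standardise within training folds; default) or
#'   "global" (standardise once on the full table before CV).
#' @return list of class "cvReport": per-fold AUC/accuracy/sensitivity/
#'   specificity, mean and SD of AUC, mean accuracy with a percentile 95%
#'   interval across folds, per-fold coefficients (penalised models), fold
#'   assignment, and out-of-fold scores aligned to the input rows.
#' @export
runCV <- function(table, spec, predictors, k = 5, seed = 42,
                  scaleMode = c("infold", "global")) {
  scaleMode <- match.arg(scaleMode)
  y <- .as01(table$label)
  x <- as.matrix(table[, predictors, drop = FALSE])
  storage.mode(x) <- "double"
  if (scaleMode == "global") x <- .zscale(x, x)$x
  fold <- .stratified_folds(y, k, seed)
  if (any(tabulate(fold[y == 1], k) == 0) ||
      any(tabulate(fold[y == 0], k) == 0))
    stop("runCV: degenerate fold (a class is missing)")
  scores <- numeric(length(y))
  met <- data.frame(fold = seq_len(k), auc = NA_real_, accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  coefs <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (scaleMode == "infold") {
      sc <- .zscale(x[tr, , drop = FALSE], x)
      xtr <- sc$x[tr, , drop = FALSE]; xte <- sc$x[te, , drop = FALSE]
    } else {
      xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    }
    p <- .fit_predict(spec, xtr, y[tr], xte)
    scores[te] <- p
    yt <- y[te]
    met$auc[f] <- univariateAUC(p, yt)
    pred <- as.integer(p >= 0.5)
    met$accuracy[f] <- mean(pred == yt)
    met$sensitivity[f] <- if (any(yt == 1)) mean(pred[yt == 1] == 1) else NA
    met$specificity[f] <- if (any(yt == 0)) mean(pred[yt == 0] == 0) else NA
    if (spec$name %in% c("lasso", "elastic_net")) {
      fit <- .fit_glmnet(spec, xtr, y[tr])
      coefs[[f]] <- as.numeric(coef(fit))[-1][seq_along(predictors)]
    }
  }
  cf <- if (length(coefs)) {
    cm <- do.call(cbind, coefs)
    rownames(cm) <- predictors
    colnames(cm) <- paste0("fold", seq_len(k))
    cm
  } else NULL
  structure(list(model = spec$name, folds = met,
                 mean_auc = mean(met$auc), sd_auc = sd(met$auc),
                 mean_accuracy = mean(met$accuracy),
                 accuracy_ci = unname(quantile(met$accuracy,
                                               c(0.025, 0.975))),
                 coefficients = cf, fold_assignment = fold,
                 scores = scores, seed = seed, predictors = predictors),
            class = "cvReport")
}

.zscale <- function(ref, x) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, sd)
  sdv[sdv == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

#' @exportS3Method base::print
print.cvReport <- function(x, ...) {
  cat(sprintf("Cross-validated %s: mean AUC %.3f (SD %.3f), accuracy %.1f%%\n",
              x$model, x$mean_auc, x$sd_auc, 100 * x$mean_accuracy))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same labelled samples via
#' placement values and the DeLong covariance estimate, returning a
#' two-sided normal p-value. Zero variance of the AUC difference yields
#' p = 1 with a message.
#'
#' @param labels binary labels.
#' @param scoresA,scoresB paired numeric score vectors.
#' @return list with auc_a, auc_b, z, p.
#' @export
delongTest <- function(labels, scoresA, scoresB) {
  y <- .as01(labels)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("delongTest: both classes required")
  if (length(scoresA) != length(y) || length(scoresB) != length(y))
    stop("delongTest: scores must pair with labels")
  plc <- function(s) {
    ## placement values: V10[i] = P(s_pos[i] > s_neg) with tie correction
    sp <- s[pos]; sn <- s[neg]
    v10 <- vapply(sp, function(v) mean((v > sn) + 0.5 * (v == sn)), 0)
    v01 <- vapply(sn, function(v) mean((sp > v) + 0.5 * (sp == v)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- plc(scoresA); b <- plc(scoresB)
  m <- length(pos); n <- length(neg)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0) {
    message("delongTest: zero variance of the AUC difference; p = 1")
    return(list(auc_a = a$auc, auc_b = b$auc, z = 0, p = 1))
  }
  z <- (a$auc - b$auc) / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test on paired fold AUCs
#'
#' Signed-rank statistic on the paired differences with zeros dropped and
#' midranks for tied magnitudes; the two-sided p-value uses the normal
#' approximation without continuity correction (with five one-signed fold
#' differences this gives p = 0.0431). An exact-distribution mode is
#' available for small samples without ties.
#'
#' @param aucsA,aucsB equal-length paired numeric vectors (fold AUCs).
#' @param exact use the exact signed-rank distribution instead of the
#'   normal approximation (requires no ties/zeros).
#' @return two-sided p-value.
#' @export
wilcoxonSignedRankAUC <- function(aucsA, aucsB, exact = FALSE) {
  stopifnot(length(aucsA) == length(aucsB))
  d <- aucsA - aucsB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (exact) {
    if (anyDuplicated(abs(d)))
      stop("wilcoxonSignedRankAUC: exact mode requires untied magnitudes")
    return(min(1, 2 * min(stats::psignrank(w, n),
                          1 - stats::psignrank(w - 1, n))))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 == 0) return(1)
  z <- (w - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

#' Compare calcium-only, radiomics-only and integrated models
#'
#' Runs the given classifier under identical fold assignments for the three
#' predictor sets of the workflow: (1) calcium score only, (2) the selected
#' radiomic features only and (3) features plus calcium ("integrated").
#' Reports per-fold DeLong comparisons of the pooled out-of-fold scores and
#' Wilcoxon signed-rank tests on the fold AUC distributions.
#'
#' @param table data.frame from [featureTable()].
#' @param features character vector of selected radiomic feature columns.
#' @param spec model specification (default elastic net).
#' @param k,seed,scaleMode passed to [runCV()].
#' @return list with the three "cvReport" objects (`calcium`, `radiomics`,
#'   `integrated`), DeLong results on out-of-fold scores, and Wilcoxon
#'   p-values for the three AUC-distribution comparisons.
#' @export
compareModels <- function(table, features, spec = modelZoo()$elastic_net,
                          k = 5, seed = 42,
                          scaleMode = c("infold", "global")) {
  scaleMode <- match.arg(scaleMode)
  stopifnot("calcium_score" %in% names(table))
  cv_cal <- runCV(table, spec, "calcium_score", k, seed, scaleMode)
  cv_rad <- runCV(table, spec, features, k, seed, scaleMode)
  cv_int <- runCV(table, spec, c(features, "calcium_score"), k, seed,
                  scaleMode)
  y <- table$label
  list(
    calcium = cv_cal, radiomics = cv_rad, integrated = cv_int,
    delong_radiomics_vs_calcium = delongTest(y, cv_rad$scores,
                                             cv_cal$scores),
    delong_integrated_vs_calcium = delongTest(y, cv_int$scores,
                                              cv_cal$scores),
    delong_integrated_vs_radiomics = delongTest(y, cv_int$scores,
                                                cv_rad$scores),
    wilcoxon_radiomics_vs_calcium =
      wilcoxonSignedRankAUC(cv_rad$folds$auc, cv_cal$folds$auc),
    wilcoxon_integrated_vs_calcium =
      wilcoxonSignedRankAUC(cv_int$folds$auc, cv_cal$folds$auc),
    wilcoxon_integrated_vs_radiomics =
      wilcoxonSignedRankAUC(cv_int$folds$auc, cv_rad$folds$auc)
  )
}
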