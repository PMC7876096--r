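## Segmentation agreement (Dice) and feature robustness (two-way
## mixed-effects ICC) with the poor/moderate/excellent categorisation.

#' Dice similarity coefficient
#'
#' DC = 2|X n Y| / (|X| + |Y|). Two empty masks are defined as agreeing
#' perfectly (DC = 1).
#'
#' @param x,y [VoxelMask-class] objects on the same grid (or plain binary
#'   arrays of equal shape).
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(x, y) {
  vx <- if (is(x, "VoxelMask")) x@values else x
  vy <- if (is(y, "VoxelMask")) y@values else y
  if (!identical(dim(vx), dim(vy)))
    stop("diceCoefficient: masks must share the same grid")
  sx <- sum(vx); sy <- sum(vy)
  if (sx + sy == 0) return(1)
  2 * sum(vx * vy) / (sx + sy)
}

#' Two-way mixed-effects single-rater intraclass correlations
#'
#' Computes, from the two-way ANOVA mean squares of an n-subjects x
#' k-raters matrix, the consistency form
#' ICC(3,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)
#' and the absolute-agreement form
#' ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k/n (MS_C - MS_E)).
#' Estimates can be negative in small samples; they are returned as
#' computed. When a denominator is zero (e.g. all cells equal) the result is
#' flagged undefined.
#'
#' @param m numeric matrix, rows = subjects (n >= 2), columns = raters
#'   (k >= 2), no missing cells.
#' @return list with icc_consistency, icc_agreement, ms_rows, ms_cols,
#'   ms_error and `defined`.
#' @export
iccTwoWay <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("iccTwoWay: need n >= 2 subjects, k >= 2 raters")
  if (anyNA(m)) stop("iccTwoWay: missing cells not allowed")
  gm <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm_ - gm)^2)
  ss_err <- sum((m - outer(rm_, rep(1, k)) -
                   outer(rep(1, n), cm_) + gm)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  den3 <- ms_r + (k - 1) * ms_e
  den2 <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  defined <- den3 > 0 && den2 != 0
  list(
    icc_consistency = if (den3 > 0) (ms_r - ms_e) / den3 else NA_real_,
    icc_agreement = if (defined) (ms_r - ms_e) / den2 else NA_real_,
    ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
    defined = defined
  )
}

#' Categorise an ICC value into a robustness class
#'
#' ICC < 0.5 (including negative estimates) is poor, 0.5 <= ICC < 0.9 is
#' moderate, ICC >= 0.9 is excellent; NA is "undefined" (counted with poor
#' in summary proportions).
#'
#' @param icc numeric vector (NA allowed).
#' @return character vector of categories.
#' @export
categoriseICC <- function(icc) {
  ifelse(is.na(icc), "undefined",
         ifelse(icc < 0.5, "poor",
                ifelse(icc < 0.9, "moderate", "excellent")))
}

#' Per-feature robustness table across perturbation variants
#'
#' For one setting, treats mask variants as raters and arteries as subjects:
#' per feature an ICC(2,1) (absolute agreement) across variants over
#' arteries, plus the consistency ICC(3,1), each categorised by the
#' 0.5/0.9 thresholds.
#'
#' @param se a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   from [extractFeatures()] (or a subset of its columns for one setting).
#' @param settingId optional setting id to subset to.
#' @return data.frame with one row per feature: feature, class,
#'   icc_agreement, icc_consistency, category.
#' @export
robustnessTable <- function(se, settingId = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  if (!is.null(settingId)) {
    keep <- cd$setting_id == settingId
    se <- se[, keep]; cd <- cd[keep, , drop = FALSE]
  }
  a <- SummarizedExperiment::assay(se)
  variants <- unique(cd$variant)
  samples <- unique(cd$sample_id)
  if (length(variants) < 2) stop("robustnessTable: need >= 2 variants")
  reg <- featureRegistry()
  res <- lapply(seq_len(nrow(a)), function(f) {
    m <- matrix(NA_real_, length(samples), length(variants),
                dimnames = list(samples, variants))
    for (v in variants) {
      cols <- which(cd$variant == v)
      m[cd$sample_id[cols], v] <- a[f, cols]
    }
    drop <- apply(m, 1, function(r) anyNA(r) || any(!is.finite(r)))
    m <- m[!drop, , drop = FALSE]
    if (nrow(m) < 2)
      return(data.frame(icc_agreement = NA_real_,
                        icc_consistency = NA_real_))
    icc <- iccTwoWay(m)
    data.frame(icc_agreement = icc$icc_agreement,
               icc_consistency = icc$icc_consistency)
  })
  res <- do.call(rbind, res)
  data.frame(feature = rownames(a),
             class = reg$class[match(rownames(a), reg$feature)],
             icc_agreement = res$icc_agreement,
             icc_consistency = res$icc_consistency,
             category = categoriseICC(res$icc_agreement),
             stringsAsFactors = FALSE)
}

#' Class-level robustness summary (counts and percentages)
#'
#' @param rt data.frame from [robustnessTable()].
#' @return data.frame with one row per feature class plus "Total": counts
#'   and percentages of excellent/moderate/poor (undefined counted as poor).
#' @export
robustnessSummary <- function(rt) {
  cat3 <- ifelse(rt$category == "undefined", "poor", rt$category)
  mk <- function(idx, name) {
    n <- length(idx)
    ex <- sum(cat3[idx] == "excellent")
    mo <- sum(cat3[idx] == "moderate")
    po <- sum(cat3[idx] == "poor")
    data.frame(class = name, n = n,
               excellent = ex, excellent_pct = 100 * ex / n,
               moderate = mo, moderate_pct = 100 * mo / n,
               poor = po, poor_pct = 100 * po / n,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(rt$class), function(cl)
    mk(which(rt$class == cl), cl)))
  rbind(out, mk(seq_len(nrow(rt)), "Total"))
}

#' Agreement between interpolation methods, per feature
#'
#' Pairs the per-artery feature values obtained under B-spline and linear
#' resampling (k = 2 raters) and reports both ICC flavours per feature.
#'
#' @param featBspline,featLinear matrices (features x samples) with
#'   identical dimnames.
#' @return data.frame: feature, icc_agreement, icc_consistency, category.
#' @export
compareInterpolation <- function(featBspline, featLinear) {
  if (!identical(dimnames(featBspline), dimnames(featLinear)))
    stop("compareInterpolation: inputs must be paired (same features and ",
         "samples)")
  res <- lapply(seq_len(nrow(featBspline)), function(f) {
    m <- cbind(bspline = featBspline[f, ], linear = featLinear[f, ])
    m <- m[stats::complete.cases(m) & apply(is.finite(m), 1, all), ,
           drop = FALSE]
    if (nrow(m) < 2)
      return(data.frame(icc_agreement = NA_real_,
                        icc_consistency = NA_real_))
    icc <- iccTwoWay(m)
    data.frame(icc_agreement = icc$icc_agreement,
               icc_consistency = icc$icc_consistency)
  })
  res <- do.call(rbind, res)
  data.frame(feature = rownames(featBspline),
             icc_agreement = res$icc_agreement,
             icc_consistency = res$icc_consistency,
             category = categoriseICC(res$icc_agreement),
             stringsAsFactors = FALSE)
}

#' Dice agreement report across mask sources
#'
#' Computes the Dice coefficient of every non-original source against the
#' original mask, per artery, and summarises medians and IQRs per source
#' (the violin-plot summary of systematic and observer perturbations).
#'
#' @param masksBySource named list; each element is a list of
#'   [VoxelMask-class] of equal length (one per artery). Must contain an
#'   element named "original".
#' @return list with `pairs` (long data.frame: source, artery, dice) and
#'   `summary` (per source: median, q1, q3).
#' @export
observerAgreementReport <- function(masksBySource) {
  if (!"original" %in% names(masksBySource))
    stop("observerAgreementReport: need an 'original' source")
  orig <- masksBySource$original
  others <- setdiff(names(masksBySource), "original")
  pairs <- do.call(rbind, lapply(others, function(src) {
    d <- vapply(seq_along(orig), function(i)
      diceCoefficient(orig[[i]], masksBySource[[src]][[i]]), 0)
    data.frame(source = src, artery = seq_along(orig), dice = d,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(pairs, pairs$source), function(g)
    data.frame(source = g$source[1],
               median = median(g$dice),
               q1 = unname(quantile(g$dice, 0.25)),
               q3 = unname(quantile(g$dice, 0.75)))))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}
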