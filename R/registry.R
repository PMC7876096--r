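## Fixed registry of the 93 unfiltered radiomic features, grouped by class.
## Names follow the IBSI-conformant reference naming; order is frozen so that
## feature vectors are positionally stable across runs.

.firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

.glcm_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
  "Imc1", "Imc2", "InverseVariance", "JointEnergy", "JointEntropy",
  "MCC", "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

.glrlm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.glszm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.gldm_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

.ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                  "Strength")

#' Registry of the 93 radiomic features
#'
#' Returns the frozen list of feature names and their classes: 18 first-order
#' intensity statistics, 24 grey-level co-occurrence (GLCM), 16 run-length
#' (GLRLM), 16 size-zone (GLSZM), 14 dependence (GLDM) and 5 neighbouring
#' grey tone difference (NGTDM) features. Full feature names are
#' "<class>_<feature>", e.g. "glcm_Autocorrelation".
#'
#' @return data.frame with columns `feature` (qualified name), `class` and
#'   `short` (unqualified name), 93 rows.
#' @export
#' @examples
#' table(featureRegistry()$class)
featureRegistry <- function() {
  cls <- c(rep("firstorder", length(.firstorder_names)),
           rep("glcm", length(.glcm_names)),
           rep("glrlm", length(.glrlm_names)),
           rep("glszm", length(.glszm_names)),
           rep("gldm", length(.gldm_names)),
           rep("ngtdm", length(.ngtdm_names)))
  short <- c(.firstorder_names, .glcm_names, .glrlm_names, .glszm_names,
             .gldm_names, .ngtdm_names)
  data.frame(feature = paste(cls, short, sep = "_"), class = cls,
             short = short, stringsAsFactors = FALSE)
}
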