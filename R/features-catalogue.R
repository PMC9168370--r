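## Feature family name tables.  Names follow the widely used
## <image>_<family>_<feature> convention so every column of the 851-feature
## table is auditable.

.FIRSTORDER <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                 "Percentile10", "Percentile90", "Maximum", "Mean", "Median",
                 "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                 "Kurtosis", "Variance", "Uniformity")

.SHAPE <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
            "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
            "Elongation", "Flatness")

.GLCM <- c("Autocorrelation", "JointAverage", "ClusterProminence",
           "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
           "Id", "Idn", "InverseVariance", "MaximumProbability", "MCC",
           "SumAverage", "SumEntropy", "SumSquares")

.GLRLM <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

.GLSZM <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
            "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
            "ZoneEntropy", "LowGrayLevelZoneEmphasis",
            "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
            "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
            "LargeAreaHighGrayLevelEmphasis")

.GLDM <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "GrayLevelVariance",
           "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
           "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis",
           "LargeDependenceHighGrayLevelEmphasis")

.NGTDM <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

.WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

## the 93 non-shape features recomputed on each wavelet sub-band
nonshape_names <- function(prefix) {
  c(paste0(prefix, "_firstorder_", .FIRSTORDER),
    paste0(prefix, "_glcm_", .GLCM),
    paste0(prefix, "_glrlm_", .GLRLM),
    paste0(prefix, "_glszm_", .GLSZM),
    paste0(prefix, "_gldm_", .GLDM),
    paste0(prefix, "_ngtdm_", .NGTDM))
}

#' The handcrafted radiomics feature catalogue
#'
#' 851 uniquely named features: 14 shape + 18 first-order + 75 texture
#' features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5) on the original
#' image (107 in total), plus the 93 non-shape features recomputed on each
#' of the 8 sub-bands of a single-level 3-D wavelet transform (744).  Shape
#' is computed once, never per sub-band.
#'
#' @return data.frame with columns `name`, `image`, `family`, `feature`.
#' @export
feature_catalogue <- function() {
  split3 <- function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)
    data.frame(name = nm,
               image = vapply(parts, `[`, character(1), 1),
               family = vapply(parts, `[`, character(1), 2),
               feature = vapply(parts, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  }
  nm <- c(paste0("original_shape_", .SHAPE), nonshape_names("original"),
          unlist(lapply(paste0("wavelet.", .WAVELET_BANDS), nonshape_names),
                 use.names = FALSE))
  split3(nm)
}

#' Discretization configuration for texture matrices
#'
#' Gray levels are discretized with `n_bins` equal-width bins spanning the
#' in-mask minimum to maximum of the image at hand (the original image and
#' every wavelet sub-band are binned independently), which makes texture
#' features invariant to additive intensity shifts.
#'
#' @param n_bins number of gray levels (>= 2).
#' @return list of class `discretization_config`.
#' @export
discretization_config <- function(n_bins = 32L) {
  stop_if_not(n_bins >= 2, "n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins)), class = "discretization_config")
}

## Equal-width discretization over the value range; constant input -> bin 1.
discretize_values <- function(values, n_bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  pmin(n_bins, floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L)
}
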