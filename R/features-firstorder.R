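#' First-order intensity statistics
#'
#' The 18 standard first-order features over the pooled in-mask voxels of a
#' slice stack.  Entropy and Uniformity use the discretized histogram (same
#' binning scheme as the texture families); TotalEnergy scales Energy by the
#' voxel volume in cubic mm.
#'
#' @param values numeric vector of in-mask voxel intensities.
#' @param voxel_volume voxel volume in cubic mm.
#' @param n_bins histogram bins for Entropy/Uniformity.
#' @return named numeric vector of length 18.
#' @export
extract_first_order <- function(values, voxel_volume = 1, n_bins = 32L) {
  stop_if_not(length(values) > 0, "first-order: empty pooled voxel set")
  n <- length(values)
  p <- tabulate(discretize_values(values, n_bins), n_bins) / n
  p <- p[p > 0]
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  p10 <- qtl(values, 0.10); p90 <- qtl(values, 0.90)
  mid <- values[values >= p10 & values <= p90]
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else 0
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(values),
    Mean = mu,
    Median = stats::median(values),
    InterquartileRange = qtl(values, 0.75) - qtl(values, 0.25),
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}
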