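#' One-call compartment calling pipeline
#'
#' Chains [filter_bins()], [truncate_trans_outliers()], [ice_balance()] and
#' [compartment_eigenvector()] with their standard defaults.
#'
#' @param m raw [contact_matrix()].
#' @param min_coverage_fraction,low_coverage_quantile see [filter_bins()].
#' @param top_quantile see [truncate_trans_outliers()].
#' @param mode,orientation_track,timepoint,min_bins_per_chrom see
#'   [compartment_eigenvector()].
#' @return an `eigen_track`.
#' @export
call_compartments <- function(m, min_coverage_fraction = 0.5,
                              low_coverage_quantile = 0.01,
                              top_quantile = 0.0005,
                              mode = "trans_only",
                              orientation_track = NULL,
                              timepoint = NA_character_,
                              min_bins_per_chrom = 10) {
  m <- filter_bins(m, min_coverage_fraction, low_coverage_quantile)
  m <- truncate_trans_outliers(m, top_quantile)
  m <- ice_balance(m)
  compartment_eigenvector(m, mode = mode,
                          orientation_track = orientation_track,
                          timepoint = timepoint,
                          min_bins_per_chrom = min_bins_per_chrom)
}
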