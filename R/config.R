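#' Sequencing quality-control thresholds
#'
#' Container for the three sample-level QC gates applied before copy-number
#' calling: the fraction of panel exons covered at 100X or more (strict
#' "more than"), the mean sequencing depth, and the read mapping rate.
#'
#' @param min_exon_cov_frac Minimum fraction of exons at >= 100X; a sample
#'   passes only if its fraction is strictly greater than this. Default 0.98.
#' @param min_depth Minimum mean sequencing depth in X (inclusive).
#'   Default 200.
#' @param min_map_rate Minimum mapping rate (inclusive). Default 0.95.
#' @return An object of class `qc_thresholds`.
#' @seealso [qc_check()]
#' @export
qc_thresholds <- function(min_exon_cov_frac = 0.98, min_depth = 200,
                          min_map_rate = 0.95) {
  if (!is.numeric(min_exon_cov_frac) || min_exon_cov_frac < 0 ||
      min_exon_cov_frac > 1) {
    stop_validation("min_exon_cov_frac must be a fraction in [0, 1]")
  }
  if (!is.numeric(min_depth) || min_depth <= 0) {
    stop_validation("min_depth must be positive")
  }
  if (!is.numeric(min_map_rate) || min_map_rate < 0 || min_map_rate > 1) {
    stop_validation("min_map_rate must be a fraction in [0, 1]")
  }
  structure(
    list(min_exon_cov_frac = min_exon_cov_frac, min_depth = min_depth,
         min_map_rate = min_map_rate),
    class = "qc_thresholds"
  )
}

#' Segmentation parameters for band-level region building
#'
#' Tunables of the cytoband segmentation: the non-significance level of the
#' between-band t-tests, the copy-number-gain threshold, and the two
#' region-merging rules.
#'
#' @param alpha Between-band t-test P values at or above this are treated as
#'   "no difference" (default 0.1).
#' @param cng_threshold A region is a copy-number gain when its mean copy
#'   number is strictly greater than this (default 2.3; diploid = 2).
#' @param merge_frac_major Rule (i): adjacent regions merge when the
#'   fraction of non-significant cross-region band pairs is strictly greater
#'   than this (default 0.5).
#' @param merge_frac_minor Rule (ii): when the larger region has more than
#'   `merge_big_region_bands` bands, merging requires only a fraction
#'   strictly greater than this (default 0.3).
#' @param merge_big_region_bands Band count the larger region must strictly
#'   exceed for rule (ii) (default 7).
#' @param min_bins_per_band Bands with fewer bins than this are pre-merged
#'   into the neighbouring band with the closer mean copy number so every
#'   t-test is defined (default 2).
#' @param pair_rule `"all"` (default): a band joins a growing region only if
#'   it is non-significantly different from every band already in the
#'   region; `"adjacent"`: only the immediately preceding band is tested.
#' @param var_equal Use the pooled-variance t-test instead of Welch's
#'   unequal-variance test (default `FALSE`).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(alpha = 0.1, cng_threshold = 2.3,
                                merge_frac_major = 0.5,
                                merge_frac_minor = 0.3,
                                merge_big_region_bands = 7,
                                min_bins_per_band = 2,
                                pair_rule = c("all", "adjacent"),
                                var_equal = FALSE) {
  pair_rule <- match.arg(pair_rule)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must lie strictly between 0 and 1")
  }
  for (v in c(cng_threshold, merge_frac_major, merge_frac_minor,
              merge_big_region_bands, min_bins_per_band)) {
    if (!is.numeric(v) || v <= 0) stop_validation("thresholds must be positive")
  }
  structure(
    list(alpha = alpha, cng_threshold = cng_threshold,
         merge_frac_major = merge_frac_major,
         merge_frac_minor = merge_frac_minor,
         merge_big_region_bands = merge_big_region_bands,
         min_bins_per_band = min_bins_per_band,
         pair_rule = pair_rule, var_equal = isTRUE(var_equal)),
    class = "segmentation_config"
  )
}

#' Classification thresholds for the four-way MET status call
#'
#' @param gcn_threshold MET gene copy number below this is "negative";
#'   shared with region copy-number-gain calling (default 2.3).
#' @param frac_amp_max Amplified fraction of 7q at or below this is focal
#'   MET amplification (default 0.10).
#' @param frac_polysomy_min Amplified fraction at or above this is polysomy
#'   (default 0.80).
#' @param fish_ratio_threshold MET/CEP7 ratio strictly above this is FISH
#'   amplification (default 2.0).
#' @param fish_gcn_threshold FISH mean MET copies per cell at or above this
#'   (with ratio at or below `fish_ratio_threshold`) is FISH polysomy
#'   (default 5).
#' @return An object of class `classifier_config`.
#' @seealso [classify_met()], [classify_fish()]
#' @export
classifier_config <- function(gcn_threshold = 2.3, frac_amp_max = 0.10,
                              frac_polysomy_min = 0.80,
                              fish_ratio_threshold = 2.0,
                              fish_gcn_threshold = 5.0) {
  if (!(frac_amp_max > 0 && frac_amp_max < frac_polysomy_min &&
        frac_polysomy_min < 1)) {
    stop_validation("need 0 < frac_amp_max < frac_polysomy_min < 1")
  }
  if (gcn_threshold <= 0 || fish_ratio_threshold <= 0 ||
      fish_gcn_threshold <= 0) {
    stop_validation("thresholds must be positive")
  }
  structure(
    list(gcn_threshold = gcn_threshold, frac_amp_max = frac_amp_max,
         frac_polysomy_min = frac_polysomy_min,
         fish_ratio_threshold = fish_ratio_threshold,
         fish_gcn_threshold = fish_gcn_threshold),
    class = "classifier_config"
  )
}

#' MET status labels
#'
#' The four statuses, in the package's canonical order.
#' @return Character vector of length 4.
#' @export
met_statuses <- function() {
  c("negative", "amplification", "pan_met_amplification", "polysomy")
}
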