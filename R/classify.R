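# Four-way MET status call from the gene copy number and the 7q
# segmentation, plus the FISH-side classification used as reference.

#' Estimate MET gene copy number from capture bins
#'
#' Unweighted mean copy number of the capture bins annotated with the MET
#' gene symbol.
#'
#' @param bins Bin `data.frame` (see [read_cnr()]).
#' @param gene Gene symbol to average over (default `"MET"`).
#' @return Numeric copy number.
#' @export
met_gcn_estimate <- function(bins, gene = "MET") {
  sel <- bins$kind == "capture" & !is.na(bins$gene) & bins$gene == gene
  if (!any(sel)) {
    stop_validation(paste0("no capture bins annotated '", gene,
                           "' and no gene copy number supplied"))
  }
  mean(bins$cn[sel])
}

#' The four-way MET decision rule
#'
#' Total function over (gene copy number, amplified fraction of 7q,
#' CNG state of the MET-band region), evaluated in fixed order:
#' \enumerate{
#'   \item gene copy number below `gcn_threshold` (2.3): `negative`;
#'   \item amplified fraction at or above `frac_polysomy_min` (0.80):
#'     `polysomy`;
#'   \item MET-band region not a CNG, or amplified fraction at or below
#'     `frac_amp_max` (0.10): `amplification`;
#'   \item otherwise (MET region gained and 10--80\% of the arm gained):
#'     `pan_met_amplification`.
#' }
#' Putting polysomy before the amplification clause makes the overlapping
#' conditions deterministic.
#'
#' @param met_gcn MET gene copy number (diploid = 2).
#' @param amplified_fraction Fraction of the 7q arm in CNG regions.
#' @param met_region_cng Logical: is the region containing the MET band a
#'   copy-number gain?
#' @param config A [classifier_config()].
#' @return One of [met_statuses()].
#' @export
met_decision_rule <- function(met_gcn, amplified_fraction, met_region_cng,
                              config = classifier_config()) {
  stopifnot(is.numeric(met_gcn), met_gcn >= 0,
            is.numeric(amplified_fraction),
            amplified_fraction >= 0, amplified_fraction <= 1,
            is.logical(met_region_cng))
  if (met_gcn < config$gcn_threshold) return("negative")
  if (amplified_fraction >= config$frac_polysomy_min) return("polysomy")
  if (!met_region_cng || amplified_fraction <= config$frac_amp_max) {
    return("amplification")
  }
  "pan_met_amplification"
}

#' Classify MET status from a gene copy number and an arm segmentation
#'
#' Applies [met_decision_rule()] to the supplied MET gene copy number and
#' the segmentation's amplified fraction and MET-band region state.
#'
#' @param met_gcn MET gene copy number.
#' @param seg An `arm_segmentation` built with a `met_band` anchor.
#' @param config A [classifier_config()].
#' @param sample Sample label carried into the call.
#' @return Object of class `met_call` with `status`, `met_gcn`,
#'   `amplified_fraction`, `met_region_cng`, `met_band`, `sample` and the
#'   `segmentation` itself.
#' @export
classify_met <- function(met_gcn, seg, config = classifier_config(),
                         sample = "sample") {
  stopifnot(inherits(seg, "arm_segmentation"))
  if (!any(seg$regions$contains_met)) {
    stop_validation("segmentation has no MET-band anchor; pass met_band to segment_arm()")
  }
  met_region_cng <- seg$regions$is_cng[seg$regions$contains_met]
  status <- met_decision_rule(met_gcn, seg$amplified_fraction,
                              met_region_cng, config)
  structure(
    list(sample = sample, status = status, met_gcn = met_gcn,
         amplified_fraction = seg$amplified_fraction,
         met_region_cng = met_region_cng, met_band = seg$met_band,
         segmentation = seg),
    class = "met_call"
  )
}

#' End-to-end MET status call from a bin table
#'
#' Runs the full pipeline on one sample: off-target bins are aggregated per
#' 7q cytoband, segmented into regions, regions merged, the MET gene copy
#' number estimated from the capture bins (unless supplied), and the
#' four-way status called.
#'
#' The MET anchor band defaults to the band containing the midpoint of the
#' MET capture bins; supply `met_band` to override (the arm map must
#' contain it).
#'
#' @param bins Bin `data.frame` (see [read_cnr()]).
#' @param bands Cytoband `data.frame` (see [read_cytobands()]).
#' @param seg_config A [segmentation_config()].
#' @param config A [classifier_config()].
#' @param met_gcn Optional externally determined MET gene copy number;
#'   bypasses estimation from capture bins.
#' @param met_band Optional band name anchoring MET (e.g. `"q31.2"`).
#' @param gene Capture-bin gene symbol (default `"MET"`).
#' @param sample Sample label.
#' @param arm Arm to segment (default `"q"`).
#' @return A `met_call` (see [classify_met()]).
#' @examples
#' spec <- synthetic_spec(status = "amplification", seed = 7)
#' prof <- simulate_tissue_profile(spec)
#' call_met_status(prof$bins, synthetic_band_map(), sample = "example")
#' @export
call_met_status <- function(bins, bands, seg_config = segmentation_config(),
                            config = classifier_config(), met_gcn = NULL,
                            met_band = NULL, gene = "MET",
                            sample = "sample", arm = "q") {
  bins <- as_bins(bins)
  if (is.null(met_band)) {
    sel <- bins$kind == "capture" & !is.na(bins$gene) & bins$gene == gene
    if (!any(sel)) {
      stop_validation(
        "cannot locate the MET band: no MET capture bins and no met_band given")
    }
    mid <- (min(bins$start[sel]) + max(bins$end[sel])) / 2
    hit <- bands$start <= mid & bands$end > mid & bands$arm == arm
    if (!any(hit)) {
      stop_validation("MET capture bins fall outside the supplied band map")
    }
    met_band <- bands$name[which(hit)[1]]
  }
  seg <- segment_arm(bins, bands, arm = arm, config = seg_config,
                     met_band = met_band)
  gcn <- met_gcn %||% met_gcn_estimate(bins, gene = gene)
  classify_met(gcn, seg, config = config, sample = sample)
}

#' @export
print.met_call <- function(x, ...) {
  cat(sprintf("MET status call for '%s'\n", x$sample))
  cat(sprintf("  status:             %s\n", x$status))
  cat(sprintf("  MET gene copy no.:  %.3f\n", x$met_gcn))
  cat(sprintf("  amplified fraction: %.3f of 7q\n", x$amplified_fraction))
  cat(sprintf("  MET-band region:    %s (band %s)\n",
              if (isTRUE(x$met_region_cng)) "copy-number gain" else "no gain",
              x$met_band %||% "?"))
  invisible(x)
}

#' MET/CEP7 ratio
#'
#' Mean MET signals per cell divided by mean CEP7 (chromosome 7 centromere)
#' signals per cell; displayed to one decimal in reports.
#'
#' @param mean_gcn Mean MET signals per cell.
#' @param cep7 Mean CEP7 signals per cell (must be positive).
#' @return Numeric ratio.
#' @export
met_cep7_ratio <- function(mean_gcn, cep7) {
  if (!is.numeric(cep7) || cep7 <= 0) stop_validation("cep7 must be positive")
  mean_gcn / cep7
}

#' Classify a FISH result
#'
#' MET amplification by FISH is a MET/CEP7 ratio strictly above
#' `fish_ratio_threshold` (2.0). Among non-amplified samples, a mean MET
#' copy number at or above `fish_gcn_threshold` (5) — i.e. proportional
#' gain of gene and centromere — is called polysomy; everything else is
#' negative. The ratio-first rule is the simplest one consistent with
#' the assay's amplification criterion (gene copy number >= 5 and/or
#' ratio > 2.0); FISH labels can always be supplied externally instead.
#'
#' @param mean_gcn Mean MET signals per cell.
#' @param cep7 Mean CEP7 signals per cell.
#' @param config A [classifier_config()].
#' @return Object of class `fish_result` with `mean_gcn`, `cep7`, `ratio`,
#'   `status` (`amplification` / `polysomy` / `negative`).
#' @export
classify_fish <- function(mean_gcn, cep7, config = classifier_config()) {
  ratio <- met_cep7_ratio(mean_gcn, cep7)
  status <- if (ratio > config$fish_ratio_threshold) {
    "amplification"
  } else if (mean_gcn >= config$fish_gcn_threshold) {
    "polysomy"
  } else {
    "negative"
  }
  structure(list(mean_gcn = mean_gcn, cep7 = cep7, ratio = ratio,
                 status = status),
            class = "fish_result")
}

#' @export
print.fish_result <- function(x, ...) {
  cat(sprintf("FISH: MET %.1f / CEP7 %.1f, ratio %.1f -> %s\n", x$mean_gcn,
              x$cep7, x$ratio, x$status))
  invisible(x)
}
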