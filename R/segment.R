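# Region formation and merging on a chromosome arm, and the amplified
# fraction of the arm. Regions are contiguous runs of band profiles; a
# region is a copy-number gain (CNG) when its mean copy number over all
# member bins exceeds the configured threshold.

region_stats <- function(idx, profiles, config) {
  cns <- unlist(lapply(profiles[idx], `[[`, "cns"))
  len <- sum(vapply(profiles[idx], function(p) p$end - p$start, numeric(1)))
  mean_cn <- mean(cns)
  list(idx = idx, n_bands = length(idx), n_bins = length(cns),
       mean_cn = mean_cn, length_bp = len,
       is_cng = mean_cn > config$cng_threshold)
}

# Greedy left-to-right region growth on the precomputed P matrix. Under
# pair_rule "all" a band joins only if it is non-significantly different
# from every band already in the region; under "adjacent", only from the
# last one.
grow_regions <- function(P, config) {
  k <- nrow(P)
  if (k == 0) stop_validation("no band profiles to segment")
  regions <- list()
  cur <- 1L
  if (k >= 2) {
    for (j in 2:k) {
      members <- if (config$pair_rule == "all") cur else cur[length(cur)]
      if (all(P[j, members] >= config$alpha)) {
        cur <- c(cur, j)
      } else {
        regions[[length(regions) + 1L]] <- cur
        cur <- j
      }
    }
  }
  regions[[length(regions) + 1L]] <- cur
  regions
}

# Merge sweep: the leftmost adjacent pair satisfying either rule merges,
# statistics are recomputed, and the sweep restarts; repeated to fixpoint.
# Rule (i): fraction f of non-significant cross-region band pairs
# > merge_frac_major. Rule (ii): the larger region has
# > merge_big_region_bands bands and f > merge_frac_minor.
merge_sweep <- function(regions, P, config) {
  repeat {
    merged <- FALSE
    if (length(regions) >= 2) {
      for (i in seq_len(length(regions) - 1)) {
        a <- regions[[i]]; b <- regions[[i + 1]]
        f <- mean(P[a, b, drop = FALSE] >= config$alpha)
        n_large <- max(length(a), length(b))
        if (f > config$merge_frac_major ||
            (n_large > config$merge_big_region_bands &&
             f > config$merge_frac_minor)) {
          regions[[i]] <- c(a, b)
          regions[[i + 1]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) return(regions)
  }
}

#' Form initial regions from band profiles
#'
#' Grows regions greedily left to right: a band joins the current region
#' only while it shows no significant copy-number difference (t-test P at
#' or above `config$alpha`) from the bands already in the region (all
#' pairs by default). The regions partition the bands.
#'
#' @param profiles A `band_profiles` object from [assign_bins_to_bands()].
#' @param config A [segmentation_config()].
#' @return List of integer vectors, each the band indices of one region.
#' @export
form_initial_regions <- function(profiles, config = segmentation_config()) {
  stopifnot(inherits(profiles, "band_profiles"))
  grow_regions(band_p_matrix(profiles$profiles, config), config)
}

#' Merge similar adjacent regions
#'
#' Adjacent regions merge when (i) the fraction of cross-region band pairs
#' without a significant copy-number difference exceeds
#' `config$merge_frac_major`, or (ii) the larger region has more than
#' `config$merge_big_region_bands` bands and that fraction exceeds
#' `config$merge_frac_minor`. The leftmost eligible pair merges first and
#' sweeps repeat until no merge applies (a fixpoint).
#'
#' @param regions List of band-index vectors (see [form_initial_regions()]).
#' @param profiles The `band_profiles` the regions refer to.
#' @param config A [segmentation_config()].
#' @return List of band-index vectors after merging.
#' @export
merge_regions <- function(regions, profiles,
                          config = segmentation_config()) {
  stopifnot(inherits(profiles, "band_profiles"))
  merge_sweep(regions, band_p_matrix(profiles$profiles, config), config)
}

#' Segment a chromosome arm into copy-number regions
#'
#' The full band-level segmentation: off-target bins are aggregated per
#' cytoband, adjacent bands compared by t-tests, bands grouped greedily
#' into regions without significant internal differences, similar adjacent
#' regions merged, and each region flagged as copy-number gain (CNG) when
#' its mean copy number exceeds `config$cng_threshold`. The amplified
#' fraction is the summed genomic length of CNG regions over the arm span.
#'
#' @param bins Bin `data.frame` (see [read_cnr()]).
#' @param bands Cytoband `data.frame` (see [read_cytobands()]).
#' @param arm `"q"` (default) or `"p"`.
#' @param config A [segmentation_config()].
#' @param met_band Band name anchoring the MET locus (e.g. `"q31.2"`);
#'   when given, the region containing it is flagged.
#' @return An object of class `arm_segmentation` with elements `chrom`,
#'   `arm`, `band_profiles`, `regions` (a `data.frame`),
#'   `amplified_fraction`, `arm_length`, `met_band`, `config`.
#' @export
segment_arm <- function(bins, bands, arm = "q",
                        config = segmentation_config(), met_band = NULL) {
  bp <- assign_bins_to_bands(bins, bands, arm = arm, config = config)
  P <- band_p_matrix(bp$profiles, config)
  regions <- merge_sweep(grow_regions(P, config), P, config)
  stats <- lapply(regions, region_stats, profiles = bp$profiles,
                  config = config)
  contains_met <- rep(FALSE, length(regions))
  if (!is.null(met_band)) {
    hit <- which(vapply(regions, function(idx) {
      met_band %in% unlist(lapply(bp$profiles[idx], `[[`, "bands"))
    }, logical(1)))
    if (length(hit) != 1) {
      stop_validation(sprintf(
        "MET band '%s' not found in exactly one region of the band map",
        met_band))
    }
    contains_met[hit] <- TRUE
  }
  rdf <- data.frame(
    region = seq_along(regions),
    start_band = vapply(stats, function(s) bp$profiles[[s$idx[1]]]$bands[1],
                        character(1)),
    end_band = vapply(stats, function(s) {
      b <- bp$profiles[[s$idx[s$n_bands]]]$bands
      b[length(b)]
    }, character(1)),
    start = vapply(stats, function(s) bp$profiles[[s$idx[1]]]$start,
                   numeric(1)),
    end = vapply(stats, function(s) bp$profiles[[s$idx[s$n_bands]]]$end,
                 numeric(1)),
    n_bands = vapply(stats, `[[`, integer(1), "n_bands"),
    n_bins = vapply(stats, `[[`, integer(1), "n_bins"),
    mean_cn = vapply(stats, `[[`, numeric(1), "mean_cn"),
    length_bp = vapply(stats, `[[`, numeric(1), "length_bp"),
    is_cng = vapply(stats, `[[`, logical(1), "is_cng"),
    contains_met = contains_met,
    stringsAsFactors = FALSE
  )
  arm_length <- bp$arm_end - bp$arm_start
  if (arm_length <= 0) stop_validation("arm length must be positive")
  seg <- structure(
    list(chrom = bp$chrom, arm = arm, band_profiles = bp,
         region_bands = regions, regions = rdf,
         amplified_fraction = sum(rdf$length_bp[rdf$is_cng]) / arm_length,
         arm_length = arm_length, met_band = met_band, config = config),
    class = "arm_segmentation"
  )
  seg
}

#' Amplified fraction of the arm
#'
#' The summed genomic length of copy-number-gain regions divided by the
#' arm length (span from the first to the last band of the arm). An
#' alternative CNG threshold re-evaluates the region flags without
#' re-segmenting.
#'
#' @param seg An `arm_segmentation`.
#' @param cng_threshold Optional copy-number threshold overriding the one
#'   the segmentation was built with.
#' @return Fraction in `[0, 1]`.
#' @export
amplified_fraction <- function(seg, cng_threshold = NULL) {
  stopifnot(inherits(seg, "arm_segmentation"))
  if (seg$arm_length <= 0) stop_validation("arm length must be positive")
  thr <- cng_threshold %||% seg$config$cng_threshold
  cng <- seg$regions$mean_cn > thr
  sum(seg$regions$length_bp[cng]) / seg$arm_length
}

#' @export
print.arm_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation of %s%s (%.1f Mb, %d band profiles)\n", x$chrom,
              x$arm, x$arm_length / 1e6, length(x$band_profiles$profiles)))
  cat(sprintf("  %d region(s); amplified fraction %.3f (CNG: mean cn > %.2f)\n",
              nrow(x$regions), x$amplified_fraction, x$config$cng_threshold))
  print(x$regions, digits = 4)
  invisible(x)
}

#' @export
summary.arm_segmentation <- function(object, ...) {
  r <- object$regions
  cat(sprintf("%s%s: %d regions, %d CNG, amplified fraction %.3f\n",
              object$chrom, object$arm, nrow(r), sum(r$is_cng),
              object$amplified_fraction))
  invisible(object)
}

#' Plot an arm segmentation
#'
#' Bin copy numbers along the arm with region means overlaid; CNG regions
#' are highlighted.
#'
#' @param x An `arm_segmentation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.arm_segmentation <- function(x, ...) {
  prof <- x$band_profiles$profiles
  pos <- unlist(lapply(prof, function(p) {
    if (length(p$cns)) seq(p$start, p$end, length.out = length(p$cns)) else numeric()
  }))
  cns <- unlist(lapply(prof, `[[`, "cns"))
  graphics::plot(pos / 1e6, cns, pch = 16, cex = 0.4, col = "grey50",
                 xlab = sprintf("%s position (Mb)", x$chrom),
                 ylab = "copy number", ...)
  graphics::abline(h = x$config$cng_threshold, lty = 3)
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    graphics::segments(r$start / 1e6, r$mean_cn, r$end / 1e6, r$mean_cn,
                       lwd = 3, col = if (r$is_cng) "firebrick" else "navy")
  }
  invisible(x)
}
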